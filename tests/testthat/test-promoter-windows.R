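# Gene-model parsing and the TSS-anchored promoter interval rule.

make_gff <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF3 coordinates convert to 0-based TSS and translation start", {
  gff <- make_gff(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tsrc\tCDS\t1201\t1800\t.\t+\t0\tID=c1;Parent=g1.t1",
    "chr1\tsrc\tgene\t3001\t4000\t.\t-\t.\tID=g2",
    "chr1\tsrc\tmRNA\t3001\t4000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\tsrc\tCDS\t3101\t3900\t.\t-\t0\tID=c2;Parent=g2.t1",
    "chr1\tsrc\tgene\t5001\t6000\t.\t+\t.\tID=g3",
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t+\t.\tID=g3.t1;Parent=g3"))
  m <- parse_gene_models(gff)
  expect_equal(m$tss[m$gene_id == "g1"], 1000)
  expect_equal(m$translation_start[m$gene_id == "g1"], 1200)
  # minus strand: 5' end is the right edge, 5'-most CDS base the CDS max
  expect_equal(m$tss[m$gene_id == "g2"], 3999)
  expect_equal(m$translation_start[m$gene_id == "g2"], 3899)
  # no CDS child: translation_start absent, flagged
  expect_true(is.na(m$translation_start[m$gene_id == "g3"]))
  expect_true(m$no_cds[m$gene_id == "g3"])
})

test_that("multi-transcript genes use the first-listed transcript", {
  gff <- make_gff(c(
    "chr1\tsrc\tgene\t1001\t3000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1501\t3000\t.\t+\t.\tID=g1.tB;Parent=g1",
    "chr1\tsrc\tCDS\t1601\t2800\t.\t+\t0\tID=cB;Parent=g1.tB",
    "chr1\tsrc\tmRNA\t1001\t3000\t.\t+\t.\tID=g1.tA;Parent=g1",
    "chr1\tsrc\tCDS\t1201\t2800\t.\t+\t0\tID=cA;Parent=g1.tA"))
  m <- parse_gene_models(gff)
  expect_equal(nrow(m), 1)
  expect_equal(m$transcript_id, "g1.tB")
  expect_equal(m$tss, 1500)
})

test_that("malformed GFF lines are reported with their line number", {
  gff <- make_gff(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t2000"))
  expect_error(parse_gene_models(gff), "line 3")
})

test_that("genes with CDS upstream of the TSS are dropped with a warning", {
  gff <- make_gff(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=g1.t1;Parent=g1",
    # on minus strand the 5'-most CDS base must be <= tss (right edge)
    "chr1\tsrc\tCDS\t1001\t2400\t.\t-\t0\tID=c1;Parent=g1.t1",
    "chr1\tsrc\tgene\t5001\t6000\t.\t+\t.\tID=g2",
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t+\t.\tID=g2.t1;Parent=g2",
    "chr1\tsrc\tCDS\t5101\t5900\t.\t+\t0\tID=c2;Parent=g2.t1"))
  expect_warning(m <- parse_gene_models(gff), "upstream of TSS")
  expect_equal(m$gene_id, "g2")
})

toy_genome <- function(len = 10000, seed = 11) {
  set.seed(seed)
  c(chr1 = random_dna(len))
}

test_that("promoter windows follow the upstream/translation-start/cap rule", {
  genome <- toy_genome()
  models <- data.frame(
    gene_id = c("a", "b", "c", "d"), chrom = "chr1",
    strand = c("+", "+", "-", "+"),
    tss = c(5000, 5000, 8000, 300),
    translation_start = c(5200, 6500, 7900, 800))
  w <- extract_promoter_windows(genome, models)
  expect_s3_class(w, "promoter_windows")
  # d = min(200, 1000)
  expect_equal(unlist(w[w$gene_id == "a", c("start", "end")]),
               c(start = 4400, end = 5200))
  # d capped at 1000
  expect_equal(unlist(w[w$gene_id == "b", c("start", "end")]),
               c(start = 4400, end = 6000))
  # minus strand: transcript -600..+99 -> genomic [7901, 8601)
  expect_equal(unlist(w[w$gene_id == "c", c("start", "end")]),
               c(start = 7901, end = 8601))
  # clipping at the chromosome edge
  expect_equal(w$start[w$gene_id == "d"], 0)
  expect_equal(nchar(w$sequence), w$end - w$start)
  expect_equal(nchar(w$sequence)[1:3], c(800, 1600, 700))
})

test_that("minus-strand sequences are transcript-oriented", {
  genome <- toy_genome()
  models <- data.frame(gene_id = "c", chrom = "chr1", strand = "-",
                       tss = 8000, translation_start = 7900)
  w <- extract_promoter_windows(genome, models)
  slice <- substr(genome[["chr1"]], 7902, 8601)  # genomic [7901, 8601)
  expect_identical(w$sequence, oracle_revcomp(slice))
})

test_that("genes with TSS at the translation start keep upstream only, and
          missing translation starts fall back to the cap", {
  genome <- toy_genome()
  models <- data.frame(gene_id = c("e", "f"), chrom = "chr1",
                       strand = "+", tss = c(5000, 5000),
                       translation_start = c(5000, NA))
  w <- extract_promoter_windows(genome, models)
  expect_equal(w$end[w$gene_id == "e"] - w$start[w$gene_id == "e"], 600)
  expect_equal(w$end[w$gene_id == "f"] - w$start[w$gene_id == "f"], 1600)
})

test_that("flipping genome and annotation preserves transcript-oriented
          windows", {
  genome <- toy_genome(4000, seed = 21)
  L <- nchar(genome[["chr1"]])
  models <- data.frame(
    gene_id = c("p", "m"), chrom = "chr1", strand = c("+", "-"),
    tss = c(2000, 3000), translation_start = c(2350, 2800))
  flipped_genome <- c(chr1 = oracle_revcomp(genome[["chr1"]]))
  flipped_models <- models
  flipped_models$strand <- ifelse(models$strand == "+", "-", "+")
  flipped_models$tss <- L - 1 - models$tss
  flipped_models$translation_start <- L - 1 - models$translation_start
  w1 <- extract_promoter_windows(genome, models)
  w2 <- extract_promoter_windows(flipped_genome, flipped_models)
  expect_identical(w1$sequence, w2$sequence)
})

test_that("missing chromosomes error with the gene ids", {
  genome <- toy_genome(1000)
  models <- data.frame(gene_id = "zz", chrom = "chrX", strand = "+",
                       tss = 500, translation_start = 700)
  expect_error(extract_promoter_windows(genome, models), "zz")
})

test_that("empty windows after clipping are skipped with a warning", {
  genome <- toy_genome(1000)
  # minus-strand gene on the last base with d = 0: window [1000, 1600)
  # clips to nothing
  models <- data.frame(gene_id = c("edge", "ok"), chrom = "chr1",
                       strand = "-", tss = c(999, 500),
                       translation_start = c(999, 400))
  expect_warning(w <- extract_promoter_windows(genome, models),
                 "empty promoter window")
  expect_equal(w$gene_id, "ok")
})

test_that("FASTA/BED round trips are deterministic and id-preserving", {
  genome <- toy_genome()
  models <- data.frame(gene_id = c("a", "c"), chrom = "chr1",
                       strand = c("+", "-"), tss = c(5000, 8000),
                       translation_start = c(5200, 7900))
  w <- extract_promoter_windows(genome, models)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  b1 <- tempfile(fileext = ".bed"); b2 <- tempfile(fileext = ".bed")
  write_promoter_fasta(w, f1); write_promoter_fasta(w, f2)
  write_promoter_bed(w, b1); write_promoter_bed(w, b2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(b1), readLines(b2))
  back <- read_promoter_fasta(f1)
  expect_identical(unname(back), w$sequence)
  expect_identical(names(back), w$gene_id)
  bed <- read.delim(b1, header = FALSE)
  expect_equal(bed$V2, w$start)
  expect_equal(bed$V6, w$strand)
})
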