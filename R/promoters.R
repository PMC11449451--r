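## Promoter window extraction: TSS-anchored intervals in a single internal
## convention (0-based, half-open, transcript-oriented sequence).

#' Parse gene models from a GFF3 annotation
#'
#' Reads a GFF3 file and reduces it to one gene model per gene: the gene's
#' transcription start site (TSS, the transcript 5' end on the feature's
#' strand) and translation start (the 5'-most CDS base in transcript
#' orientation), both converted to 0-based genomic positions.
#'
#' Multi-transcript genes are collapsed to a single primary transcript: the
#' first-listed mRNA of the gene, ties broken by lexicographically smallest
#' transcript id. Transcripts lacking a CDS child get `translation_start = NA`
#' and are flagged `no_cds`. Genes whose CDS lies upstream of the TSS in
#' transcript orientation are invalid; they are dropped with a warning.
#'
#' @param gff_file Path to a GFF3 annotation (1-based, inclusive coordinates;
#'   `gene`, `mRNA`/transcript and `CDS` features).
#' @return A data.frame of class `gene_models` with columns `gene_id`,
#'   `transcript_id`, `chrom`, `strand` (`"+"`/`"-"`), `tss`,
#'   `translation_start` (0-based; `NA` when no CDS) and logical `no_cds`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c(
#'   "##gff-version 3",
#'   "chr1\tx\tgene\t1001\t2000\t.\t+\t.\tID=g1",
#'   "chr1\tx\tmRNA\t1001\t2000\t.\t+\t.\tID=g1.t1;Parent=g1",
#'   "chr1\tx\tCDS\t1201\t1800\t.\t+\t0\tID=c1;Parent=g1.t1"), gff)
#' parse_gene_models(gff)
#' @export
parse_gene_models <- function(gff_file) {
  if (!file.exists(gff_file)) {
    stop("annotation file not found: ", gff_file)
  }
  .check_gff_lines(gff_file)
  gr <- rtracklayer::import(gff_file, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  tx_types <- c("mRNA", "transcript")

  is_tx <- type %in% tx_types
  is_cds <- type == "CDS"
  if (!any(is_tx)) stop("no mRNA/transcript features in ", gff_file)

  tx_id <- as.character(meta$ID[is_tx])
  tx_parent <- vapply(meta$Parent[is_tx], function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  tx_chrom <- as.character(GenomicRanges::seqnames(gr))[is_tx]
  tx_strand <- as.character(BiocGenerics::strand(gr))[is_tx]
  tx_start <- BiocGenerics::start(gr)[is_tx]   # 1-based inclusive
  tx_end <- BiocGenerics::end(gr)[is_tx]
  tx_order <- seq_along(tx_id)                 # file order

  if (any(!tx_strand %in% c("+", "-"))) {
    bad <- tx_id[!tx_strand %in% c("+", "-")]
    stop("transcripts without strand: ", paste(bad, collapse = ", "))
  }

  # primary transcript per gene: first-listed, ties by smallest id
  gene_of_tx <- ifelse(is.na(tx_parent), tx_id, tx_parent)
  ord <- order(gene_of_tx, tx_order, tx_id)
  keep <- ord[!duplicated(gene_of_tx[ord])]

  # 5'-most CDS base per transcript, in transcript orientation
  cds_parent <- unlist(lapply(meta$Parent[is_cds], function(p) {
    as.character(p[[1]])
  }), use.names = FALSE)
  cds_start <- BiocGenerics::start(gr)[is_cds]
  cds_end <- BiocGenerics::end(gr)[is_cds]
  cds_min <- tapply(cds_start, cds_parent, min)
  cds_max <- tapply(cds_end, cds_parent, max)

  id <- tx_id[keep]
  strand <- tx_strand[keep]
  tss <- ifelse(strand == "+", tx_start[keep] - 1L, tx_end[keep] - 1L)
  ts <- ifelse(strand == "+",
               as.integer(cds_min[id]) - 1L,
               as.integer(cds_max[id]) - 1L)
  no_cds <- is.na(ts)

  models <- data.frame(
    gene_id = gene_of_tx[keep],
    transcript_id = id,
    chrom = tx_chrom[keep],
    strand = strand,
    tss = as.integer(tss),
    translation_start = as.integer(ts),
    no_cds = no_cds,
    stringsAsFactors = FALSE
  )

  # CDS upstream of TSS in transcript orientation -> invalid model
  dist <- ifelse(models$strand == "+",
                 models$translation_start - models$tss,
                 models$tss - models$translation_start)
  bad <- !is.na(dist) & dist < 0
  if (any(bad)) {
    warning("dropping ", sum(bad), " gene(s) with CDS upstream of TSS: ",
            paste(models$gene_id[bad], collapse = ", "))
    models <- models[!bad, , drop = FALSE]
  }
  rownames(models) <- NULL
  class(models) <- c("gene_models", "data.frame")
  models
}

# fast structural check so malformed lines are reported with their number
.check_gff_lines <- function(gff_file) {
  lines <- readLines(gff_file, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L)) {
    lineno <- which(body)[which(nfield != 9L)[1]]
    stop("malformed GFF3 line ", lineno, " in ", gff_file,
         " (expected 9 tab-separated fields, found ", nfield[nfield != 9L][1],
         ")")
  }
  invisible(TRUE)
}

#' Extract TSS-anchored promoter windows
#'
#' For each gene model, takes the interval from `upstream` bp upstream of the
#' TSS to either the translation start site or `downstream_cap` bp downstream
#' of the TSS, whichever is smaller. Windows are clipped to chromosome bounds
#' and returned with the sequence in transcript orientation (minus-strand
#' windows are reverse-complemented).
#'
#' Genes with no annotated translation start fall back to the full
#' `downstream_cap`; genes whose TSS equals the translation start get the
#' upstream part only. Coordinates are 0-based half-open genomic.
#'
#' @param genome A named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or a path to a FASTA file.
#' @param models A `gene_models` data.frame from [parse_gene_models()] (or any
#'   data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `translation_start`).
#' @param upstream Bases upstream of the TSS (default 600).
#' @param downstream_cap Maximum bases downstream of the TSS (default 1000).
#' @return A data.frame of class `promoter_windows` with columns `gene_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `strand` and `sequence`
#'   (uppercase, transcript-oriented).
#' @seealso [write_promoter_fasta()], [write_promoter_bed()]
#' @export
extract_promoter_windows <- function(genome, models, upstream = 600,
                                     downstream_cap = 1000) {
  stopifnot(upstream > 0, downstream_cap > 0)
  genome <- .as_dna_set(genome)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  missing_chr <- !(models$chrom %in% names(genome))
  if (any(missing_chr)) {
    stop("chromosome(s) missing from genome for gene(s): ",
         paste(models$gene_id[missing_chr], collapse = ", "))
  }

  dist <- ifelse(models$strand == "+",
                 models$translation_start - models$tss,
                 models$tss - models$translation_start)
  d <- pmin(ifelse(is.na(dist), downstream_cap, dist), downstream_cap)

  start <- ifelse(models$strand == "+", models$tss - upstream,
                  models$tss - d + 1L)
  end <- ifelse(models$strand == "+", models$tss + d,
                models$tss + upstream + 1L)
  start <- pmax(start, 0L)
  end <- pmin(end, chrom_len[models$chrom])

  empty <- start >= end
  if (any(empty)) {
    warning("skipping ", sum(empty), " gene(s) with empty promoter window: ",
            paste(models$gene_id[empty], collapse = ", "))
  }
  keep <- which(!empty)

  seqs <- character(length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    s <- Biostrings::subseq(genome[[models$chrom[j]]],
                            start = start[j] + 1L, end = end[j])
    if (models$strand[j] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- toupper(as.character(s))
  }

  out <- data.frame(
    gene_id = models$gene_id[keep],
    chrom = models$chrom[keep],
    start = as.integer(start[keep]),
    end = as.integer(end[keep]),
    strand = models$strand[keep],
    sequence = seqs,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("promoter_windows", "data.frame")
  out
}

.as_dna_set <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("genome must be a DNAStringSet, named character vector or FASTA path")
}

#' Write promoter windows to FASTA
#'
#' Record ids are gene ids; sequences are transcript-oriented.
#'
#' @param windows A `promoter_windows` data.frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(windows, path) {
  seqs <- Biostrings::DNAStringSet(windows$sequence)
  names(seqs) <- windows$gene_id
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Write promoter windows to BED6
#'
#' Emits 0-based half-open intervals with `name = gene_id` and the strand
#' column set, in the input's row order.
#'
#' @inheritParams write_promoter_fasta
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(windows, path) {
  bed <- data.frame(windows$chrom, windows$start, windows$end,
                    windows$gene_id, 0L, windows$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a promoters FASTA into a named sequence vector
#'
#' Convenience inverse of [write_promoter_fasta()] for feeding the motif
#' scanners.
#'
#' @param path FASTA path.
#' @return Named uppercase character vector (names = gene ids).
#' @export
read_promoter_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
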