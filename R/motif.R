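## TGTCNN hexamer scanning, repeat-syntax classification (DR/IR/ER with
## spacers), and gene-level Fisher enrichment.

.revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  n <- nchar(comp)
  if (length(unique(n)) == 1 && n[1] <= 12) {
    # fixed-width fast path (hexamers and repeat blocks)
    cols <- lapply(rev(seq_len(n[1])), function(i) substring(comp, i, i))
    return(do.call(paste0, cols))
  }
  vapply(strsplit(comp, NULL), function(s) paste(rev(s), collapse = ""),
         character(1))
}

.check_dna <- function(sequence) {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", sequence)
  if (any(bad)) {
    stop("sequence contains non-IUPAC characters: ",
         paste(utils::head(names(sequence)[bad], 5), collapse = ", "))
  }
  invisible(TRUE)
}

#' Scan a promoter sequence for TGTCNN hexamer occurrences
#'
#' Finds every complete 6-mer footprint whose first four bases are the core
#' (`TGTC` by default), on either strand. A minus-strand occurrence is a
#' position where the reverse complement of the 6-mer footprint starts with
#' the core (i.e. `NNGACA` on the given strand); it is reported at the
#' footprint's left edge with the hexamer written core-first. Overlapping
#' occurrences are all reported; ambiguity codes (`N` etc.) never match.
#'
#' @param sequence A single uppercase DNA string, or a named character vector
#'   of promoter sequences (one element per gene).
#' @param core The 4-base core (default `"TGTC"`).
#' @return A data.frame with columns `gene_id`, `offset` (0-based left edge of
#'   the 6-mer footprint), `strand_rel` (`"+"`/`"-"`) and `hexamer` (always
#'   written core-first), sorted by gene then offset.
#' @examples
#' scan_hexamers(c(p1 = "TGTCGGAT"))
#' scan_hexamers(c(p1 = "CCGACA"))   # minus-strand TGTCGG
#' @export
scan_hexamers <- function(sequence, core = "TGTC") {
  stopifnot(is.character(sequence), nchar(core) == 4)
  if (is.null(names(sequence))) {
    names(sequence) <- if (length(sequence) == 1) "seq1" else
      paste0("seq", seq_along(sequence))
  }
  .check_dna(sequence)
  core_rc <- .revcomp(core)
  len <- nchar(sequence)

  hit_list <- function(pattern) {
    m <- gregexpr(pattern, sequence, fixed = TRUE)
    lapply(m, function(p) if (p[1] == -1L) integer(0) else as.integer(p))
  }
  # core has no self-overlap, so fixed non-overlapping search finds all hits
  plus <- hit_list(core)        # 1-based core start; footprint = core + 2
  minus <- hit_list(core_rc)    # 1-based rc-core start; footprint starts 2 left

  # flatten to one vectorized pass over all sequences
  plus <- mapply(function(p, l) p[p + 5L <= l], plus, len, SIMPLIFY = FALSE)
  minus <- mapply(function(q, l) q[q >= 3L & q + 3L <= l], minus, len,
                  SIMPLIFY = FALSE)
  np <- lengths(plus); nm <- lengths(minus)
  seq_idx <- c(rep(seq_along(sequence), np), rep(seq_along(sequence), nm))
  off <- c(unlist(plus, use.names = FALSE) - 1L,
           unlist(minus, use.names = FALSE) - 3L)
  strand <- rep(c("+", "-"), c(sum(np), sum(nm)))
  if (!length(off)) {
    return(data.frame(gene_id = character(), offset = integer(),
                      strand_rel = character(), hexamer = character(),
                      stringsAsFactors = FALSE))
  }
  foot <- substring(sequence[seq_idx], off + 1L, off + 6L)
  hex <- foot
  is_minus <- strand == "-"
  if (any(is_minus)) hex[is_minus] <- .revcomp(foot[is_minus])
  ord <- order(seq_idx, off, strand)
  out <- data.frame(
    gene_id = names(sequence)[seq_idx][ord], offset = off[ord],
    strand_rel = strand[ord], hexamer = hex[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-sided Fisher exact enrichment of gene counts
#'
#' Exact hypergeometric tail probability of observing at least `fg_with`
#' motif-bearing genes when drawing `fg_total` genes from the pooled
#' foreground + background population. This is the one-sided
#' ("greater") Fisher exact test on the 2x2 gene-count table.
#'
#' @param fg_with,fg_total Motif-bearing and total foreground gene counts.
#' @param bg_with,bg_total Same for the background. All arguments vectorised.
#' @param alternative `"greater"` (over-representation, default) or `"less"`.
#' @return p-value(s) in (0, 1].
#' @examples
#' fisher_exact_enrichment(8, 10, 20, 100)
#' @export
fisher_exact_enrichment <- function(fg_with, fg_total, bg_with, bg_total,
                                    alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(fg_with >= 0, bg_with >= 0, fg_with <= fg_total,
            bg_with <= bg_total)
  if (any(fg_total == 0) || any(bg_total == 0)) {
    stop("fg_total and bg_total must be positive")
  }
  N <- fg_total + bg_total
  K <- fg_with + bg_with
  if (alternative == "greater") {
    p <- stats::phyper(fg_with - 1, K, N - K, fg_total, lower.tail = FALSE)
  } else {
    p <- stats::phyper(fg_with, K, N - K, fg_total, lower.tail = TRUE)
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

.as_promoter_seqs <- function(x) {
  if (inherits(x, "promoter_windows")) {
    return(stats::setNames(x$sequence, x$gene_id))
  }
  if (inherits(x, "DNAStringSet")) {
    return(stats::setNames(toupper(as.character(x)), names(x)))
  }
  if (is.character(x) && length(x) == 0) return(stats::setNames(x, x))
  if (is.character(x) && !is.null(names(x))) return(toupper(x))
  stop("promoters must be a promoter_windows object, DNAStringSet, ",
       "or named character vector")
}

.new_enrichment_table <- function(df) {
  df$fg_fraction <- df$fg_with / df$fg_total
  df$bg_fraction <- df$bg_with / df$bg_total
  df$p_value <- fisher_exact_enrichment(df$fg_with, df$fg_total,
                                        df$bg_with, df$bg_total)
  df$q_value <- stats::p.adjust(df$p_value, method = "BH")
  df$neg_log10_p <- -log10(df$p_value)
  df <- df[order(df$p_value, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("enrichment_table", "data.frame")
  df
}

#' Gene-level enrichment of the 16 TGTCNN hexamers
#'
#' For each of the 16 dinucleotide completions of the core, counts foreground
#' and background genes carrying at least one occurrence on either strand and
#' tests over-representation with a one-sided Fisher exact test. Raw
#' p-values are reported alongside Benjamini-Hochberg q-values.
#'
#' @param fg_promoters,bg_promoters Foreground / background promoter sets: a
#'   `promoter_windows` object, `DNAStringSet` or named character vector.
#'   Gene ids must be disjoint between the two sets.
#' @param core The 4-base core (default `"TGTC"`).
#' @return An `enrichment_table` data.frame (one row per hexamer, sorted by
#'   p): `feature`, `fg_with`, `fg_total`, `bg_with`, `bg_total`,
#'   `fg_fraction`, `bg_fraction`, `p_value`, `q_value`, `neg_log10_p`.
#' @export
hexamer_enrichment_table <- function(fg_promoters, bg_promoters,
                                     core = "TGTC") {
  fg <- .as_promoter_seqs(fg_promoters)
  bg <- .as_promoter_seqs(bg_promoters)
  if (length(fg) == 0) stop("empty foreground set")
  shared <- intersect(names(fg), names(bg))
  if (length(shared)) {
    stop("gene(s) in both foreground and background: ",
         paste(utils::head(shared, 5), collapse = ", "))
  }
  nn <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0))
  hexamers <- paste0(core, nn)

  count_with <- function(seqs) {
    occ <- scan_hexamers(seqs, core = core)
    tab <- table(factor(occ$hexamer[!duplicated(occ[c("gene_id", "hexamer")])],
                        levels = hexamers))
    as.integer(tab)
  }
  .new_enrichment_table(data.frame(
    feature = hexamers,
    fg_with = count_with(fg), fg_total = length(fg),
    bg_with = count_with(bg), bg_total = length(bg),
    stringsAsFactors = FALSE))
}

#' Classify spaced hexamer repeats (DR/IR/ER) in a promoter
#'
#' Takes the hexamer occurrences of one or more genes and reports, per gene,
#' the distinct (orientation, spacer) repeat configurations present. For
#' every ordered pair of non-overlapping occurrences (left footprint entirely
#' before the right), the spacer is the gap between the two 6-mer footprints;
#' the pair is kept when `min_spacer <= spacer <= max_spacer`. Orientation is
#' `DR` (direct) when both occurrences are on the same strand, `IR`
#' (inverted, convergent cores) for `+` then `-`, and `ER` (everted,
#' divergent cores) for `-` then `+`.
#'
#' @param occurrences Either a data.frame from [scan_hexamers()] (may span
#'   several genes) or a sequence input accepted by [scan_hexamers()], which
#'   is then scanned first.
#' @param min_spacer,max_spacer Spacer bounds in bp (defaults 0 and 25).
#' @return A data.frame with columns `gene_id`, `orientation`, `spacer` and
#'   `n_pairs` (pair multiplicity; presence is one row regardless of
#'   multiplicity).
#' @examples
#' scan_repeat_configurations(c(g = "TGTCGGAAATGTCGG"))  # (DR, 3)
#' @export
scan_repeat_configurations <- function(occurrences, min_spacer = 0,
                                       max_spacer = 25) {
  stopifnot(min_spacer >= 0, max_spacer >= min_spacer)
  if (!is.data.frame(occurrences)) {
    occurrences <- scan_hexamers(occurrences)
  }
  if (nrow(occurrences) == 0) {
    return(data.frame(gene_id = character(), orientation = character(),
                      spacer = integer(), n_pairs = integer(),
                      stringsAsFactors = FALSE))
  }
  # all within-gene ordered pairs, vectorized across genes
  occurrences <- occurrences[order(occurrences$gene_id,
                                   occurrences$offset), , drop = FALSE]
  gene <- occurrences$gene_id
  n_per <- as.integer(table(factor(gene, levels = unique(gene))))
  base <- rep(cumsum(c(0L, n_per[-length(n_per)])), n_per^2)
  i <- base + unlist(lapply(n_per, function(k) rep(seq_len(k), each = k)),
                     use.names = FALSE)
  j <- base + unlist(lapply(n_per, function(k) rep.int(seq_len(k), k)),
                     use.names = FALSE)
  spacer <- occurrences$offset[j] - (occurrences$offset[i] + 6L)
  keep <- spacer >= min_spacer & spacer <= max_spacer
  if (!any(keep)) {
    return(data.frame(gene_id = character(), orientation = character(),
                      spacer = integer(), n_pairs = integer(),
                      stringsAsFactors = FALSE))
  }
  i <- i[keep]; j <- j[keep]; spacer <- spacer[keep]
  sl <- occurrences$strand_rel[i]; sr <- occurrences$strand_rel[j]
  orientation <- ifelse(sl == sr, "DR", ifelse(sl == "+", "IR", "ER"))
  key <- paste0(gene[i], "\r", orientation, "\r", spacer)
  first <- !duplicated(key)
  out <- data.frame(gene_id = gene[i][first],
                    orientation = orientation[first],
                    spacer = spacer[first],
                    n_pairs = tabulate(match(key, key[first]),
                                       nbins = sum(first)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$orientation, out$spacer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-level enrichment of repeat configurations
#'
#' For every consensus-level (orientation, spacer) configuration — 3
#' orientations x 26 spacers = 78 for the defaults — counts foreground and
#' background genes containing at least one such repeat pair and tests
#' over-representation with a one-sided Fisher exact test. A gene is "with" a
#' configuration on presence; pair multiplicity does not enter the test.
#'
#' @inheritParams hexamer_enrichment_table
#' @inheritParams scan_repeat_configurations
#' @return An `enrichment_table` data.frame with one row per configuration
#'   (`feature` is `"<orientation>_<spacer>"`; `orientation` and `spacer`
#'   also given as columns), sorted by p.
#' @export
repeat_enrichment_table <- function(fg_promoters, bg_promoters,
                                    min_spacer = 0, max_spacer = 25,
                                    core = "TGTC") {
  fg <- .as_promoter_seqs(fg_promoters)
  bg <- .as_promoter_seqs(bg_promoters)
  if (length(fg) == 0) stop("empty foreground set")
  shared <- intersect(names(fg), names(bg))
  if (length(shared)) {
    stop("gene(s) in both foreground and background: ",
         paste(utils::head(shared, 5), collapse = ", "))
  }
  spacers <- seq.int(min_spacer, max_spacer)
  universe <- expand.grid(orientation = c("DR", "ER", "IR"), spacer = spacers,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  universe <- universe[order(universe$orientation, universe$spacer), ]
  key <- function(o, s) paste0(o, "_", s)

  count_with <- function(seqs) {
    cfg <- scan_repeat_configurations(scan_hexamers(seqs, core = core),
                                      min_spacer, max_spacer)
    tab <- table(factor(key(cfg$orientation, cfg$spacer),
                        levels = key(universe$orientation, universe$spacer)))
    as.integer(tab)
  }
  df <- data.frame(
    feature = key(universe$orientation, universe$spacer),
    orientation = universe$orientation, spacer = universe$spacer,
    fg_with = count_with(fg), fg_total = length(fg),
    bg_with = count_with(bg), bg_total = length(bg),
    stringsAsFactors = FALSE)
  .new_enrichment_table(df)
}

#' @export
print.enrichment_table <- function(x, n = 10, ...) {
  cat("Gene-level Fisher enrichment: ", nrow(x), " feature(s), ",
      x$fg_total[1], " foreground vs ", x$bg_total[1],
      " background genes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), digits = 4, ...)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}
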