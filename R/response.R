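## Differential-expression response profiling: DEG classification, direction
## dominance, amplitude decomposition, rank-sum testing, z-score scaling.

#' Classify genes of a DE table as up, down or non-significant
#'
#' A gene is `up` when `padj < alpha` and `log2fc > lfc_threshold`, `down`
#' when `padj < alpha` and `log2fc < -lfc_threshold`, and `ns` otherwise
#' (missing `padj` is `ns`). The default thresholds correspond to the usual
#' `padj < 0.05` DEG call; setting `lfc_threshold = log2(1.25)` gives the
#' non-stringent fold-change>1.25 style filter.
#'
#' @param table A data.frame with at least `gene_id`, `log2fc`, `padj`.
#' @param alpha Adjusted-p cutoff in (0, 1); default 0.05.
#' @param lfc_threshold Non-negative absolute log2 fold-change cutoff
#'   (default 0).
#' @return `table` with an added factor column `deg_class` with levels
#'   `up`, `down`, `ns`.
#' @export
classify_degs <- function(table, alpha = 0.05, lfc_threshold = 0) {
  stopifnot(is.data.frame(table),
            all(c("gene_id", "log2fc", "padj") %in% names(table)),
            alpha > 0, alpha < 1, lfc_threshold >= 0)
  if (anyDuplicated(table$gene_id)) stop("gene_id must be unique")
  ok <- !is.na(table$padj) & table$padj < alpha
  cls <- rep("ns", nrow(table))
  cls[ok & table$log2fc > lfc_threshold] <- "up"
  cls[ok & table$log2fc < -lfc_threshold] <- "down"
  table$deg_class <- factor(cls, levels = c("up", "down", "ns"))
  table
}

#' Summarise the direction and amplitude of a DEG set
#'
#' Computes the activation:repression balance (up/down counts and fraction),
#' the mean log2 fold change of all DEGs, and a fixed-width histogram of DEG
#' log2 fold changes (the density-histogram view of a response profile).
#'
#' @param degs A table from [classify_degs()] (rows with `deg_class` of `up`
#'   or `down` are the DEGs), or any data.frame with `log2fc` and
#'   `deg_class`.
#' @param binwidth Histogram bin width in log2 units (default 0.25).
#' @return An object of class `response_profile`: `n_up`, `n_down`,
#'   `up_fraction`, `ratio` (a `"n_up:n_down"` string), `mean_l2fc`,
#'   `histogram` (data.frame `bin_left`, `bin_right`, `count`).
#' @export
response_summary <- function(degs, binwidth = 0.25) {
  stopifnot(is.data.frame(degs), "deg_class" %in% names(degs))
  lfc <- degs$log2fc[degs$deg_class %in% c("up", "down")]
  cls <- degs$deg_class[degs$deg_class %in% c("up", "down")]
  if (length(lfc) == 0) stop("empty DEG set")
  n_up <- sum(cls == "up")
  n_down <- sum(cls == "down")
  edges <- seq(floor(min(lfc) / binwidth) * binwidth,
               ceiling(max(lfc) / binwidth) * binwidth + binwidth,
               by = binwidth)
  counts <- as.integer(table(cut(lfc, edges, right = FALSE,
                                 include.lowest = FALSE)))
  out <- list(
    n_up = n_up, n_down = n_down,
    up_fraction = n_up / (n_up + n_down),
    ratio = paste0(n_up, ":", n_down),
    mean_l2fc = mean(lfc),
    histogram = data.frame(bin_left = edges[-length(edges)],
                           bin_right = edges[-1], count = counts))
  class(out) <- "response_profile"
  out
}

#' @export
print.response_profile <- function(x, ...) {
  cat("Auxin response profile\n")
  cat("  DEGs: ", x$n_up + x$n_down, " (", x$ratio, " up:down, up fraction ",
      sprintf("%.3f", x$up_fraction), ")\n", sep = "")
  cat("  mean log2FC: ", sprintf("%.3f", x$mean_l2fc), "\n", sep = "")
  invisible(x)
}

#' Top-k / bottom-k amplitude decomposition of a DEG direction
#'
#' Ranks the DEGs of one direction by absolute log2 fold change, takes the
#' `k` strongest (`top_genes`) and `k` weakest (`bottom_genes`) responders,
#' and contrasts their normalized expression under mock and treatment: group
#' means plus a two-sample rank-sum test (top vs bottom) for each condition.
#' High amplitude arising from low mock expression (efficient repression
#' without auxin) shows up as a low top-group mock mean at similar treated
#' means.
#'
#' @param table A table from [classify_degs()] with columns
#'   `norm_expr_mock` and `norm_expr_treated` (log2-scale normalized
#'   expression).
#' @param k Group size (default 20). Clamped with a warning when fewer than
#'   `2k` DEGs are available in the direction.
#' @param direction `"up"` (default) or `"down"`.
#' @param alternative Alternative for the rank tests (default two-sided).
#' @return An object of class `amplitude_decomposition`: `k`, `direction`,
#'   `top_genes`, `bottom_genes`, `genes` (per-gene table), `mock_mean_top`,
#'   `mock_mean_bottom`, `treated_mean_top`, `treated_mean_bottom`,
#'   `mock_p`, `treated_p`.
#' @export
amplitude_decomposition <- function(table, k = 20, direction = c("up", "down"),
                                    alternative = "two.sided") {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(table), k >= 1,
            all(c("gene_id", "log2fc", "deg_class", "norm_expr_mock",
                  "norm_expr_treated") %in% names(table)))
  d <- table[table$deg_class == direction, , drop = FALSE]
  if (nrow(d) == 0) stop("no DEGs in direction '", direction, "'")
  if (nrow(d) < 2 * k) {
    k <- min(k, nrow(d))
    warning("k clamped to ", k, " (only ", nrow(d), " '", direction,
            "' DEGs; top and bottom groups overlap)")
  }
  ord <- order(-abs(d$log2fc), d$gene_id)
  top <- d[ord[seq_len(k)], , drop = FALSE]
  bottom <- d[rev(ord)[seq_len(k)], , drop = FALSE]

  out <- list(
    k = k, direction = direction,
    top_genes = top$gene_id, bottom_genes = bottom$gene_id,
    genes = rbind(cbind(top, group = "top"), cbind(bottom, group = "bottom")),
    mock_mean_top = mean(top$norm_expr_mock),
    mock_mean_bottom = mean(bottom$norm_expr_mock),
    treated_mean_top = mean(top$norm_expr_treated),
    treated_mean_bottom = mean(bottom$norm_expr_treated),
    mock_p = rank_sum_test(top$norm_expr_mock, bottom$norm_expr_mock,
                           alternative)$p_value,
    treated_p = rank_sum_test(top$norm_expr_treated,
                              bottom$norm_expr_treated,
                              alternative)$p_value)
  class(out) <- "amplitude_decomposition"
  out
}

#' @export
print.amplitude_decomposition <- function(x, ...) {
  cat("Amplitude decomposition (", x$direction, "-regulated, k = ", x$k,
      ")\n", sep = "")
  cat(sprintf("  mock:    top %.3f vs bottom %.3f (rank-sum p = %.3g)\n",
              x$mock_mean_top, x$mock_mean_bottom, x$mock_p))
  cat(sprintf("  treated: top %.3f vs bottom %.3f (rank-sum p = %.3g)\n",
              x$treated_mean_top, x$treated_mean_bottom, x$treated_p))
  invisible(x)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact p by full enumeration of rank assignments (with tie-corrected
#' mid-ranks) when `n_a + n_b <= exact_max_n`; otherwise the normal
#' approximation with continuity and tie correction. One-sided `"less"`
#' means `a` is shifted low relative to `b`.
#'
#' @param a,b Numeric samples (non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param exact_max_n Largest combined size for the enumeration branch
#'   (default 12).
#' @return A list of class `rank_sum_test`: `statistic` (rank sum of `a`),
#'   `p_value`, `method` (`"exact"` or `"normal"`), `alternative`.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4), "less")$p_value  # 1/6
#' @export
rank_sum_test <- function(a, b,
                          alternative = c("two.sided", "less", "greater"),
                          exact_max_n = 12) {
  alternative <- match.arg(alternative)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  w <- sum(r[seq_len(na)])

  if (n <= exact_max_n) {
    sets <- utils::combn(n, na)
    ws <- colSums(matrix(r[sets], nrow = na))
    eps <- 1e-9
    p_le <- mean(ws <= w + eps)
    p_ge <- mean(ws >= w - eps)
    p <- switch(alternative,
                less = p_le, greater = p_ge,
                two.sided = min(1, 2 * min(p_le, p_ge)))
    method <- "exact"
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z_le <- (w - mu + 0.5) / sqrt(sigma2)
      z_ge <- (w - mu - 0.5) / sqrt(sigma2)
      p_le <- stats::pnorm(z_le)
      p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
      p <- switch(alternative,
                  less = p_le, greater = p_ge,
                  two.sided = min(1, 2 * min(p_le, p_ge)))
    }
    method <- "normal"
  }
  structure(list(statistic = w, p_value = p, method = method,
                 alternative = alternative),
            class = "rank_sum_test")
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat("Wilcoxon rank-sum test (", x$method, "), ", x$alternative,
      ": W = ", x$statistic, ", p = ", format(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Z-score normalize an expression matrix
#'
#' Scales each gene (row) to mean 0, sample standard deviation (n-1) 1 — the
#' usual per-gene z-score applied to TPM matrices before heatmap display.
#' Constant rows map to all zeros.
#'
#' @param expression_matrix Numeric matrix (genes x samples).
#' @param axis `"gene"` (rows, default) or `"sample"` (columns).
#' @return Matrix of the same shape.
#' @export
zscore_normalize <- function(expression_matrix, axis = c("gene", "sample")) {
  axis <- match.arg(axis)
  m <- as.matrix(expression_matrix)
  if (axis == "sample") return(t(zscore_normalize(t(m), "gene")))
  if (ncol(m) < 2) stop("each normalized row needs >= 2 values")
  mu <- rowMeans(m)
  s <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Read a DE results table from TSV
#'
#' Reads a tab-separated DE results file and standardises the column names
#' the profiling functions expect.
#'
#' @param path TSV path with a header.
#' @param gene_id,log2fc,padj,norm_expr_mock,norm_expr_treated Column names
#'   in the file (defaults follow the common DESeq2 export:
#'   `gene_id`, `log2FoldChange`, `padj`, plus the two per-condition
#'   normalized-expression columns).
#' @return A data.frame with columns `gene_id`, `log2fc`, `padj`,
#'   `norm_expr_mock`, `norm_expr_treated`.
#' @export
read_deg_table <- function(path, gene_id = "gene_id",
                           log2fc = "log2FoldChange", padj = "padj",
                           norm_expr_mock = "norm_expr_mock",
                           norm_expr_treated = "norm_expr_treated") {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- c(gene_id, log2fc, padj, norm_expr_mock, norm_expr_treated)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  }
  out <- raw[cols]
  names(out) <- c("gene_id", "log2fc", "padj", "norm_expr_mock",
                  "norm_expr_treated")
  out
}
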