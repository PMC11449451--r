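## Vein-network indices with the two-stage F-then-t comparison, and
## nuclear-intensity quantification for ploidy inference.

#' Vein-network indices from feature-point counts
#'
#' Computes, per leaf, the operational vein-network indices from counts of
#' the four feature-point types (touch `T`, end `E`, break `B`, exit `X`):
#'
#' * `cardinality_abs = T + E + B + X` — total feature points, a proxy for
#'   the amount of venation;
#' * `connectivity = T / (T + E + X)` — fraction of non-break points that are
#'   vein-vein contacts (0 when the denominator is 0);
#' * `continuity = 1 - B / (T + E + B + X)` — fraction of points that are not
#'   breaks.
#'
#' When per-index control means are supplied, relative indices (index divided
#' by the control-group mean) are added so different experiments can be
#' pooled.
#'
#' @param counts A data.frame with columns `leaf_id`, `T`, `E`, `B`, `X`
#'   (non-negative integers; a row of all zeros is an error).
#' @param control_stats Optional named numeric vector with elements
#'   `cardinality_abs`, `connectivity`, `continuity` — the control-group
#'   means used for the relative indices.
#' @return `counts` with added columns `cardinality_abs`, `connectivity`,
#'   `continuity` (and `rel_*` variants when `control_stats` is given).
#' @examples
#' vein_indices(data.frame(leaf_id = "l1", T = 10, E = 5, B = 2, X = 3))
#' @export
vein_indices <- function(counts, control_stats = NULL) {
  stopifnot(is.data.frame(counts),
            all(c("leaf_id", "T", "E", "B", "X") %in% names(counts)))
  cnt <- as.matrix(counts[c("T", "E", "B", "X")])
  if (any(cnt < 0)) stop("negative feature-point counts")
  card <- rowSums(cnt)
  if (any(card == 0)) {
    stop("all-zero counts for leaf: ",
         paste(counts$leaf_id[card == 0], collapse = ", "))
  }
  denom <- cnt[, "T"] + cnt[, "E"] + cnt[, "X"]
  counts$cardinality_abs <- card
  counts$connectivity <- ifelse(denom == 0, 0, cnt[, "T"] / denom)
  counts$continuity <- 1 - cnt[, "B"] / card
  if (!is.null(control_stats)) {
    for (idx in c("cardinality_abs", "connectivity", "continuity")) {
      if (is.na(control_stats[idx]) || control_stats[idx] == 0) {
        stop("invalid control mean for ", idx)
      }
      counts[[paste0("rel_", idx)]] <- counts[[idx]] / control_stats[idx]
    }
  }
  counts
}

#' Two-stage comparison of an index between groups
#'
#' The classical venation-statistics recipe: first test equality of
#' variances with a two-sided F test; if its p-value is at least
#' `alpha_var`, compare means with a pooled-variance two-sample Student
#' t-test, otherwise with the unequal-variance (Welch) t-test.
#'
#' @param group_a,group_b Numeric vectors of per-leaf index values
#'   (each `n >= 2`).
#' @param alpha_var F-test significance cutoff deciding the t flavor
#'   (default 0.05).
#' @param alternative Passed to [stats::t.test()] (default two-sided).
#' @return An object of class `group_comparison`: `variance_test_p`,
#'   `mean_test_p`, `test_flavor` (`"pooled-variance"` or
#'   `"unequal-variance"`), `mean_a`, `mean_b`, `df`.
#' @export
compare_index_groups <- function(group_a, group_b, alpha_var = 0.05,
                                 alternative = "two.sided") {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs n >= 2")
  }
  f <- stats::var.test(group_a, group_b, alternative = "two.sided")
  pooled <- f$p.value >= alpha_var
  tt <- stats::t.test(group_a, group_b, var.equal = pooled,
                      alternative = alternative)
  structure(list(
    variance_test_p = min(f$p.value, 1),
    mean_test_p = tt$p.value,
    test_flavor = if (pooled) "pooled-variance" else "unequal-variance",
    mean_a = mean(group_a), mean_b = mean(group_b),
    df = unname(tt$parameter)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("F-then-t group comparison\n")
  cat(sprintf("  F test (equal variances): p = %.4g -> %s t-test\n",
              x$variance_test_p, x$test_flavor))
  cat(sprintf("  means %.4g vs %.4g, t-test p = %.4g (df = %.2f)\n",
              x$mean_a, x$mean_b, x$mean_test_p, x$df))
  invisible(x)
}

#' Segment nuclei from a greyscale image
#'
#' Binarizes the image (Otsu threshold by default), labels connected
#' components of the foreground at the given pixel connectivity, discards
#' components smaller than `min_area` pixels, and measures each surviving
#' region's mean intensity on the original image.
#'
#' @param image A numeric matrix of non-negative intensities (rows x
#'   columns), or a path to a greyscale TIFF/PNG.
#' @param threshold `"otsu"` (default) or a fixed numeric threshold; pixels
#'   strictly above it are foreground.
#' @param min_area Minimum component area in pixels (default 30; components
#'   with `area < min_area` are discarded).
#' @param connectivity 4 (default) or 8.
#' @return A data.frame of class `nucleus_rois`: `label`, `area`,
#'   `mean_intensity`, `centroid_row`, `centroid_col`.
#' @export
segment_nuclei <- function(image, threshold = "otsu", min_area = 30,
                           connectivity = 4) {
  img <- .as_grey_matrix(image)
  if (any(img < 0)) stop("negative intensities")
  if (diff(range(img)) == 0) stop("no foreground (constant image)")
  thr <- if (identical(threshold, "otsu")) .otsu_threshold(img) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1)
    threshold
  }
  mask <- img > thr
  if (!any(mask)) {
    # a user-supplied threshold above every pixel is a legal empty result
    out <- data.frame(label = integer(), area = integer(),
                      mean_intensity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
    class(out) <- c("nucleus_rois", "data.frame")
    return(out)
  }

  lab <- EBImage::bwlabel(mask + 0)        # 4-connected labeling
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(img))
  if (connectivity == 8) {
    lab <- .merge_diagonal_labels(lab)
  } else if (connectivity != 4) {
    stop("connectivity must be 4 or 8")
  }

  idx <- which(lab > 0)
  lbl <- lab[idx]
  area <- tabulate(lbl)
  keep <- which(area >= min_area)
  if (length(keep) == 0) {
    out <- data.frame(label = integer(), area = integer(),
                      mean_intensity = numeric(), centroid_row = numeric(),
                      centroid_col = numeric())
    class(out) <- c("nucleus_rois", "data.frame")
    return(out)
  }
  rows <- (idx - 1L) %% nrow(img) + 1L
  cols <- (idx - 1L) %/% nrow(img) + 1L
  sum_int <- rowsum(img[idx], lbl)[, 1]
  sum_r <- rowsum(as.numeric(rows), lbl)[, 1]
  sum_c <- rowsum(as.numeric(cols), lbl)[, 1]
  present <- sort(unique(lbl))
  area_p <- area[present]
  out <- data.frame(
    label = present, area = area_p,
    mean_intensity = sum_int / area_p,
    centroid_row = sum_r / area_p,
    centroid_col = sum_c / area_p)
  out <- out[out$area >= min_area, , drop = FALSE]
  out$label <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("nucleus_rois", "data.frame")
  out
}

.as_grey_matrix <- function(image) {
  if (is.matrix(image) && is.numeric(image)) return(image)
  if (is.character(image) && length(image) == 1) {
    img <- EBImage::imageData(EBImage::readImage(image))
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(t(img))                          # EBImage stores x (col) first
  }
  stop("image must be a numeric matrix or a TIFF/PNG path")
}

# Otsu threshold on a 256-bin histogram (maximizes between-class variance)
.otsu_threshold <- function(img) {
  r <- range(img)
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- as.numeric(tabulate(findInterval(img, breaks, all.inside = TRUE),
                           nbins = 256))
  w <- cumsum(h)
  m <- cumsum(h * seq_len(256))
  total_w <- w[256]; total_m <- m[256]
  w0 <- w[-256]; w1 <- total_w - w0
  m0 <- m[-256] / pmax(w0, 1)
  m1 <- (total_m - m[-256]) / pmax(w1, 1)
  between <- w0 * w1 * (m0 - m1)^2
  between[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(between)
  breaks[k + 1]
}

# promote a 4-connected labeling to 8-connectivity by merging labels that
# touch diagonally (small union-find over diagonal neighbor pairs)
.merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]     # down-right diagonal
  c1 <- lab[-1, -nc]; d <- lab[-nr, -1]    # up-right diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  lab[lab > 0] <- root[lab[lab > 0]]
  lab
}

#' Compare nuclear intensities between two ROI groups
#'
#' Summarises two segmented nucleus sets (e.g. putative diploid vs haploid
#' tissue) by their median mean-intensity, the ratio of group b over group a,
#' and a two-sided rank-sum test. A ratio near 2 at similar nuclear sizes is
#' the expected signature of a genome doubling.
#'
#' @param rois_a,rois_b `nucleus_rois` data.frames from [segment_nuclei()]
#'   (each with at least 3 ROIs).
#' @return An object of class `intensity_summary`: `median_a`, `median_b`,
#'   `ratio` (`median_b / median_a`), `p_value`, `n_a`, `n_b`.
#' @export
nuclear_intensity_summary <- function(rois_a, rois_b) {
  if (nrow(rois_a) < 3 || nrow(rois_b) < 3) {
    stop("each group needs >= 3 ROIs")
  }
  a <- rois_a$mean_intensity; b <- rois_b$mean_intensity
  structure(list(
    median_a = stats::median(a), median_b = stats::median(b),
    ratio = stats::median(b) / stats::median(a),
    p_value = rank_sum_test(a, b, "two.sided")$p_value,
    n_a = length(a), n_b = length(b)),
    class = "intensity_summary")
}

#' @export
print.intensity_summary <- function(x, ...) {
  cat("Nuclear intensity summary\n")
  cat(sprintf("  medians: %.3f (n=%d) vs %.3f (n=%d), ratio b/a = %.3f\n",
              x$median_a, x$n_a, x$median_b, x$n_b, x$ratio))
  cat("  rank-sum p = ", format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}
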