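## Orthogroup-space set overlap: parse OrthoFinder-style tables, map
## per-species gene sets to orthogroups, hypergeometric overlap enrichment.

#' Parse an orthogroup membership table
#'
#' Reads the OrthoFinder-style TSV dialect: first column the orthogroup id,
#' one column per species, cells holding comma-separated gene/protein ids
#' (empty cell = no member). Whitespace around ids is tolerated. A gene id
#' occurring in more than one orthogroup for the same species keeps its
#' first assignment (with a warning).
#'
#' @param path TSV path with a header row naming the species columns.
#' @return An object of class `orthogroup_table`: a long data.frame with
#'   columns `orthogroup`, `species`, `gene_id`, plus attributes `species`
#'   (column order) and `orthogroups` (all ids, including empty ones).
#' @export
parse_orthogroups <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty orthogroup table: ", path)
  ntab <- vapply(gregexpr("\t", lines, fixed = TRUE), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  if (any(ntab != ntab[1])) {
    bad <- which(ntab != ntab[1])[1]
    stop("ragged orthogroup table row at line ", bad, " (", ntab[bad] + 1,
         " fields, expected ", ntab[1] + 1, ")")
  }
  ncol_exp <- ntab[1] + 1L
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # strsplit drops trailing empty cells; pad them back
  fields <- lapply(fields, function(f) c(f, rep("", ncol_exp - length(f))))
  header <- fields[[1]]
  species <- header[-1]
  if (length(species) == 0) stop("orthogroup table needs >= 1 species column")
  rows <- fields[-1]
  og_ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(og_ids)) {
    stop("duplicate orthogroup id: ", og_ids[duplicated(og_ids)][1])
  }

  long <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][-1]
    ids <- lapply(cells, function(cell) {
      if (!nzchar(trimws(cell))) return(character(0))
      trimws(strsplit(cell, ",", fixed = TRUE)[[1]])
    })
    nper <- lengths(ids)
    if (sum(nper) == 0) next
    long[[i]] <- data.frame(
      orthogroup = og_ids[i],
      species = rep(species, nper),
      gene_id = unlist(ids, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, long)
  if (is.null(out)) {
    out <- data.frame(orthogroup = character(), species = character(),
                      gene_id = character(), stringsAsFactors = FALSE)
  }
  dup <- duplicated(out[c("species", "gene_id")])
  if (any(dup)) {
    warning(sum(dup), " gene id(s) listed in multiple orthogroups; ",
            "keeping first assignment (e.g. ", out$gene_id[dup][1], ")")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "species") <- species
  attr(out, "orthogroups") <- og_ids
  class(out) <- c("orthogroup_table", "data.frame")
  out
}

#' Map a gene/protein id set to orthogroup space
#'
#' @param id_set Character vector of gene or protein ids.
#' @param species Species name (must be a column of the table).
#' @param table An `orthogroup_table` from [parse_orthogroups()].
#' @return A list with `orthogroups` (distinct orthogroups containing at
#'   least one input id for that species) and `unmapped` (ids not present in
#'   any orthogroup of that species).
#' @export
map_set_to_orthogroups <- function(id_set, species, table) {
  stopifnot(inherits(table, "orthogroup_table"))
  if (!species %in% attr(table, "species")) {
    stop("unknown species '", species, "'; table has: ",
         paste(attr(table, "species"), collapse = ", "))
  }
  id_set <- unique(id_set)
  sub <- table[table$species == species, , drop = FALSE]
  hit <- match(id_set, sub$gene_id)
  list(orthogroups = unique(sub$orthogroup[hit[!is.na(hit)]]),
       unmapped = id_set[is.na(hit)])
}

#' Hypergeometric overlap enrichment of two sets
#'
#' Tests whether two sets (typically orthogroup sets of auxin-responsive
#' genes from two species) overlap more than expected by chance inside a
#' shared universe: exact upper-tail hypergeometric p of observing at least
#' the observed overlap.
#'
#' @param set_a,set_b Character vectors; must be subsets of `universe`.
#' @param universe Character vector, the shared universe (e.g. orthogroups
#'   represented in both species).
#' @return An object of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `N`, `expected` (`n_a*n_b/N`), `p_value`, `overlap` (the ids).
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("ids outside the universe: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "))
  }
  N <- length(universe)
  n_a <- length(set_a); n_b <- length(set_b)
  ov <- intersect(set_a, set_b)
  k <- length(ov)
  p <- if (k == 0) 1 else
    stats::phyper(k - 1, n_a, N - n_a, n_b, lower.tail = FALSE)
  structure(list(n_a = n_a, n_b = n_b, n_overlap = k, N = N,
                 expected = n_a * n_b / N, p_value = min(p, 1),
                 overlap = ov),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Set overlap in a universe of ", x$N, "\n", sep = "")
  cat(sprintf("  |A| = %d, |B| = %d, overlap = %d (expected %.2f)\n",
              x$n_a, x$n_b, x$n_overlap, x$expected))
  cat("  hypergeometric P[X >= overlap] = ", format(x$p_value, digits = 4),
      "\n", sep = "")
  invisible(x)
}

#' Exclusive multi-set intersection counts (Venn regions)
#'
#' Exact set algebra for up to five named sets: for every non-empty
#' combination of sets, the number of elements belonging to exactly that
#' combination.
#'
#' @param sets Named list of character vectors (2-5 sets).
#' @return A data.frame with one row per region: `combination`
#'   (`&`-joined set names), one logical membership column per set, and
#'   `count`.
#' @export
multi_set_intersections <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, length(sets) <= 5,
            !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, unique)
  elements <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) elements %in% s,
                   logical(length(elements)))
  if (length(elements) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL,
                                                              names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)),
                        KEEP.OUT.ATTRS = FALSE)
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  key <- apply(member, 1, paste, collapse = ",")
  combo_key <- apply(combos, 1, paste, collapse = ",")
  counts <- as.integer(table(factor(key, levels = combo_key)))
  data.frame(
    combination = apply(combos, 1, function(r) {
      paste(names(sets)[as.logical(r)], collapse = "&")
    }),
    combos, count = counts, row.names = NULL, stringsAsFactors = FALSE)
}
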