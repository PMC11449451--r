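## Seeded synthetic-data generators with truth tables. Every generator is a
## pure function of its arguments: one root seed expands to per-component
## child seeds by a fixed derivation, so adding a generator never perturbs
## the outputs of the others.

.child_seed <- function(seed, component) {
  offsets <- c(promoters = 101L, de = 211L, orthogroups = 307L,
               veins = 401L, nuclei = 503L)
  stopifnot(component %in% names(offsets))
  as.integer((as.numeric(seed) * 1009 + offsets[[component]]) %% 2147483647)
}

.random_dna <- function(n, len, gc_content) {
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  chars <- sample(names(p), n * len, replace = TRUE, prob = p)
  big <- paste(chars, collapse = "")
  substring(big, (seq_len(n) - 1) * len + 1, seq_len(n) * len)
}

.random_hexamer <- function(core = "TGTC") {
  paste0(core, paste(sample(c("A", "C", "G", "T"), 2, replace = TRUE),
                     collapse = ""))
}

# splice `insert` into `seq` with its left edge at 0-based `offset`
.plant <- function(seq, insert, offset) {
  paste0(substr(seq, 1, offset),
         insert,
         substr(seq, offset + nchar(insert) + 1, nchar(seq)))
}

.repeat_block <- function(orientation, spacer, gc_content, core = "TGTC") {
  h1 <- .random_hexamer(core)
  h2 <- .random_hexamer(core)
  rc <- .revcomp(c(h1, h2))
  spacer_seq <- if (spacer > 0) {
    paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE,
                 prob = c((1 - gc_content) / 2, gc_content / 2,
                          gc_content / 2, (1 - gc_content) / 2)),
          collapse = "")
  } else ""
  block <- switch(orientation,
                  DR = paste0(h1, spacer_seq, h2),
                  IR = paste0(h1, spacer_seq, rc[2]),
                  ER = paste0(rc[1], spacer_seq, h2),
                  stop("orientation must be DR, IR or ER"))
  list(block = block, hexamers = c(h1, h2))
}

#' Simulate promoter sets with planted TGTCNN features
#'
#' Generates i.i.d. random promoter sequences at a given GC content for a
#' foreground and a background gene set, planting (independently per gene
#' and per feature, with probability `fg_rate` in the foreground and
#' `bg_rate` in the background) a single hexamer and/or a spaced repeat pair
#' at uniformly chosen non-overlapping positions. Planted single hexamers
#' land on a random strand; planted repeats are written at the consensus
#' level (random NN completions) in the requested orientation. Chance
#' (background) motif occurrences are left in place; analyses compare
#' against rate-0 baselines.
#'
#' @param n_fg,n_bg Foreground / background gene counts (defaults 150, 1000).
#' @param promoter_length Sequence length in bp (default 600).
#' @param gc_content GC fraction in (0, 1) (default 0.4).
#' @param planted_hexamer A TGTCNN hexamer to plant, or `NULL` (default
#'   `"TGTCGG"`, the high-affinity ARF-binding element).
#' @param planted_config A `list(orientation =, spacer =)` repeat to plant,
#'   or `NULL` (default `list("DR", 7)`).
#' @param fg_rate,bg_rate Planting probability per feature per gene
#'   (defaults 0.4 and 0.05).
#' @param seed Integer seed.
#' @return A list with `sequences` (named character vector, foreground then
#'   background), `foreground` (gene ids), `background` (gene ids) and
#'   `truth` (data.frame `gene_id`, `feature_type` (`"hexamer"`/`"repeat"`),
#'   `feature`, `offset`).
#' @export
simulate_promoters <- function(n_fg = 150, n_bg = 1000,
                               promoter_length = 600, gc_content = 0.4,
                               planted_hexamer = "TGTCGG",
                               planted_config = list(orientation = "DR",
                                                     spacer = 7),
                               fg_rate = 0.4, bg_rate = 0.05, seed = 1) {
  stopifnot(n_fg >= 1, n_bg >= 0, fg_rate >= 0, fg_rate <= 1,
            bg_rate >= 0, bg_rate <= 1, gc_content > 0, gc_content < 1)
  if (!is.null(planted_config)) {
    names(planted_config) <- c("orientation", "spacer")[seq_along(planted_config)]
    if (promoter_length < 12 + planted_config$spacer) {
      stop("promoter too short for the planted repeat")
    }
  }
  if (!is.null(planted_hexamer) && promoter_length < 6) {
    stop("promoter too short for the planted hexamer")
  }
  set.seed(.child_seed(seed, "promoters"))
  n <- n_fg + n_bg
  ids <- sprintf("g%05d", seq_len(n))
  fg_ids <- ids[seq_len(n_fg)]
  bg_ids <- setdiff(ids, fg_ids)
  seqs <- stats::setNames(.random_dna(n, promoter_length, gc_content), ids)

  truth <- list()
  rates <- c(rep(fg_rate, n_fg), rep(bg_rate, n_bg))
  for (i in seq_len(n)) {
    used <- integer(0)  # occupied footprint positions (0-based)
    if (!is.null(planted_config) && stats::runif(1) < rates[i]) {
      rb <- .repeat_block(planted_config$orientation, planted_config$spacer,
                          gc_content)
      w <- nchar(rb$block)
      off <- sample.int(promoter_length - w + 1L, 1) - 1L
      seqs[i] <- .plant(seqs[i], rb$block, off)
      used <- seq.int(off, off + w - 1L)
      truth[[length(truth) + 1]] <- data.frame(
        gene_id = ids[i], feature_type = "repeat",
        feature = paste0(planted_config$orientation, "_",
                         planted_config$spacer),
        offset = off, stringsAsFactors = FALSE)
    }
    if (!is.null(planted_hexamer) && stats::runif(1) < rates[i]) {
      word <- if (stats::runif(1) < 0.5) planted_hexamer else
        .revcomp(planted_hexamer)
      for (try in 1:50) {
        off <- sample.int(promoter_length - 5L, 1) - 1L
        if (!any(seq.int(off, off + 5L) %in% used)) break
        off <- NA_integer_
      }
      if (!is.na(off)) {
        seqs[i] <- .plant(seqs[i], word, off)
        truth[[length(truth) + 1]] <- data.frame(
          gene_id = ids[i], feature_type = "hexamer",
          feature = planted_hexamer, offset = off, stringsAsFactors = FALSE)
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene_id = character(), feature_type = character(),
               feature = character(), offset = integer(),
               stringsAsFactors = FALSE)
  list(sequences = seqs, foreground = fg_ids, background = bg_ids,
       truth = truth)
}

#' Simulate per-generation differential-expression tables
#'
#' Emulates the response structure of an auxin-treatment RNA-seq contrast in
#' two generations sharing their responsive genes: up-regulated genes have a
#' common per-gene treated level across generations but generation-specific
#' mock (untreated) levels, so the generation with the lower mock mean shows
#' the larger activation amplitude. Adjusted p-values are emulated by
#' drawing per-gene p-values (near zero for responsive genes, uniform for
#' null genes) and applying Benjamini-Hochberg correction; this stands in
#' for a DE fitter, it is not one.
#'
#' All expression values are log2-scale normalized expression; the reported
#' per-condition values are means over `n_replicates` noisy replicates.
#'
#' @param n_genes Total genes (default 10000).
#' @param n_responsive Truly responsive genes (default 2000).
#' @param up_fraction Probability a responsive gene is up-regulated
#'   (default 0.75, the activation dominance of the auxin response).
#' @param mock_mu Named numeric: per-generation mean mock level of
#'   up-regulated genes (default `c(gametophyte = 3.78, sporophyte =
#'   2.76)`).
#' @param treated_mu Mean treated level of up-regulated genes, shared across
#'   generations (default 7.0).
#' @param noise_sd Replicate noise sd in log2 units (default 0.2).
#' @param n_replicates Replicates per condition (default 3; must be >= 2).
#' @param seed Integer seed.
#' @return A list with `tables` (named list of data.frames `gene_id`,
#'   `log2fc`, `padj`, `norm_expr_mock`, `norm_expr_treated`, one per
#'   generation) and `truth` (data.frame `gene_id`, `responsive`,
#'   `direction`, plus true per-generation mock/treated levels).
#' @export
simulate_de_tables <- function(n_genes = 10000, n_responsive = 2000,
                               up_fraction = 0.75,
                               mock_mu = c(gametophyte = 3.78,
                                           sporophyte = 2.76),
                               treated_mu = 7.0, noise_sd = 0.2,
                               n_replicates = 3, seed = 1) {
  stopifnot(n_responsive <= n_genes, up_fraction >= 0, up_fraction <= 1,
            noise_sd >= 0, !is.null(names(mock_mu)))
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  set.seed(.child_seed(seed, "de"))
  gens <- names(mock_mu)
  ids <- sprintf("g%05d", seq_len(n_genes))
  responsive <- seq_len(n_responsive)
  direction <- rep("null", n_genes)
  direction[responsive] <- ifelse(stats::runif(n_responsive) < up_fraction,
                                  "up", "down")

  # shared gene-level parameters
  treated_level <- rep(NA_real_, n_genes)     # up genes: shared treated level
  mock_dev <- stats::rnorm(n_genes, 0, 0.5)   # gene-level mock heterogeneity
  base_level <- stats::rnorm(n_genes, 5, 2)   # null / down baseline
  drop_amp <- pmax(stats::rnorm(n_genes, 2.5, 1), 0.5)  # down amplitude
  is_up <- direction == "up"
  # planted activation must be genuinely up in every generation: enforce a
  # minimum amplitude of 0.5 log2 units above the highest mock level
  treated_level[is_up] <- pmax(stats::rnorm(sum(is_up), treated_mu, 1.5),
                               max(mock_mu) + mock_dev[is_up] + 0.5)

  p_raw <- stats::runif(n_genes)
  p_raw[responsive] <- stats::runif(n_responsive, 0, 1e-8)
  padj <- stats::p.adjust(p_raw, method = "BH")

  rep_mean <- function(mu) {
    mu + stats::rnorm(length(mu), 0, noise_sd / sqrt(n_replicates))
  }
  tables <- lapply(gens, function(g) {
    mock_true <- base_level
    treat_true <- base_level
    mock_true[is_up] <- mock_mu[[g]] + mock_dev[is_up]
    treat_true[is_up] <- treated_level[is_up]
    is_down <- direction == "down"
    treat_true[is_down] <- base_level[is_down] - drop_amp[is_down]
    mock_obs <- rep_mean(mock_true)
    treat_obs <- rep_mean(treat_true)
    data.frame(gene_id = ids, log2fc = treat_obs - mock_obs, padj = padj,
               norm_expr_mock = mock_obs, norm_expr_treated = treat_obs,
               stringsAsFactors = FALSE)
  })
  names(tables) <- gens

  truth <- data.frame(gene_id = ids,
                      responsive = direction != "null",
                      direction = direction, stringsAsFactors = FALSE)
  for (g in gens) {
    truth[[paste0("mock_", g)]] <-
      ifelse(is_up, mock_mu[[g]] + mock_dev, base_level)
    truth[[paste0("treated_", g)]] <-
      ifelse(is_up, treated_level,
             ifelse(direction == "down", base_level - drop_amp, base_level))
  }
  list(tables = tables, truth = truth)
}

#' Simulate an orthogroup table with controlled DEG overlap
#'
#' Builds `n_og` orthogroups with 0-3 genes per species, then draws one
#' responsive (DEG) orthogroup set per species with a controlled shared
#' component: a fraction `deg_overlap_rate` of each set is drawn jointly,
#' the rest independently, so the true orthogroup-space overlap equals
#' `deg_overlap_rate` in expectation beyond the independence baseline.
#' At `deg_overlap_rate = 0` the sets are independent draws.
#'
#' @param n_og Number of orthogroups (default 500).
#' @param species Character vector of species names (>= 2).
#' @param deg_overlap_rate Controlled joint-membership fraction in `[0, 1]`
#'   (default 0).
#' @param n_deg Responsive orthogroups per species (default 50).
#' @param seed Integer seed.
#' @return A list with `tsv` (the orthogroup table as TSV lines, the dialect
#'   [parse_orthogroups()] reads), `table` (the parsed `orthogroup_table`),
#'   `deg_lists` (named list: per-species responsive gene ids), and `truth`
#'   (list with per-species responsive orthogroup sets and the shared set).
#' @export
simulate_orthogroups <- function(n_og = 500, species = c("ceratopteris",
                                                         "marchantia"),
                                 deg_overlap_rate = 0, n_deg = 50,
                                 seed = 1) {
  stopifnot(length(species) >= 2, deg_overlap_rate >= 0,
            deg_overlap_rate <= 1, n_deg <= n_og)
  set.seed(.child_seed(seed, "orthogroups"))
  og_ids <- sprintf("OG%07d", seq_len(n_og))
  counts <- matrix(sample(0:3, n_og * length(species), replace = TRUE,
                          prob = c(0.15, 0.5, 0.25, 0.1)),
                   nrow = n_og, dimnames = list(og_ids, species))

  cells <- matrix("", n_og, length(species))
  gene_lists <- vector("list", length(species))
  names(gene_lists) <- species
  for (s in seq_along(species)) {
    per_og <- lapply(seq_len(n_og), function(i) {
      k <- counts[i, s]
      if (k == 0) character(0) else
        sprintf("%s_%s_%d", substr(species[s], 1, 2), og_ids[i], seq_len(k))
    })
    cells[, s] <- vapply(per_og, paste, character(1), collapse = ",")
    gene_lists[[s]] <- per_og
  }

  # responsive orthogroup sets: shared core + independent remainder,
  # drawn from orthogroups represented in the species
  n_shared <- round(deg_overlap_rate * n_deg)
  all_present <- which(apply(counts > 0, 1, all))
  if (length(all_present) < n_deg) {
    stop("not enough jointly represented orthogroups for n_deg")
  }
  shared <- sample(all_present, n_shared)
  deg_og <- vector("list", length(species))
  names(deg_og) <- species
  deg_lists <- deg_og
  for (s in seq_along(species)) {
    present <- which(counts[, s] > 0)
    rest <- sample(setdiff(present, shared), n_deg - n_shared)
    deg_og[[s]] <- og_ids[sort(c(shared, rest))]
    deg_lists[[s]] <- unlist(lapply(sort(c(shared, rest)), function(i) {
      gene_lists[[s]][[i]][1]
    }), use.names = FALSE)
  }

  tsv <- c(paste(c("Orthogroup", species), collapse = "\t"),
           paste(og_ids, apply(cells, 1, paste, collapse = "\t"),
                 sep = "\t"))
  tf <- tempfile(fileext = ".tsv")
  writeLines(tsv, tf)
  table <- parse_orthogroups(tf)
  unlink(tf)
  list(tsv = tsv, table = table, deg_lists = deg_lists,
       truth = list(deg_orthogroups = deg_og,
                    shared_orthogroups = og_ids[sort(shared)]))
}

#' Simulate per-leaf vein feature-point counts
#'
#' Draws touch/end/break/exit counts per leaf from independent negative
#' binomial distributions around group means (Poisson when
#' `dispersion = 0`).
#'
#' @param group_means Named list: group name -> numeric vector
#'   `c(T =, E =, B =, X =)` of positive-sum means.
#' @param dispersion Negative binomial dispersion (variance = mu +
#'   dispersion * mu^2); 0 gives Poisson (default).
#' @param n_leaves Leaves per group (default 20).
#' @param seed Integer seed.
#' @return A list with `counts` (data.frame `leaf_id`, `group`, `T`, `E`,
#'   `B`, `X`) and `truth` (the group means).
#' @export
simulate_vein_counts <- function(group_means, dispersion = 0, n_leaves = 20,
                                 seed = 1) {
  stopifnot(is.list(group_means), !is.null(names(group_means)),
            dispersion >= 0, n_leaves >= 1)
  for (g in names(group_means)) {
    mu <- group_means[[g]]
    if (length(mu) != 4 || any(mu < 0) || sum(mu) == 0) {
      stop("group '", g, "': means must be 4 non-negative values, not all 0")
    }
  }
  set.seed(.child_seed(seed, "veins"))
  draw <- function(mu, n) {
    if (mu == 0) return(rep(0L, n))
    if (dispersion == 0) stats::rpois(n, mu) else
      stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  }
  out <- lapply(names(group_means), function(g) {
    mu <- group_means[[g]]
    data.frame(
      leaf_id = sprintf("%s_leaf%03d", g, seq_len(n_leaves)), group = g,
      T = draw(mu[1], n_leaves), E = draw(mu[2], n_leaves),
      B = draw(mu[3], n_leaves), X = draw(mu[4], n_leaves),
      stringsAsFactors = FALSE)
  })
  list(counts = do.call(rbind, out), truth = group_means)
}

#' Simulate a pair of nuclei images with a planted intensity ratio
#'
#' Rasterizes disc-shaped nuclei at non-overlapping random centers on a zero
#' background with small additive noise. Group-b nuclear intensities equal
#' group-a intensities times `group_ratio` times multiplicative lognormal
#' noise — the signature of an extra genome copy under proportional
#' reporter expression.
#'
#' @param n_nuclei Nuclei per image (default 50).
#' @param radius Disc radius in pixels (default 8).
#' @param base_intensity Group-a mean nuclear intensity (default 100).
#' @param group_ratio True b/a intensity ratio (default 2).
#' @param noise_cv Coefficient of variation of the per-nucleus lognormal
#'   noise (default 0.05).
#' @param shape Image dimensions `c(rows, cols)` (default `c(400, 400)`).
#' @param seed Integer seed.
#' @param max_tries Placement retries before giving up (default 2000 per
#'   nucleus).
#' @return A list with `image_a`, `image_b` (numeric matrices) and `truth`
#'   (data.frame `image`, `nucleus`, `row`, `col`, `intensity`; plus the
#'   planted `group_ratio` as an attribute).
#' @export
simulate_nuclei_image <- function(n_nuclei = 50, radius = 8,
                                  base_intensity = 100, group_ratio = 2,
                                  noise_cv = 0.05, shape = c(400, 400),
                                  seed = 1, max_tries = 2000) {
  stopifnot(n_nuclei >= 1, radius >= 1, base_intensity > 0,
            group_ratio > 0, noise_cv >= 0, length(shape) == 2)
  set.seed(.child_seed(seed, "nuclei"))
  sdlog <- sqrt(log(1 + noise_cv^2))

  place <- function() {
    centers <- matrix(NA_real_, n_nuclei, 2)
    for (i in seq_len(n_nuclei)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- stats::runif(1, radius + 1, shape[1] - radius)
        c0 <- stats::runif(1, radius + 1, shape[2] - radius)
        if (i == 1 || all((centers[seq_len(i - 1), 1] - r0)^2 +
                            (centers[seq_len(i - 1), 2] - c0)^2 >
                            (2 * radius + 2)^2)) {
          centers[i, ] <- c(r0, c0)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("cannot place ", n_nuclei, " non-overlapping nuclei in ",
                    shape[1], "x", shape[2], " after ", max_tries, " tries")
    }
    centers
  }
  rasterize <- function(centers, intensities) {
    img <- matrix(abs(stats::rnorm(prod(shape), 0, base_intensity * 0.01)),
                  shape[1], shape[2])
    for (i in seq_len(nrow(centers))) {
      rr <- seq.int(max(1, floor(centers[i, 1] - radius)),
                    min(shape[1], ceiling(centers[i, 1] + radius)))
      cc <- seq.int(max(1, floor(centers[i, 2] - radius)),
                    min(shape[2], ceiling(centers[i, 2] + radius)))
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, `+`)
      img[rr, cc][d2 <= radius^2] <- intensities[i]
    }
    img
  }
  int_a <- base_intensity * stats::rlnorm(n_nuclei, -sdlog^2 / 2, sdlog)
  int_b <- base_intensity * group_ratio *
    stats::rlnorm(n_nuclei, -sdlog^2 / 2, sdlog)
  cen_a <- place()
  cen_b <- place()
  truth <- rbind(
    data.frame(image = "a", nucleus = seq_len(n_nuclei),
               row = cen_a[, 1], col = cen_a[, 2], intensity = int_a),
    data.frame(image = "b", nucleus = seq_len(n_nuclei),
               row = cen_b[, 1], col = cen_b[, 2], intensity = int_b))
  attr(truth, "group_ratio") <- group_ratio
  list(image_a = rasterize(cen_a, int_a),
       image_b = rasterize(cen_b, int_b),
       truth = truth)
}
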