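# Generators: determinism, truth-table round trips, planted structure.

test_that("promoter simulation is a pure function of its seed", {
  a <- simulate_promoters(n_fg = 20, n_bg = 30, seed = 5)
  b <- simulate_promoters(n_fg = 20, n_bg = 30, seed = 5)
  expect_identical(a, b)
  c <- simulate_promoters(n_fg = 20, n_bg = 30, seed = 6)
  expect_false(identical(a$sequences, c$sequences))
  # byte-identical FASTA output
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(paste0(">", names(a$sequences), "\n", a$sequences), f1)
  writeLines(paste0(">", names(b$sequences), "\n", b$sequences), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted promoter features are recovered by the scanners", {
  sim <- simulate_promoters(n_fg = 60, n_bg = 60, fg_rate = 0.5,
                            bg_rate = 0.1, seed = 41)
  occ <- scan_hexamers(sim$sequences)
  cfg <- scan_repeat_configurations(occ)
  hx <- sim$truth[sim$truth$feature_type == "hexamer", ]
  for (i in seq_len(nrow(hx))) {
    g <- occ[occ$gene_id == hx$gene_id[i], ]
    expect_true(any(g$offset == hx$offset[i] & g$hexamer == hx$feature[i]))
  }
  rp <- sim$truth[sim$truth$feature_type == "repeat", ]
  for (i in seq_len(nrow(rp))) {
    g <- cfg[cfg$gene_id == rp$gene_id[i], ]
    expect_true(any(paste0(g$orientation, "_", g$spacer) == rp$feature[i]))
  }
})

test_that("rate-0 configurations plant nothing", {
  sim <- simulate_promoters(n_fg = 20, n_bg = 20, fg_rate = 0, bg_rate = 0,
                            seed = 2)
  expect_equal(nrow(sim$truth), 0)
  expect_error(simulate_promoters(promoter_length = 10, seed = 1),
               "too short")
})

test_that("all three planted orientations round-trip through the scanner", {
  for (ori in c("DR", "IR", "ER")) {
    sim <- simulate_promoters(n_fg = 40, n_bg = 0, promoter_length = 80,
                              planted_hexamer = NULL,
                              planted_config = list(orientation = ori,
                                                    spacer = 11),
                              fg_rate = 1, seed = 19)
    cfg <- scan_repeat_configurations(sim$sequences)
    planted <- sim$truth$gene_id[sim$truth$feature_type == "repeat"]
    expect_equal(sort(planted), sort(sim$foreground))
    for (g in planted) {
      expect_true(any(cfg$gene_id == g & cfg$orientation == ori &
                        cfg$spacer == 11))
    }
  }
})

test_that("DE simulation plants direction dominance and amplitude
          structure", {
  sim <- simulate_de_tables(n_genes = 4000, n_responsive = 1000,
                            up_fraction = 0.75,
                            mock_mu = c(gam = 3.76, spo = 2.76), seed = 9)
  expect_identical(sim, simulate_de_tables(
    n_genes = 4000, n_responsive = 1000, up_fraction = 0.75,
    mock_mu = c(gam = 3.76, spo = 2.76), seed = 9))
  # realized truth-table up fraction within the exact binomial 99% interval
  n_up <- sum(sim$truth$direction == "up")
  n_resp <- sum(sim$truth$responsive)
  expect_equal(n_resp, 1000)
  ci <- qbinom(c(0.005, 0.995), n_resp, 0.75)
  expect_gte(n_up, ci[1])
  expect_lte(n_up, ci[2])
  # planted amplitude difference is exactly the mock_mu gap for up genes,
  # with equal treated levels across generations
  up <- sim$truth$direction == "up"
  expect_equal(sim$truth$mock_gam[up] - sim$truth$mock_spo[up],
               rep(1.0, sum(up)))
  expect_equal(sim$truth$treated_gam[up], sim$truth$treated_spo[up])
  expect_error(simulate_de_tables(n_replicates = 1), "n_replicates")
})

test_that("emulated padj behaves like a BH-adjusted test", {
  sim <- simulate_de_tables(n_genes = 3000, n_responsive = 600, seed = 14)
  tab <- sim$tables[[1]]
  resp <- sim$truth$responsive
  expect_true(all(tab$padj[resp] < 1e-4))
  # null genes are mostly non-significant; BH keeps false calls near alpha
  frac_null_sig <- mean(tab$padj[!resp] < 0.05)
  expect_lt(frac_null_sig, 0.05)
})

test_that("orthogroup simulation emits a parseable table with planted
          overlap", {
  sim <- simulate_orthogroups(n_og = 250, deg_overlap_rate = 0.4,
                              n_deg = 40, seed = 3)
  expect_identical(sim$tsv, simulate_orthogroups(
    n_og = 250, deg_overlap_rate = 0.4, n_deg = 40, seed = 3)$tsv)
  # round trip: parsing the emitted TSV reproduces the parsed table
  f <- tempfile(fileext = ".tsv")
  writeLines(sim$tsv, f)
  expect_equal(parse_orthogroups(f), sim$table)
  # planted joint core is inside both responsive orthogroup sets
  shared <- sim$truth$shared_orthogroups
  expect_length(shared, 16)
  for (s in names(sim$truth$deg_orthogroups)) {
    expect_true(all(shared %in% sim$truth$deg_orthogroups[[s]]))
  }
  expect_error(simulate_orthogroups(n_og = 10, n_deg = 10, seed = 1),
               "jointly represented")
})

test_that("independent responsive sets sit at the chance baseline", {
  # with deg_overlap_rate = 0 the overlap enrichment p should be roughly
  # uniform: check no systematic enrichment across seeds
  ps <- vapply(1:30, function(s) {
    sim <- simulate_orthogroups(n_og = 300, deg_overlap_rate = 0,
                                n_deg = 40, seed = s)
    uni <- Reduce(intersect, lapply(names(sim$deg_lists), function(sp) {
      unique(sim$table$orthogroup[sim$table$species == sp])
    }))
    m <- lapply(names(sim$deg_lists), function(sp) {
      intersect(map_set_to_orthogroups(sim$deg_lists[[sp]], sp,
                                       sim$table)$orthogroups, uni)
    })
    overlap_enrichment(m[[1]], m[[2]], uni)$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), -1)  # computed without error
  expect_lt(mean(ps < 0.05), 0.35)
})

test_that("vein count draws match their Poisson means", {
  sim <- simulate_vein_counts(list(mock = c(T = 10, E = 5, B = 2, X = 3)),
                              dispersion = 0, n_leaves = 200, seed = 8)
  expect_identical(sim$counts, simulate_vein_counts(
    list(mock = c(T = 10, E = 5, B = 2, X = 3)), dispersion = 0,
    n_leaves = 200, seed = 8)$counts)
  expect_lt(abs(mean(sim$counts$T) - 10), 3 * sqrt(10 / 200))
  expect_error(simulate_vein_counts(list(g = c(T = 0, E = 0, B = 0, X = 0)),
                                    seed = 1), "not all 0")
})

test_that("nuclei images rasterize discs with exact pixel areas", {
  sim <- simulate_nuclei_image(n_nuclei = 2, radius = 8, noise_cv = 0,
                               shape = c(120, 120), seed = 33)
  expect_identical(sim$image_a, simulate_nuclei_image(
    n_nuclei = 2, radius = 8, noise_cv = 0, shape = c(120, 120),
    seed = 33)$image_a)
  rois <- segment_nuclei(sim$image_a, min_area = 10)
  expect_equal(nrow(rois), 2)
  # oracle: count lattice points inside each disc from the truth centers
  tr <- sim$truth[sim$truth$image == "a", ]
  expected_area <- vapply(seq_len(2), function(i) {
    grid <- expand.grid(r = 1:120, c = 1:120)
    sum((grid$r - tr$row[i])^2 + (grid$c - tr$col[i])^2 <= 64)
  }, numeric(1))
  expect_setequal(rois$area, expected_area)
  # no-noise nuclei intensities equal the planted values
  expect_setequal(round(rois$mean_intensity, 6), round(tr$intensity, 6))
  expect_error(simulate_nuclei_image(n_nuclei = 500, radius = 10,
                                     shape = c(100, 100), seed = 1,
                                     max_tries = 20), "cannot place")
})
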