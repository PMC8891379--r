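test_that("distribution specs draw reproducibly and respect truncation", {
  expect_equal(draw_dist(dist_spec("point", value = 3), 5), rep(3, 5))
  u1 <- draw_dist(dist_spec("uniform", min = 0, max = 1), 20, seed = 42)
  u2 <- draw_dist(dist_spec("uniform", min = 0, max = 1), 20, seed = 42)
  expect_identical(u1, u2)
  big <- draw_dist(dist_spec("uniform", min = 0, max = 1), 1e5, seed = 1)
  expect_equal(mean(big), 0.5, tolerance = 0.01)
  tr <- draw_dist(dist_spec("normal", mean = 0, sd = 1,
                            lower = 0.5, upper = 2), 500, seed = 3)
  expect_true(all(tr >= 0.5 & tr <= 2))
  expect_error(
    draw_dist(dist_spec("uniform", min = 0, max = 1, lower = 5, upper = 6),
              100, seed = 1),
    "reject")
  tri <- draw_dist(dist_spec("triangular", min = 1, mode = 2, max = 4),
                   1e4, seed = 2)
  expect_true(all(tri >= 1 & tri <= 4))
  expect_equal(mean(tri), (1 + 2 + 4) / 3, tolerance = 0.02)
  ln <- draw_dist(dist_spec("lognormal", mean = 2, sd = 0.5), 1e5, seed = 4)
  expect_equal(mean(ln), 2, tolerance = 0.02)
  expect_equal(sd(ln), 0.5, tolerance = 0.05)
  expect_error(dist_spec("uniform", min = 2, max = 1), "min")
  expect_error(dist_spec("lognormal", mean = -1, sd = 1), "positive")
})

test_that("point-mass Monte Carlo collapses to the deterministic result", {
  smry <- summary_from_targets()
  conc <- summary_concentrations(smry, unit = "ug/kg",
                                 congeners = setdiff(
                                   attr(smry, "panel")$abbrev,
                                   never_detected(smry)))
  specs <- lapply(conc, function(v) dist_spec("point", value = v))
  p <- exposure_params()
  mc <- run_exposure_mc(specs, param_dists = default_param_dists(q95_q50 = NULL),
                        cfg = mc_config(iterations = 200, seed = 9))
  det <- assess_risk(conc, p)
  for (q in unique(mc$edi$percentile)) {
    for (cg in names(conc)) {
      v <- mc$edi$value[mc$edi$congener == cg & mc$edi$percentile == q]
      expect_equal(v, unname(det$edi[cg]), tolerance = 1e-12)
    }
  }
  expect_equal(unname(mc$ilcr), rep(det$ilcr, 4), tolerance = 1e-12)
})

test_that("percentiles are monotone and ILCR scales linearly in SF", {
  smry <- summary_from_targets()
  cfg <- mc_config(iterations = 2000, seed = 11)
  mc <- run_exposure_mc(conc_specs(smry), cfg = cfg)
  by_cg <- split(mc$edi, mc$edi$congener)
  for (tbl in by_cg) {
    tbl <- tbl[order(tbl$percentile), ]
    expect_true(all(diff(tbl$value) >= 0))
  }
  expect_true(all(diff(unname(mc$ilcr)) >= 0))
  p2 <- exposure_params(SF = 14.6)
  mc2 <- run_exposure_mc(conc_specs(smry),
                         param_dists = default_param_dists(params = p2),
                         cfg = cfg)
  expect_equal(unname(mc2$ilcr), 2 * unname(mc$ilcr), tolerance = 1e-10)
})

test_that("runs are seed-reproducible and seeds matter", {
  smry <- summary_from_targets()
  specs <- conc_specs(smry)
  a <- run_exposure_mc(specs, cfg = mc_config(iterations = 500, seed = 7))
  b <- run_exposure_mc(specs, cfg = mc_config(iterations = 500, seed = 7))
  expect_identical(a$edi$value, b$edi$value)
  expect_identical(a$ilcr, b$ilcr)
  c <- run_exposure_mc(specs, cfg = mc_config(iterations = 500, seed = 8))
  expect_false(identical(a$ilcr, c$ilcr))
  # but within Monte Carlo error of one another
  expect_equal(unname(a$ilcr["p50"]), unname(c$ilcr["p50"]),
               tolerance = 0.1)
})

test_that("intake ranking reproduces the published 95th-percentile order", {
  published <- tibble::tibble(
    congener = c("NA", "Ace", "F", "Pa", "A", "P", "Ch", "BbF", "BkF",
                 "BaP", "DhA", "IP"),
    percentile = 95,
    value = c(4.34e-8, 5.53e-8, 1.19e-7, 3.75e-8, 6.22e-8, 1.26e-7,
              7.79e-8, 2.20e-8, 9.91e-8, 8.11e-8, 1.41e-8, 1.43e-8)
  )
  expect_equal(rank_by_percentile(published, 95),
               c("P", "F", "BkF", "BaP", "Ch", "A", "Ace", "NA", "Pa",
                 "BbF", "IP", "DhA"))
  expect_equal(rank_by_percentile(published[published$congener == "P", ], 95),
               "P")
  expect_error(rank_by_percentile(published, 40), "not in the table")
  # ties break by table (panel) order
  tied <- tibble::tibble(congener = c("x", "y"), percentile = 95,
                         value = c(1, 1))
  expect_equal(rank_by_percentile(tied, 95), c("x", "y"))
})

test_that("EDI ranking follows concentrations under a shared exposure factor", {
  smry <- summary_from_targets()
  specs <- conc_specs(smry)
  conc <- vapply(specs, function(s) s$params$value, numeric(1))
  mc <- run_exposure_mc(specs, cfg = mc_config(iterations = 2000, seed = 2))
  for (q in c(5, 50, 95)) {
    expect_equal(rank_by_percentile(mc$edi, q),
                 names(conc)[order(-conc)])
  }
})

test_that("convergence ladder drift shrinks with iterations", {
  smry <- summary_from_targets()
  point_specs <- lapply(conc_specs(smry), function(s) s)
  flat <- convergence_check(point_specs,
                            param_dists = default_param_dists(q95_q50 = NULL),
                            ladder = c(200, 400), seed = 5)
  expect_true(is.na(flat$drift[1]))
  expect_equal(flat$drift[2], 0)
  noisy_specs <- conc_specs(smry, family = "lognormal")
  ladder <- convergence_check(noisy_specs, ladder = c(500, 5000, 50000),
                              seed = 5)
  expect_lt(ladder$drift[3], ladder$drift[2])
  expect_error(convergence_check(point_specs, ladder = 100), "at least 2")
})

test_that("undersized runs warn about unstable tails", {
  smry <- summary_from_targets()
  expect_warning(
    run_exposure_mc(conc_specs(smry),
                    cfg = mc_config(iterations = 50, seed = 1)),
    "unstable")
})
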