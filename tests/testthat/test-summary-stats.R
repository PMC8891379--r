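targets_summary <- summary_from_targets()

test_that("congener sums reproduce the published group scores", {
  rice <- c(BaA = 0.06, Ch = 0.26, BbF = 0.04, BaP = 0.11)
  expect_equal(congener_sum(rice, names(rice)), 0.47)
  expect_equal(congener_sum(c(a = 0, b = 0), c("a", "b")), 0)
  expect_error(congener_sum(rice, c("BaA", "BkF")), "BkF")

  panel <- default_panel()
  honey <- summary_concentrations(targets_summary,
                                  "mixed wheat and honey-based",
                                  unit = "ug/kg")
  total <- congener_sum(honey, panel$abbrev)
  expect_equal(total, 3.32, tolerance = 1e-8)
  expect_lt(abs(total - 3.31), 0.04 + 1e-9)
})

test_that("overall row aggregates group means the way the survey reports", {
  ov <- function(stat) {
    targets_summary$mean[targets_summary$product_type == "overall" &
                           targets_summary$statistic == stat]
  }
  expect_equal(round(ov("sigma_pah16"), 2), 3.73)
  expect_equal(round(ov("pah4"), 2), 0.72)
  expect_equal(round(ov("BaP"), 2), 0.29)
  # overall min/max are extrema of the group minima/maxima
  tot <- dplyr::filter(targets_summary, statistic == "sigma_pah16",
                       product_type != "overall")
  expect_equal(min(tot$min), 2.70)
  bap <- dplyr::filter(targets_summary, statistic == "BaP",
                       product_type != "overall")
  expect_equal(max(bap$max), 0.58)
})

test_that("per-group sums of imputed means match printed totals", {
  panel <- default_panel()
  scores <- load_group_scores()
  for (g in unique(scores$product_type)) {
    conc <- summary_concentrations(targets_summary, g, unit = "ug/kg")
    printed <- scores[scores$product_type == g, ]
    tot <- congener_sum(conc, panel$abbrev)
    p4 <- congener_sum(conc, pah4_members(panel))
    expect_lt(abs(tot - printed$mean[printed$statistic == "sigma_pah16"]),
              0.04 + 1e-9)
    expect_lt(abs(p4 - printed$mean[printed$statistic == "pah4"]),
              0.02 + 1e-9)
  }
})

test_that("group summaries recover generator targets at large n", {
  targets <- load_group_targets()
  ds <- generate_dataset(targets, n_per_group = 200, seed = 31,
                         censor_at_lod = FALSE)
  smry <- summarize_groups(impute_nondetects(ds))
  detected <- dplyr::filter(targets, !all_nd)
  zs <- vapply(seq_len(nrow(detected)), function(i) {
    row <- detected[i, ]
    m <- smry$mean[smry$product_type == row$product_type &
                     smry$statistic == row$congener]
    abs(m - row$mean) / (row$sd / sqrt(200))
  }, numeric(1))
  # calibrated recovery: bulk within 2 SE, nothing grossly biased
  expect_gte(mean(zs <= 2), 0.95)
  expect_true(all(zs <= 4))
  # min <= mean <= max and sd >= 0 throughout
  grp <- dplyr::filter(smry, product_type != "overall")
  expect_true(all(grp$min <= grp$mean + 1e-12))
  expect_true(all(grp$mean <= grp$max + 1e-12))
  expect_true(all(grp$sd >= 0))
  # the total burden dominates the regulatory subset in every group
  wide <- dplyr::filter(grp, statistic %in% c("sigma_pah16", "pah4"))
  tot <- wide$mean[wide$statistic == "sigma_pah16"]
  p4 <- wide$mean[wide$statistic == "pah4"]
  expect_true(all(tot >= p4))
})

test_that("summaries are invariant to record order and brand labels", {
  ds <- generate_dataset(seed = 13)
  imp <- impute_nondetects(ds)
  s1 <- summarize_groups(imp)
  shuffled <- imp$measurements[rev(seq_len(nrow(imp$measurements))), ]
  shuffled$brand <- sample(c("X", "Y"), nrow(shuffled), replace = TRUE)
  s2 <- summarize_groups(pah_dataset(shuffled, ds$panel, imputed = TRUE))
  expect_equal(as.data.frame(s1), as.data.frame(s2))
})

test_that("a single-sample group reports mean = min = max and sd 0", {
  panel <- default_panel()
  m <- tidyr::expand_grid(sample_id = "only", congener = panel$abbrev)
  m$product_type <- "rice-based"
  m$brand <- "A"
  m$value <- seq(0.1, 1.6, by = 0.1)
  m$censored <- FALSE
  smry <- summarize_groups(pah_dataset(m, panel, imputed = TRUE))
  row <- dplyr::filter(smry, product_type == "rice-based",
                       statistic == "BaP")
  expect_equal(row$mean, row$min)
  expect_equal(row$mean, row$max)
  expect_equal(row$sd, 0)
})

test_that("extreme-group lookup reports the published maxima and minima", {
  tot <- extreme_groups(targets_summary, "sigma_pah16")
  expect_equal(tot$max_group, "mixed 5 cereal-based")
  expect_equal(tot$max_value, 5.06)
  expect_equal(tot$min_group, "mixed wheat and date-based")
  expect_equal(tot$min_value, 3.03)
  p4 <- extreme_groups(targets_summary, "pah4")
  expect_equal(p4$max_group, "mixed 5 cereal-based")
  expect_equal(p4$max_value, 0.98)
  expect_equal(p4$min_value, 0.47)
  expect_error(extreme_groups(targets_summary, "nope"), "unknown")
})

test_that("compliance uses strict inequality against the limits", {
  rep <- compliance(targets_summary)
  expect_true(all(rep$bap_compliant))
  expect_true(all(rep$pah4_compliant))
  at_limit <- targets_summary
  at_limit$mean[at_limit$statistic == "BaP" &
                  at_limit$product_type == "rice-based"] <- 1.0
  at_limit$mean[at_limit$statistic == "pah4" &
                  at_limit$product_type == "wheat-based"] <- 1.2
  rep2 <- compliance(at_limit)
  expect_false(rep2$bap_compliant[rep2$product_type == "rice-based"])
  expect_false(rep2$pah4_compliant[rep2$product_type == "wheat-based"])
  expect_error(compliance(targets_summary, c(BaP = -1, pah4 = 1)),
               "positive")
})

test_that("one-way F reduces to the squared t statistic with two groups", {
  set.seed(99)
  vals <- c(rnorm(6, 5, 1), rnorm(7, 6, 1))
  grp <- rep(c("a", "b"), c(6, 7))
  ds <- single_congener_dataset(vals, grp)
  fit <- oneway_anova(ds, "BaP")
  tt <- t.test(vals[grp == "a"], vals[grp == "b"], var.equal = TRUE)
  expect_equal(fit$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
})

test_that("degenerate and undersized ANOVA inputs are handled", {
  flat <- single_congener_dataset(rep(2.5, 8), rep(c("a", "b"), each = 4))
  fit <- oneway_anova(flat, "BaP")
  expect_equal(fit$f, 0)
  expect_equal(fit$p, 1)
  tiny <- single_congener_dataset(c(1, 2, 3), c("a", "a", "b"))
  expect_error(oneway_anova(tiny, "BaP"), "at least 2")
})
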