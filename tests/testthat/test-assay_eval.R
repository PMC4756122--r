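test_that("standard curves recover exact and noisy dilution series", {
  # exact points on Ct = -3.4 log10(c) + 40.1
  copies <- rep(10^(1:5), each = 3)
  ct <- 40.1 - 3.4 * log10(copies)
  sc <- fit_standard_curve(copies, ct, assay_id = "Av24-like")
  expect_equal(sc$slope_magnitude, 3.4, tolerance = 1e-12)
  expect_equal(sc$intercept, 40.1, tolerance = 1e-12)
  expect_equal(sc$r_squared, 1.0, tolerance = 1e-12)
  expect_equal(sc$efficiency_percent, 96.8419, tolerance = 1e-4)
  expect_equal(unname(sc$roq), c(10, 1e5))

  # perfect doubling: slope 1/log10(2) gives exactly 100%
  ct2 <- 38 - (1 / log10(2)) * log10(copies)
  sc2 <- fit_standard_curve(copies, ct2)
  expect_equal(sc2$efficiency_percent, 100, tolerance = 1e-9)

  # noisy synthetic series recovers the planted slope within 0.1
  spec <- synth_spec(seed = 71)
  sim <- make_qpcr_series(spec, copies_levels = 10^(1:8), n_replicates = 3)
  fit <- fit_standard_curve(sim$table$copies, sim$table$ct)
  expect_lt(abs(fit$slope_magnitude - spec$qpcr$slope_magnitude), 0.1)

  expect_error(fit_standard_curve(c(10, 100), c(35, 31)), "3 distinct")
  expect_error(fit_standard_curve(c(0, 10, 100), c(38, 35, 31)), "positive")
})

test_that("efficiency follows the dilution-slope formula and decreases in slope", {
  expect_equal(efficiency_from_slope(3.75), 84.785, tolerance = 1e-3)
  expect_equal(truncate_reported(efficiency_from_slope(3.75), 1), 84.7)
  expect_equal(efficiency_from_slope(3.43), 95.679, tolerance = 1e-3)
  expect_equal(truncate_reported(efficiency_from_slope(3.43), 1), 95.6)
  expect_equal(efficiency_from_slope(1 / log10(2)), 100, tolerance = 1e-9)
  slopes <- seq(2.8, 4.2, by = 0.1)
  expect_true(all(diff(efficiency_from_slope(slopes)) < 0))
  expect_error(efficiency_from_slope(0), "positive")
  expect_error(efficiency_from_slope(-3.4), "positive")
})

test_that("LOD is the smallest level reaching the detection rate", {
  lod <- estimate_lod(data.frame(copies = c(5, 2),
                                 n_positive = c(10, 6), n_total = c(10, 10)))
  expect_equal(lod$lod_copies, 5)
  # boundary inclusive: 9/10 at rate 0.90 qualifies
  lod2 <- estimate_lod(data.frame(copies = 10, n_positive = 9, n_total = 10))
  expect_equal(lod2$lod_copies, 10)
  # no qualifying level: explicit undefined result, not an error
  lod3 <- estimate_lod(data.frame(copies = c(5, 50),
                                  n_positive = c(1, 8), n_total = c(10, 10)))
  expect_true(is.na(lod3$lod_copies))
  # named-list interface
  lod4 <- estimate_lod(list(`5` = c(10, 10), `2` = c(6, 10)))
  expect_equal(lod4$lod_copies, 5)
})

test_that("confusion summaries reproduce printed panel percentages", {
  av <- expand_detection_counts(avian_panel_counts("avian"))
  cs <- confusion(av, "Av216", "waterfowl")
  expect_identical(cs$TP, 13L + 0L)
  expect_equal(cs$sensitivity_percent, 76) # 13/17 floor-truncated
  nv <- expand_detection_counts(avian_panel_counts("nonavian"))
  cn <- confusion(nv, "Av163", avian_panel_targets()[["Av163"]])
  expect_identical(cn$FP, 15L)
  expect_identical(cn$TN, 89L)
  expect_equal(cn$specificity_percent, 85) # 89/104 floor-truncated
  expect_true(is.na(cn$sensitivity)) # no target samples in that matrix

  # degenerate all-positive matrix: sensitivity 100, specificity 0
  allpos <- detection_matrix(data.frame(
    assay = "X", sample = sprintf("s%d", 1:6),
    host_group = rep(c("t", "n"), each = 3), call = TRUE))
  ca <- confusion(allpos, "X", "t")
  expect_equal(ca$sensitivity_percent, 100)
  expect_equal(ca$specificity_percent, 0)

  # invariant to sample ordering
  df <- data.frame(assay = "X", sample = sprintf("s%d", 1:20),
                   host_group = rep(c("t", "n"), 10),
                   call = rep(c(TRUE, FALSE, TRUE, TRUE), 5))
  c1 <- confusion(detection_matrix(df), "X", "t")
  c2 <- confusion(detection_matrix(df[sample(20), ]), "X", "t")
  expect_identical(c1[c("TP", "FN", "TN", "FP")], c2[c("TP", "FN", "TN", "FP")])

  expect_error(confusion(allpos, "nosuch", "t"), "absent")
  expect_error(confusion(allpos, "X", character(0)), "non-empty")
})

test_that("plasmid mass converts to copy number by molar mass", {
  c1 <- copies_from_plasmid_mass(1, 3000)
  expect_equal(c1, 3.041e8, tolerance = 1e-3)
  expect_equal(copies_from_plasmid_mass(0.5, 3000), c1 / 2)
  expect_equal(copies_from_plasmid_mass(1, 6000), c1 / 2)
  expect_error(copies_from_plasmid_mass(0, 3000), "positive")
  expect_error(copies_from_plasmid_mass(1, -1), "positive")
})

test_that("profile statistics match the box-plot quantile conventions", {
  dm <- detection_matrix(data.frame(
    assay = "A", sample = sprintf("s%d", 1:5), host_group = "waterfowl",
    call = TRUE, quantity = c(1, 2, 3, 4, 5)))
  ps <- profile_stats(dm, "waterfowl")
  expect_equal(ps$median, 3)
  expect_equal(ps$q25, 2)
  expect_equal(ps$q75, 4)
  expect_identical(ps$n_outliers, 0L)

  dm2 <- detection_matrix(data.frame(
    assay = "A", sample = sprintf("s%d", 1:6), host_group = "waterfowl",
    call = TRUE, quantity = c(1, 2, 3, 4, 5, 100)))
  ps2 <- profile_stats(dm2, "waterfowl")
  expect_identical(ps2$n_outliers, 1L)
  expect_match(ps2$outliers, "100")

  # brute-force quantile oracle on a lognormal sample
  withr::with_seed(73, {
    x <- rlnorm(40, 5, 1)
    dm3 <- detection_matrix(data.frame(
      assay = "A", sample = sprintf("s%d", 1:40), host_group = "g",
      call = TRUE, quantity = x))
    ps3 <- profile_stats(dm3, "g")
    expect_equal(ps3$median, unname(quantile(x, 0.5)), tolerance = 1e-12)
    expect_equal(ps3$q25, unname(quantile(x, 0.25)), tolerance = 1e-12)
    expect_equal(ps3$q75, unname(quantile(x, 0.75)), tolerance = 1e-12)
    iqr <- ps3$q75 - ps3$q25
    expect_identical(ps3$n_outliers,
                     sum(x < ps3$q25 - 1.5 * iqr | x > ps3$q75 + 1.5 * iqr))
  })
  expect_identical(nrow(profile_stats(dm, "nosuch")), 0L)
})
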