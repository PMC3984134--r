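# Normalization, detection limits, gamma rank correlation, bootstrap,
# residual bias.

test_that("normalization yields percentages that sum to 100 per sample", {
  ann <- data.frame(reference_id = c("a", "b", "c"),
                    type_name = c("X", "X", "Y"), stringsAsFactors = FALSE)
  counts <- matrix(c(50, 50, 0,   2, 3, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  ab <- normalize_and_aggregate(counts, ann)
  expect_equal(unname(ab$ref_percent["s1", ]), c(50, 50, 0))
  expect_equal(unname(ab$type_percent["s2", "X"]), 50)
  expect_equal(unname(rowSums(ab$ref_percent)), c(100, 100), tolerance = 1e-6)
  expect_equal(unname(rowSums(ab$type_percent)), c(100, 100), tolerance = 1e-6)
})

test_that("zero-mapped samples are flagged, missing annotations rejected", {
  ann <- data.frame(reference_id = "a", type_name = "X")
  counts <- matrix(c(5L, 0L), 2, 1, dimnames = list(c("s1", "s2"), "a"))
  expect_warning(ab <- normalize_and_aggregate(counts, ann), "zero mapped")
  expect_equal(ab$zero_samples, "s2")
  expect_true(is.na(ab$ref_percent["s2", "a"]))
  counts2 <- matrix(1L, 1, 2, dimnames = list("s1", c("a", "zz")))
  expect_error(normalize_and_aggregate(counts2, ann), "missing")
})

test_that("the detection cutoff is mean FP plus two standard errors", {
  expect_equal(detection_cutoff(0.07, 0.02), 0.11)
  expect_equal(detection_cutoff(0, 0), 0)
})

make_fp_abundance <- function(fp_percents) {
  # one absent type Y observed at given percents; dominant type X carries the
  # rest
  n <- length(fp_percents)
  samples <- sprintf("p%d", seq_len(n))
  counts <- matrix(0, n, 2, dimnames = list(samples, c("x", "y")))
  counts[, "y"] <- round(fp_percents * 100)      # per-10,000 read counts
  counts[, "x"] <- 10000 - counts[, "y"]
  ann <- data.frame(reference_id = c("x", "y"), type_name = c("X", "Y"),
                    stringsAsFactors = FALSE)
  designs <- rbind(
    data.frame(sample_id = samples, type_name = "X", cell_fraction = 1),
    data.frame(sample_id = samples, type_name = "Y", cell_fraction = 0)
  )
  list(ab = normalize_and_aggregate(counts, ann), designs = designs)
}

test_that("detection limit follows the mean + 2 SE formula on FP values", {
  fx <- make_fp_abundance(c(0.05, 0.07, 0.09))
  dl <- estimate_detection_limit(fx$ab, fx$designs)
  expect_equal(dl$mean_fp, 0.07, tolerance = 1e-6)
  expect_equal(dl$se_fp, sd(c(0.05, 0.07, 0.09)) / sqrt(3), tolerance = 1e-6)
  expect_equal(dl$cutoff, dl$mean_fp + 2 * dl$se_fp)
  expect_gte(dl$cutoff, dl$mean_fp)

  # all-zero false positives: cutoff 0
  fx0 <- make_fp_abundance(rep(0, 4))
  expect_equal(estimate_detection_limit(fx0$ab, fx0$designs)$cutoff, 0)
})

test_that("gross outliers are excluded before the cutoff is computed", {
  vals <- c(rep(0.07, 10), 15.6)
  fx <- make_fp_abundance(vals)
  dl <- estimate_detection_limit(fx$ab, fx$designs, outlier_k = 5)
  expect_length(dl$outliers, 1)
  expect_equal(unname(dl$outliers), 15.6, tolerance = 1e-6)
  expect_lt(dl$cutoff, 1)

  # no absent types anywhere: explicit failure
  ann <- data.frame(reference_id = "x", type_name = "X")
  counts <- matrix(10L, 1, 1, dimnames = list("s1", "x"))
  ab <- normalize_and_aggregate(counts, ann)
  designs <- data.frame(sample_id = "s1", type_name = "X", cell_fraction = 1)
  expect_error(estimate_detection_limit(ab, designs), "cannot estimate")
})

test_that("gamma matches hand-computed and boundary cases", {
  expect_equal(gamma_correlation(1:6, c(2, 4, 5, 7, 8, 11))$gamma, 1)
  expect_equal(gamma_correlation(1:6, rev(c(2, 4, 5, 7, 8, 11)))$gamma, -1)
  g <- gamma_correlation(c(1, 2, 2, 3, 4), c(1, 3, 2, 1, 5))
  expect_equal(g$gamma, 0.5)
  expect_equal(g$n_concordant, 6L)
  expect_equal(g$n_discordant, 2L)
  # undefined when x is constant
  expect_true(gamma_correlation(rep(1, 4), 1:4)$undefined)
})

test_that("gamma equals brute-force pair enumeration, with and without tolerance", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    r <- sample(c(0, 0, 1), 1)
    ours <- gamma_correlation(x, y, tolerance_r = r)
    oracle <- brute_gamma(x, y, r)
    expect_equal(ours$n_concordant, oracle$nc)
    expect_equal(ours$n_discordant, oracle$nd)
    expect_equal(ours$gamma, oracle$gamma)
    # antisymmetry
    flipped <- gamma_correlation(x, -y, tolerance_r = r)
    if (!ours$undefined) expect_equal(flipped$gamma, -ours$gamma)
  }
})

test_that("permutation p-values are small for monotone data and reproducible", {
  x <- 1:8
  y <- c(2, 3, 5, 8, 9, 12, 15, 20)
  g <- gamma_permutation_p(x, y, n_iter = 1000, seed = 5)
  expect_lte(g$p_value, 0.01)
  expect_gt(g$p_value, 0)
  g2 <- gamma_permutation_p(x, y, n_iter = 1000, seed = 5)
  expect_identical(g$p_value, g2$p_value)
  expect_error(gamma_permutation_p(rep(1, 5), 1:5), "undefined")
})

test_that("bootstrap CIs are degenerate on constants and reproducible", {
  ci <- bootstrap_ci(rep(3.5, 10), seed = 2)
  expect_equal(ci$lower, 3.5)
  expect_equal(ci$upper, 3.5)
  v <- c(0.4, 1.2, 0.8, 2.2, 0.1, 1.9)
  expect_identical(bootstrap_ci(v, seed = 7), bootstrap_ci(v, seed = 7))
  ci2 <- bootstrap_ci(c(1, 2, 3, 4), seed = 3)
  expect_lte(ci2$lower, ci2$mean)
  expect_gte(ci2$upper, ci2$mean)
})

test_that("bootstrap CI coverage is near nominal", {
  set.seed(123)
  hits <- 0L
  reps <- 200L
  for (i in seq_len(reps)) {
    v <- rnorm(40, mean = 10, sd = 2)
    ci <- bootstrap_ci(v, n_resamples = 400, seed = i)
    if (ci$lower <= 10 && 10 <= ci$upper) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.87)
  expect_lte(hits / reps, 0.99)
})

test_that("residual bias counts over/under-estimation per expected level", {
  obs <- c(0.1, 0.12, 1, 0.9, 5, 5.3)
  exp_ <- c(0.1, 0.1, 1, 1, 5, 5)
  rb <- residual_bias(exp_, exp_)
  expect_true(all(abs(rb$residuals) < 1e-12))
  # constant shift is absorbed by the intercept
  rb2 <- residual_bias(exp_ + 1, exp_)
  expect_true(all(abs(rb2$residuals) < 1e-12))
  # inflation at the lowest level shows up as overestimation there
  infl <- exp_
  infl[exp_ == 0.1] <- infl[exp_ == 0.1] + 0.5
  rb3 <- residual_bias(infl, exp_)
  row <- rb3$by_level[rb3$by_level$expected == 0.1, ]
  expect_equal(row$n_over, 2L)
  expect_equal(row$n_under, 0L)
  expect_error(residual_bias(c(1, 2, 3), c(1, 1, 1)), "degenerate")
})
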