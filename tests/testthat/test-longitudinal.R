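test_that("Pearson test reproduces hand-computed and boundary cases", {
  # exact linearity
  expect_equal(pearson_with_test(1:10, 2 * (1:10) + 1)$r, 1)
  # hand computation: cov 4, sd sqrt(5) each -> r = 0.8
  res <- pearson_with_test(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$t_stat, 0.8 * sqrt(2 / (1 - 0.64)))
  # preconditions
  expect_error(pearson_with_test(1:2, 2:3), "at least 3")
  expect_error(pearson_with_test(c(1, 1, 1), 1:3), "zero variance")
  # pairwise deletion of missing values
  res2 <- pearson_with_test(c(1, 2, NA, 4, 5), c(1, 3, 9, NA, 5))
  expect_identical(res2$n_pairs, 3L)
})

test_that("Pearson test agrees with the brute-force formula to 1e-12", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(4:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- pearson_with_test(x, y)
    want <- brute_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$t_stat, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
  }
})

test_that("correlation is invariant under sign-preserving affine transforms", {
  set.seed(56)
  x <- rnorm(20); y <- x + rnorm(20)
  base <- pearson_with_test(x, y)$r
  expect_equal(pearson_with_test(3 * x + 7, y)$r, base)
  expect_equal(pearson_with_test(x, 0.01 * y - 2)$r, base)
  expect_equal(pearson_with_test(-x, y)$r, -base)
})

test_that("cohort concordance counts significant patients and flags untestable ones", {
  mk <- function(id, x, y) patient_series(
    id, data.frame(week = seq_along(x), ca125 = x, marker_conc = y),
    surgery_week = 0)
  perfect <- lapply(1:3, function(i) mk(paste0("p", i), 1:10, (1:10) * i))
  cc <- cohort_concordance(perfect)
  expect_identical(cc$n_significant, 3L)

  flat <- mk("flat", rep(1, 5), c(1, 2, 3, 4, 5))
  cc2 <- cohort_concordance(c(perfect, list(flat)))
  expect_identical(cc2$n_significant, 3L)
  expect_true(cc2$results$untestable[cc2$results$patient_id == "flat"])
  expect_error(cohort_concordance(list()), "empty")
})

test_that("shared-latent patients are significant; independent ones at the alpha rate", {
  # power: both channels driven by one burden trajectory
  sig <- vapply(1:40, function(s) {
    ps <- generate_patient_series(trajectory_config(seed = 400 + s))
    pearson_with_test(ps$draws$ca125, ps$draws$marker_conc)$significant
  }, logical(1))
  expect_gte(mean(sig), 0.9)

  # calibration: marker channel from an independent patient's burden
  false_sig <- vapply(1:200, function(s) {
    a <- generate_patient_series(trajectory_config(
      baseline_burden = 0, ca125_floor = 30, seed = 900 + s))
    b <- generate_patient_series(trajectory_config(seed = 5000 + s))
    pearson_with_test(a$draws$ca125, b$draws$marker_conc)$significant
  }, logical(1))
  # false-significance rate ~ alpha (3 SE band around 0.05)
  expect_lt(mean(false_sig), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("post-resection drop compares first post-surgery draw to baseline", {
  mk <- function(ca, mc, weeks = seq_along(ca) - 1) patient_series(
    "p", data.frame(week = weeks, ca125 = ca, marker_conc = mc),
    surgery_week = 0)
  d <- post_resection_drop(mk(c(100, 10, 5), c(300, 30, 10)))
  expect_identical(d, c(ca125 = TRUE, marker = TRUE))
  # boundary: no strict decrease from a zero baseline
  d0 <- post_resection_drop(mk(c(0, 0, 1), c(0, 0, 0)))
  expect_identical(d0, c(ca125 = FALSE, marker = FALSE))
  # channels evaluated independently
  dm <- post_resection_drop(mk(c(100, 10), c(5, 50), weeks = c(0, 4)))
  expect_identical(dm, c(ca125 = TRUE, marker = FALSE))
  # untestable without a post-surgery draw
  only_base <- patient_series("p", data.frame(week = 0, ca125 = 1,
                                              marker_conc = 1),
                              surgery_week = 0)
  expect_error(post_resection_drop(only_base), "untestable")
})

test_that("default relapsing trajectories drop in both channels after surgery", {
  drops <- vapply(1:20, function(s) {
    ps <- generate_patient_series(trajectory_config(seed = 700 + s))
    all(post_resection_drop(ps))
  }, logical(1))
  expect_gte(mean(drops), 0.95)
})

test_that("ROC AUC equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(roc_auc(c(3, 5), c(1, 4)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)   # total ties
  set.seed(77)
  for (i in 1:30) {
    n1 <- sample(1:120, 1); n0 <- sample(1:80, 1)
    # integer-valued draws force ties
    cases <- sample(0:15, n1, replace = TRUE)
    controls <- sample(0:15, n0, replace = TRUE)
    expect_equal(roc_auc(cases, controls), brute_auc(cases, controls))
  }
  expect_error(roc_auc(numeric(0), 1:3), "at least one")
})

test_that("ROC AUC matches pROC on continuous data", {
  skip_if_not_installed("pROC")
  set.seed(78)
  cases <- rlnorm(16, 5, 1)
  controls <- rlnorm(8, 3, 1)
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 16), rep(0, 8)),
    predictor = c(cases, controls), quiet = TRUE, direction = "<"))
  expect_equal(roc_auc(cases, controls), as.numeric(ref))
})

test_that("bootstrap CI is deterministic under seed and honest about degeneracy", {
  cases <- c(10, 12, 15, 20); controls <- c(1, 2, 3)
  expect_warning(r1 <- bootstrap_auc_ci(cases, controls, n_boot = 200,
                                        seed = 5),
                 "degenerate")
  expect_equal(c(r1$ci_low, r1$ci_high), c(1, 1))  # perfectly separated

  set.seed(79)
  cs <- rnorm(16, 2); ct <- rnorm(8)
  r2 <- bootstrap_auc_ci(cs, ct, n_boot = 500, seed = 11)
  r3 <- bootstrap_auc_ci(cs, ct, n_boot = 500, seed = 11)
  expect_identical(r2, r3)
  r4 <- bootstrap_auc_ci(cs, ct, n_boot = 500, seed = 12)
  expect_false(identical(r2$ci_low, r4$ci_low))
  expect_error(bootstrap_auc_ci(cs, ct, n_boot = 50), "n_boot")
})

test_that("bootstrap CI brackets the empirical AUC and matches an oracle's width", {
  set.seed(80)
  cases <- rlnorm(16, 5, 1.2)
  controls <- rlnorm(8, 3, 1)
  res <- bootstrap_auc_ci(cases, controls, n_boot = 2000, seed = 21)
  expect_lte(res$ci_low, res$auc)
  expect_gte(res$ci_high, res$auc)

  # independent stratified-percentile oracle, written from scratch
  set.seed(4242)
  b <- vapply(1:2000, function(i) {
    brute_auc(cases[sample.int(16, replace = TRUE)],
              controls[sample.int(8, replace = TRUE)])
  }, numeric(1))
  oracle_ci <- unname(stats::quantile(b, c(0.025, 0.975)))
  width <- res$ci_high - res$ci_low
  oracle_width <- oracle_ci[2] - oracle_ci[1]
  expect_lt(abs(width - oracle_width), 0.05)
  expect_lt(abs(res$ci_low - oracle_ci[1]), 0.05)
})
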