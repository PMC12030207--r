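
test_that("crossover BE analysis handles degenerate and mirrored data", {
  mk <- function(d, n = 12, mu = log(20)) {
    data.frame(id = rep(seq_len(n), 2),
               treatment = rep(c("T", "R"), each = n),
               log_cmax = c(mu + d, rep(mu, n)))
  }
  out0 <- crossover_be(mk(rep(0, 12)))
  expect_equal(out0$GMR, 100)
  expect_equal(unname(out0$CI90), c(100, 100))
  expect_equal(out0$decision, "BE")
  expect_equal(out0$WSV_CV, 0)

  out70 <- crossover_be(mk(rep(log(0.7), 12)))
  expect_equal(out70$GMR, 70)
  expect_equal(unname(out70$CI90), c(70, 70), tolerance = 1e-10)
  expect_equal(out70$decision, "not-BE")

  # swapping T and R maps GMR -> 1/GMR and mirrors the CI on the log scale
  set.seed(404)
  d <- stats::rnorm(12, log(0.9), 0.1)
  rec <- mk(d)
  swapped <- rec
  swapped$treatment <- ifelse(rec$treatment == "T", "R", "T")
  a <- crossover_be(rec); b <- crossover_be(swapped)
  expect_equal(a$GMR * b$GMR, 100^2, tolerance = 1e-9)
  expect_equal(sort(log(a$CI90 / 100)), sort(-log(b$CI90 / 100)),
               tolerance = 1e-9)
  expect_equal(a$decision, b$decision)
  expect_error(crossover_be(mk(rep(0, 2), n = 2)), "insufficient")
})

test_that("variance components decompose replicated log-Cmax correctly", {
  eq <- data.frame(id = rep(1:5, each = 2), period = rep(1:2, 5),
                   log_cmax = 3)
  vc <- estimate_variance_components(eq)
  expect_equal(vc$WSV_CV, 0)
  expect_equal(vc$BSV_CV, 0)

  two <- data.frame(id = rep(1:2, each = 2), period = rep(1:2, 2),
                    log_cmax = c(3, 3, 4, 4))
  vc2 <- estimate_variance_components(two)
  expect_equal(vc2$WSV_CV, 0)
  expect_gt(vc2$BSV_CV, 0)

  des <- trial_design(10000, n_periods = 2, seed = 17)
  d <- generate_pk_dataset(des, 1, WSV_CV = 15, BSV_CV = 20)
  vc3 <- estimate_variance_components(d)
  expect_lt(abs(vc3$WSV_CV - 15), 0.5)
  expect_lt(abs(vc3$BSV_CV - 20), 0.5)

  expect_error(estimate_variance_components(
    data.frame(id = 1:3, period = 1, log_cmax = 1:3)), "2 periods")
})

test_that("closed-form sample sizes reproduce the planning table", {
  for (i in seq_len(nrow(fix_table4))) {
    expect_identical(sample_size(fix_table4$GMR_pct[i] / 100, fix_table4$WSV_CV[i], 0.80),
                     fix_table4$n_80[i])
    expect_identical(sample_size(fix_table4$GMR_pct[i] / 100, fix_table4$WSV_CV[i], 0.90),
                     fix_table4$n_90[i])
  }
  expect_error(sample_size(0.80, 15, 0.8), "zero power")
  expect_error(sample_size(1.30, 15, 0.8), "zero power")
})

test_that("sample size is monotone in GMR distance, CV, and power", {
  cvs <- c(10, 15, 20, 30)
  gmrs <- c(0.85, 0.88, 0.92, 0.95, 1.0)
  for (cv in cvs) {
    n_g <- vapply(gmrs, function(g) sample_size(g, cv, 0.8), numeric(1))
    expect_true(all(diff(n_g) <= 0))            # closer to 1 -> fewer subjects
    expect_true(all(vapply(gmrs, function(g)
      sample_size(g, cv, 0.9) >= sample_size(g, cv, 0.8), logical(1))))
  }
  for (g in gmrs) {
    n_cv <- vapply(cvs, function(cv) sample_size(g, cv, 0.8), numeric(1))
    expect_true(all(diff(n_cv) >= 0))
  }
  # exact noncentral-t iteration lands within a step or two of the closed form
  n_cf <- sample_size(0.85, 14.89, 0.8)
  n_x <- sample_size(0.85, 14.89, 0.8, method = "nct")
  expect_lte(abs(n_x - n_cf), 4)
  expect_gte(tost_power(0.85, 14.89, n_x), 0.80)
})

test_that("predicted confidence intervals reproduce the planning table", {
  named <- c(2, 4, 12)   # R 85/n74, R 90/n20, S 95/n8: exact at 2 dp
  for (i in seq_len(nrow(fix_table4))) {
    ci <- predict_ci(fix_table4$GMR_pct[i] / 100, fix_table4$WSV_CV[i], fix_table4$n_80[i])
    if (i %in% named) {
      expect_equal(round(unname(ci), 2), c(fix_table4$LL[i], fix_table4$UL[i]))
    } else {
      # printed values can carry a last-digit rounding difference
      expect_lt(max(abs(unname(ci) - c(fix_table4$LL[i], fix_table4$UL[i]))), 0.011)
    }
  }
})

test_that("predicted CI is log-symmetric and collapses as CV vanishes", {
  ci <- predict_ci(0.9, 18, 24)
  expect_equal(log(ci[["LL"]] / 90), -log(ci[["UL"]] / 90), tolerance = 1e-12)
  ci0 <- predict_ci(0.9, 1e-9, 24)
  expect_equal(unname(ci0), c(90, 90), tolerance = 1e-6)
  expect_error(predict_ci(0.9, 15, 3), "insufficient df")
})
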