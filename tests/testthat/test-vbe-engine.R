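# small mechanistic configuration: coarse PSD and modest trials keep the
# ODE workload manageable while exercising the full pipeline
small_cfg <- function(vspec = variability_default()) {
  model_config(drug = fix_drug, particles = fix_psd5, vspec = vspec)
}

test_that("identical products with no variability sit inside the safe space", {
  cfg <- small_cfg(variability_none())
  des <- trial_design(4, seed = 77)
  ss <- map_safe_space(6.02, pH_grid = c(5.9, 6.02, 6.2), design = des,
                       cfg = cfg, refine = FALSE)
  at_ref <- ss$grid[ss$grid$test_pH == 6.02 & ss$grid$analyte == "R", ]
  expect_equal(at_ref$GMR, 100, tolerance = 1e-6)
  expect_true(at_ref$BE)
  expect_true(ss$interval["lo"] <= 6.02 && ss$interval["hi"] >= 6.02)
})

test_that("safe-space GMR is monotone in test surface pH and obeys the CI rule", {
  vs <- variability_default()
  vs$cv_pct[vs$cv_pct == 150] <- 40    # damp the heavy MRT tails at tiny n
  cfg <- small_cfg(vs)
  des <- trial_design(6, seed = 123)
  ss <- map_safe_space(6.02, pH_grid = c(5.5, 5.8, 6.1), design = des,
                       cfg = cfg, refine = FALSE)
  for (an in c("R", "S", "racemate")) {
    g <- ss$grid[ss$grid$analyte == an, ]
    g <- g[order(g$test_pH), ]
    expect_true(all(diff(g$GMR) >= -1e-9))
  }
  # reported BE flags must equal the CI rule applied to the reported bounds
  expect_equal(ss$grid$BE, ss$grid$LL >= 80 & ss$grid$UL <= 125)
})

test_that("replicated campaigns are seed-stable with coherent bookkeeping", {
  cfg <- small_cfg(variability_none())
  camp <- run_vbe_campaign(4, runs = 2, replicates = 2,
                           test_surface_pH = 6.02, reference_surface_pH = 6.02,
                           cfg = cfg, seed = 5)
  # no variability, identical products: every replicate passes
  expect_equal(unname(camp$success_rate), c(100, 100, 100))
  expect_equal(nrow(camp$records), 2 * 2 * 3)
  # per-run rates average to the campaign rate exactly
  for (an in c("R", "S", "racemate")) {
    pr <- camp$per_run$success_rate[camp$per_run$analyte == an]
    expect_equal(mean(pr), unname(camp$success_rate[an]))
  }
  camp2 <- run_vbe_campaign(4, 2, 2, 6.02, 6.02, cfg = cfg, seed = 5)
  expect_identical(camp$records, camp2$records)
  expect_true(all(camp$records$seed == bitwXor(5L + 7919L * camp$records$run,
                                               camp$records$replicate)))
})

test_that("a hopeless formulation never passes", {
  cfg <- small_cfg(variability_none())
  camp <- run_vbe_campaign(4, 1, 2, test_surface_pH = 4.6,
                           reference_surface_pH = 6.02, cfg = cfg, seed = 9)
  expect_equal(unname(camp$success_rate), c(0, 0, 0))
})

test_that("empirical success rate matches closed-form power on exact lognormal data", {
  # trials drawn from the very model the power formula assumes
  gmr <- 0.95; cv <- 15; n <- 12; n_trials <- 400
  passes <- vapply(seq_len(n_trials), function(i) {
    d <- generate_pk_dataset(trial_design(n, seed = 1000 + i), gmr, cv, 20)
    crossover_be(d)$decision == "BE"
  }, logical(1))
  rate <- 100 * mean(passes)
  chk <- success_rate_vs_power_check(rate, n_trials, gmr, cv, n)
  expect_true(chk$consistent)
  expect_equal(chk$empirical_pct - chk$power_pct, chk$discrepancy_pct)
  # binomial arithmetic: at N = 100 and p ~ 0.8 the 95% band is ~ +/- 8 points
  chk100 <- success_rate_vs_power_check(80, 100, 0.85, 14.89, 74)
  expect_lt(chk100$binomial_ci_pct[1], 80)
  expect_gt(chk100$binomial_ci_pct[2], 80)
  expect_true(diff(chk100$binomial_ci_pct) < 18)
})
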