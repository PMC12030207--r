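test_that("dissolution spec validation rejects malformed experiments", {
  expect_error(synthetic_dissolution_spec(6, sampling_times_h = numeric(0)),
               "non-empty")
  expect_error(synthetic_dissolution_spec(6, sampling_times_h = c(1, 0.5)),
               "increasing")
  expect_error(synthetic_dissolution_spec(6, sampling_times_h = 1, noise_sd = -1),
               "noise_sd")
  expect_error(synthetic_dissolution_spec(15, sampling_times_h = 1),
               "true_surface_pH")
  expect_error(synthetic_dissolution_spec(6, pretreatment_pH = 2,
                                          pretreatment_duration_h = -1,
                                          sampling_times_h = 1),
               "pretreatment")
})

test_that("noise-free generation equals the deterministic forward model", {
  spec <- synthetic_dissolution_spec(5.8, pretreatment_pH = 2.0,
                                     sampling_times_h = fix_times, noise_sd = 0)
  gen <- suppressWarnings(generate_dissolution_profile(spec, fix_drug, fix_psd8))
  fwd <- quiet_sim(fix_drug, fix_psd8,
                   two_stage_protocol(treatment_h = max(fix_times) - 0.5),
                   5.8, times_h = fix_times)
  expect_identical(gen$f_dissolved_pct, fwd$f_dissolved_pct)
})

test_that("noisy generation is seed-deterministic and clipped to [0, 100]", {
  spec <- function(seed, sd = 3) {
    synthetic_dissolution_spec(6.3, sampling_times_h = seq(0.1, 3, by = 0.15),
                               noise_sd = sd, seed = seed)
  }
  g1 <- suppressWarnings(generate_dissolution_profile(spec(7), fix_drug, fix_psd8))
  g2 <- suppressWarnings(generate_dissolution_profile(spec(7), fix_drug, fix_psd8))
  g3 <- suppressWarnings(generate_dissolution_profile(spec(8), fix_drug, fix_psd8))
  expect_identical(g1$f_dissolved_pct, g2$f_dissolved_pct)
  expect_false(identical(g1$f_dissolved_pct, g3$f_dissolved_pct))
  # at high surface pH the clean profile sits at 100%: noise must not exceed it
  big <- suppressWarnings(generate_dissolution_profile(spec(9, sd = 10),
                                                       fix_drug, fix_psd8))
  expect_true(all(big$f_dissolved_pct <= 100 & big$f_dissolved_pct >= 0))
})

test_that("complete dissolution is reached when solubility dwarfs dose/volume", {
  spec <- synthetic_dissolution_spec(7.5, sampling_times_h = c(0.5, 1, 2, 4),
                                     noise_sd = 0)
  gen <- suppressWarnings(generate_dissolution_profile(spec, fix_drug, fix_psd8))
  expect_equal(utils::tail(gen$f_dissolved_pct, 1), 100, tolerance = 1e-6)
})

test_that("synthetic crossover Cmax data carry the specified effects", {
  # no variability: all values equal across subjects and periods
  d0 <- generate_pk_dataset(trial_design(8, seed = 1), true_GMR = 1,
                            WSV_CV = 0, BSV_CV = 0)
  expect_equal(stats::sd(d0$log_cmax), 0)
  # law of large numbers: empirical GMR within 1% of the truth
  dbig <- generate_pk_dataset(trial_design(10000, seed = 2), true_GMR = 0.85,
                              WSV_CV = 14.89, BSV_CV = 20)
  gmr <- exp(mean(dbig$log_cmax[dbig$treatment == "T"]) -
             mean(dbig$log_cmax[dbig$treatment == "R"]))
  expect_lt(abs(gmr - 0.85), 0.01 * 0.85)
  expect_error(generate_pk_dataset(trial_design(4, seed = 1), 0, 10, 10),
               "true_GMR")
})

test_that("replicate-design data recover the within-subject CV", {
  des <- trial_design(10000, n_periods = 4, seed = 3)
  d <- generate_pk_dataset(des, true_GMR = 1, WSV_CV = 14.89, BSV_CV = 20)
  vc <- estimate_variance_components(d)
  expect_lt(abs(vc$WSV_CV - 14.89), 0.5)
})
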