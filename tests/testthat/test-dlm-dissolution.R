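test_that("weak-acid surface solubility follows the Henderson-Hasselbalch form", {
  expect_equal(surface_solubility(fix_drug, fix_drug$pKa), 2 * fix_drug$S0)
  # fully unionized limit: 3 pH units below pKa adds only 0.1%
  expect_equal(surface_solubility(fix_drug, fix_drug$pKa - 3), fix_drug$S0,
               tolerance = 1e-3)
  # direct formula at the reference-product estimate
  expect_equal(surface_solubility(fix_drug, 6.02), 0.068 * (1 + 10^1.57),
               tolerance = 1e-10)
  # strictly increasing in surface pH
  s <- surface_solubility(fix_drug, seq(3, 8, by = 0.25))
  expect_true(all(diff(s) > 0))
  expect_error(surface_solubility(fix_drug, 14.5), "0, 14")
})

test_that("monodisperse sink-condition dissolution matches the analytic solution", {
  # closed form computed inline, independently of the package helper:
  # h = min(r, h_max); while r >= h_max the radius shrinks linearly,
  # afterwards r^2 decays linearly
  analytic <- function(r0_um, pH, h_um, tt) {
    S <- fix_drug$S0 * (1 + 10^(pH - fix_drug$pKa)) * 1e-3
    k <- fix_drug$D * 60 * S / fix_drug$rho
    r0 <- r0_um * 1e-4; h <- h_um * 1e-4
    r <- vapply(tt, function(t) {
      if (r0 <= h) return(sqrt(max(r0^2 - 2 * k * t, 0)))
      t_lin <- (r0 - h) * h / k
      if (t <= t_lin) r0 - k * t / h else sqrt(max(h^2 - 2 * k * (t - t_lin), 0))
    }, numeric(1))
    100 * (1 - (r / r0)^3)
  }
  cases <- list(list(r0 = 35, h = 30, tt = seq(0.005, 0.09, by = 0.005)),
                list(r0 = 80, h = 10, tt = seq(0.02, 0.4, by = 0.02)))
  for (cs in cases) {
    sim <- simulate_dissolution(fix_drug, psd(cs$r0, 1, fix_drug),
                                sink_protocol(), 6.02, h_max_um = cs$h,
                                times_h = cs$tt)
    expect_lt(max(abs(sim$f_dissolved_pct - analytic(cs$r0, 6.02, cs$h, cs$tt))),
              0.5)
    # package closed-form helper agrees with the inline derivation
    expect_equal(dissolution_sink_closed_form(fix_drug, cs$r0, 6.02, cs$h, cs$tt),
                 analytic(cs$r0, 6.02, cs$h, cs$tt), tolerance = 1e-12)
  }
})

test_that("dissolution respects mass balance, monotone time course, and saturation", {
  # protocol ends at the last sample so the final radii match the last fraction
  prot2 <- two_stage_protocol(treatment_h = max(fix_times) - 0.5)
  sim <- quiet_sim(fix_drug, fix_psd8, prot2, 5.6, times_h = fix_times)
  expect_true(all(diff(sim$f_dissolved_pct) >= -1e-9))
  # algebraic mass closure: solid implied by final radii + dissolved = dose
  r_end <- attr(sim, "final_radii_um") * 1e-4
  solid <- sum(fix_psd8$number * fix_drug$rho * (4 / 3) * pi * r_end^3 * 1e3)
  diss <- utils::tail(sim$f_dissolved_pct, 1) / 100 * fix_drug$dose
  expect_lt(abs(solid + diss - fix_drug$dose), 1e-5 * fix_drug$dose)

  # tiny vessel: dissolution plateaus at the surface-solubility cap,
  # never exceeding it (gradient clamp, no negative dissolution)
  prot_small <- dissolution_protocol(list(protocol_stage("sat", 6.5, 10, 2)))
  ssat <- quiet_sim(fix_drug, fix_psd8, prot_small, 5.0,
                    times_h = seq(0.1, 2, by = 0.1))
  cap <- 100 * surface_solubility(fix_drug, 5.0) * 10 / fix_drug$dose
  expect_true(all(diff(ssat$f_dissolved_pct) >= -5e-4))
  expect_lt(max(ssat$f_dissolved_pct), cap * 1.001)
  expect_gt(utils::tail(ssat$f_dissolved_pct, 1), cap * 0.98)
})

test_that("finer particles and higher surface pH dissolve faster", {
  tt <- c(0.1, 0.25, 0.5, 1)
  coarse <- psd(40, 1, fix_drug)
  # same dose split over 2x particles => radius / 2^(1/3)
  fine <- psd(40 / 2^(1 / 3), 1, fix_drug)
  f_c <- quiet_sim(fix_drug, coarse, fix_protocol, 5.8, times_h = tt)
  f_f <- quiet_sim(fix_drug, fine, fix_protocol, 5.8, times_h = tt)
  expect_true(all(f_f$f_dissolved_pct >= f_c$f_dissolved_pct - 1e-6))

  ph_grid <- c(5.3, 5.7, 6.1, 6.5)
  profs <- lapply(ph_grid, function(ph)
    quiet_sim(fix_drug, fix_psd8, fix_protocol, ph, times_h = tt)$f_dissolved_pct)
  for (i in seq_len(length(ph_grid) - 1)) {
    expect_true(all(profs[[i + 1]] >= profs[[i]] - 1e-6))
  }
})

test_that("r-squared goodness of fit behaves like a squared Pearson correlation", {
  expect_equal(goodness_r2(c(10, 50, 90), c(10, 50, 90)), 1.0)
  # affine transform of the observations still gives 1
  expect_equal(goodness_r2(c(10, 50, 90), 5 + 0.8 * c(10, 50, 90)), 1.0)
  # hand-computed from the definition
  obs <- c(10, 50, 90); pred <- c(20, 45, 85)
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(goodness_r2(obs, pred), r_hand^2, tolerance = 1e-12)
  expect_error(goodness_r2(c(50, 50, 50), c(10, 50, 90)), "zero variance")
  expect_error(goodness_r2(c(1, 2), c(1, 2)), "length")
})

test_that("surface-pH fitting recovers the generating value on clean profiles", {
  spec <- synthetic_dissolution_spec(6.02, pretreatment_pH = 2.0,
                                     sampling_times_h = fix_times,
                                     noise_sd = 0)
  prof <- suppressWarnings(
    generate_dissolution_profile(spec, fix_drug, fix_psd8))
  fit <- quiet_fit(prof, fix_drug, fix_psd8,
                   two_stage_protocol(treatment_h = max(fix_times) - 0.5),
                   init = 5.5)
  expect_lt(abs(fit$surface_pH - 6.02), 0.02)
  expect_gt(fit$r2, 0.999)
  expect_true(fit$acceptable)
  expect_true(fit$converged)
})

test_that("degenerate flat profiles are rejected by the fit", {
  flat <- data.frame(time_h = c(0.5, 1, 2), f_dissolved_pct = c(80, 80, 80))
  expect_error(
    fit_surface_pH(flat, fix_drug, fix_psd8, fix_protocol),
    "degenerate")
})
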