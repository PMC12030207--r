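#' Model configuration bundle for virtual-trial simulation
#'
#' Collects everything the mechanistic crossover simulator needs apart from
#' the products' surface pH: drug substance, particle population, GI
#' physiology, disposition, permeability, variability table and schedule.
#'
#' @param drug A [drug_substance()].
#' @param particles A [psd()].
#' @param gi GI physiology table.
#' @param disp Disposition pair.
#' @param vspec A [variability_spec()].
#' @param Peff Effective permeability, 1e-4 cm/s.
#' @param h_max_um Diffusion-layer cap, micrometres.
#' @param schedule_h Sampling schedule, hours.
#' @param solver_opts Solver options for [simulate_oral_dose()].
#' @return A list of class `model_config`.
#' @export
model_config <- function(drug = ibuprofen(), particles = NULL,
                         gi = gi_default(), disp = disposition_default(),
                         vspec = variability_default(), Peff = 5,
                         h_max_um = 30, schedule_h = clinical_schedule(),
                         solver_opts = list(atol = 1e-8, rtol = 1e-8)) {
  if (is.null(particles)) particles <- psd_lognormal(drug)
  structure(list(drug = drug, particles = particles, gi = gi, disp = disp,
                 vspec = vspec, Peff = Peff, h_max_um = h_max_um,
                 schedule_h = schedule_h, solver_opts = solver_opts),
            class = "model_config")
}

# run one mechanistic crossover trial and return per-analyte BE outcomes
trial_outcomes <- function(cfg, design, test_pH, ref_pH) {
  pop <- draw_population(cfg$vspec, design)
  rec <- run_crossover_trial(pop, cfg$drug, cfg$particles, test_pH, ref_pH,
                             gi = cfg$gi, disp = cfg$disp, Peff = cfg$Peff,
                             h_max_um = cfg$h_max_um,
                             schedule_h = cfg$schedule_h,
                             solver_opts = cfg$solver_opts)
  lapply(stats::setNames(nm = c("R", "S", "racemate")), function(an) {
    r <- rec[rec$analyte == an, ]
    r$id <- r$subject
    crossover_be(r, analyte = an)
  })
}

#' Map the in vitro safe space over test-product surface pH
#'
#' For each candidate test-product surface pH on a grid, simulates a
#' crossover trial against the reference product (same seed, hence the same
#' virtual population, at every grid point) and computes the per-analyte
#' GMR and 90% CI. The safe space is the maximal contiguous interval of the
#' grid whose 90% CI lies within 80.00-125.00% for the chosen analyte (the
#' R-enantiomer by default, being the more discriminative one); its
#' endpoints can be refined by bisection to 0.01 pH.
#'
#' @param reference_surface_pH Reference-product surface pH.
#' @param pH_grid Candidate test-product surface pH values, within (3, 8).
#' @param design A [trial_design()].
#' @param cfg A [model_config()].
#' @param analyte Analyte defining the interval (default `"R"`).
#' @param refine If `TRUE` (default), bisect the interval endpoints to
#'   `refine_tol` pH units.
#' @param refine_tol Endpoint resolution in pH units (default 0.01).
#' @return A `safe_space_result` list: `grid` (data frame: `test_pH`,
#'   `analyte`, `GMR`, `LL`, `UL`, `BE`), `interval` (named `c(lo, hi)` or
#'   `NULL` if empty), `analyte`, `reference_surface_pH`.
#' @export
map_safe_space <- function(reference_surface_pH, pH_grid, design, cfg,
                           analyte = "R", refine = TRUE, refine_tol = 0.01) {
  if (any(pH_grid <= 3 | pH_grid >= 8)) {
    stop("pH grid must lie within (3, 8)", call. = FALSE)
  }
  pH_grid <- sort(pH_grid)
  eval_point <- function(ph) {
    out <- trial_outcomes(cfg, design, test_pH = ph,
                          ref_pH = reference_surface_pH)
    do.call(rbind, lapply(out, function(o) {
      data.frame(test_pH = ph, analyte = o$analyte, GMR = o$GMR,
                 LL = o$CI90[1], UL = o$CI90[2],
                 BE = o$decision == "BE")
    }))
  }
  grid <- do.call(rbind, lapply(pH_grid, eval_point))
  rownames(grid) <- NULL
  ga <- grid[grid$analyte == analyte, ]
  pass <- ga$BE
  interval <- NULL
  if (any(pass)) {
    runs <- rle(pass)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which.max(ifelse(runs$values, runs$lengths, 0))
    i0 <- starts[best]; i1 <- ends[best]
    lo <- ga$test_pH[i0]; hi <- ga$test_pH[i1]
    pass_at <- function(ph) {
      o <- trial_outcomes(cfg, design, ph, reference_surface_pH)[[analyte]]
      o$decision == "BE"
    }
    if (refine) {
      if (i0 > 1) {
        lo <- bisect_edge(pass_at, ga$test_pH[i0 - 1], lo, refine_tol,
                          want_upper = TRUE)
      }
      if (i1 < nrow(ga)) {
        hi <- bisect_edge(pass_at, hi, ga$test_pH[i1 + 1], refine_tol,
                          want_upper = FALSE)
      }
    }
    interval <- c(lo = lo, hi = hi)
  }
  structure(list(grid = grid, interval = interval, analyte = analyte,
                 reference_surface_pH = reference_surface_pH),
            class = "safe_space_result")
}

# bisect between a failing and a passing pH; returns the passing-side edge
bisect_edge <- function(pass_at, fail_ph, pass_ph, tol, want_upper) {
  while (abs(pass_ph - fail_ph) > tol) {
    mid <- (fail_ph + pass_ph) / 2
    if (pass_at(mid)) pass_ph <- mid else fail_ph <- mid
  }
  pass_ph
}

#' Run a replicated virtual-bioequivalence campaign
#'
#' Executes `runs x replicates` independent virtual crossover trials
#' (`N = runs * replicates` total), each with a fresh virtual population.
#' Replicate seeds are `xor(run_seed, replicate_index)` with
#' `run_seed = seed + 7919 * run`, recorded in the output so that
#' seed-dependence of the success rate can be audited. The success rate per
#' analyte is `100 * (#BE) / N`, reported overall and per run.
#'
#' @param n_subjects Subjects per trial (even).
#' @param runs,replicates Campaign design; `runs * replicates` trials total.
#' @param test_surface_pH,reference_surface_pH Product surface pHs.
#' @param cfg A [model_config()].
#' @param seed Campaign base seed.
#' @param n_periods Periods per trial (default 2).
#' @return A `vbe_campaign` list: `records` (one row per trial x analyte:
#'   `run`, `replicate`, `seed`, `analyte`, `GMR`, `LL`, `UL`, `BE`),
#'   `success_rate` (percent, named by analyte), `per_run` (data frame),
#'   `n_subjects`, `design`.
#' @export
run_vbe_campaign <- function(n_subjects, runs, replicates,
                             test_surface_pH, reference_surface_pH,
                             cfg, seed = 1L, n_periods = 2) {
  if (runs < 1 || replicates < 1) stop("runs and replicates must be >= 1",
                                       call. = FALSE)
  recs <- list()
  for (run in seq_len(runs)) {
    run_seed <- seed + 7919L * run
    for (rep_i in seq_len(replicates)) {
      rep_seed <- bitwXor(run_seed, rep_i)
      design <- trial_design(n_subjects, n_periods,
                             schedule_h = cfg$schedule_h, seed = rep_seed)
      out <- trial_outcomes(cfg, design, test_surface_pH,
                            reference_surface_pH)
      recs[[length(recs) + 1L]] <- do.call(rbind, lapply(out, function(o) {
        data.frame(run = run, replicate = rep_i, seed = rep_seed,
                   analyte = o$analyte, GMR = o$GMR,
                   LL = o$CI90[1], UL = o$CI90[2],
                   BE = o$decision == "BE")
      }))
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  success <- 100 * vapply(c(R = "R", S = "S", racemate = "racemate"),
                          function(an) mean(records$BE[records$analyte == an]),
                          numeric(1))
  per_run <- stats::aggregate(BE ~ analyte + run, records,
                              function(b) 100 * mean(b))
  names(per_run)[names(per_run) == "BE"] <- "success_rate"
  structure(list(records = records,
                 success_rate = success,
                 per_run = per_run, n_subjects = n_subjects,
                 design = c(runs = runs, replicates = replicates)),
            class = "vbe_campaign")
}

#' Compare an empirical VBE success rate with closed-form TOST power
#'
#' Diagnostic (not a pass/fail test): contrasts the fraction of simulated
#' trials declared bioequivalent against the closed-form TOST power at the
#' same GMR, within-subject CV and sample size, with a binomial 95%
#' interval on the empirical rate.
#'
#' @param success_rate_pct Empirical success rate, percent.
#' @param n_trials Number of simulated trials behind the rate.
#' @param GMR Assumed ratio (fraction).
#' @param WSV_CV Within-subject CV, percent.
#' @param n Subjects per trial.
#' @return A list: `empirical_pct`, `binomial_ci_pct`, `power_pct`,
#'   `discrepancy_pct` (empirical minus power), `consistent` (logical:
#'   power falls inside the binomial interval).
#' @export
success_rate_vs_power_check <- function(success_rate_pct, n_trials,
                                        GMR, WSV_CV, n) {
  x <- round(success_rate_pct / 100 * n_trials)
  bt <- stats::binom.test(x, n_trials)
  power_pct <- 100 * tost_power(GMR, WSV_CV, n)
  ci <- 100 * as.numeric(bt$conf.int)
  list(empirical_pct = success_rate_pct,
       binomial_ci_pct = ci,
       power_pct = power_pct,
       discrepancy_pct = success_rate_pct - power_pct,
       consistent = power_pct >= ci[1] && power_pct <= ci[2])
}
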