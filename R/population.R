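#' Trial design for a crossover bioequivalence study
#'
#' @param n_subjects Total subjects; must be even (balanced TR/RT sequences)
#'   and >= 4.
#' @param n_periods Number of periods (2 for a standard crossover, 4 for a
#'   full replicate design).
#' @param schedule_h Plasma sampling schedule, hours.
#' @param seed Integer seed governing all randomness downstream.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_subjects = 24, n_periods = 2,
                         schedule_h = clinical_schedule(), seed = 1L) {
  if (n_subjects %% 2 != 0 || n_subjects < 4) {
    stop("n_subjects must be even and >= 4 for balanced sequences", call. = FALSE)
  }
  if (!n_periods %in% c(2, 4)) stop("n_periods must be 2 or 4", call. = FALSE)
  if (any(diff(schedule_h) <= 0)) {
    stop("schedule times must be strictly increasing", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_periods = as.integer(n_periods),
                 sequences = c("TR", "RT"),
                 schedule_h = schedule_h, seed = as.integer(seed)),
            class = "trial_design")
}

#' Variability specification for the virtual population
#'
#' One row per physiological/disposition parameter: the central value, the
#' lognormal CV (percent), truncation limits, and whether the parameter
#' carries within-subject variability (redrawn each period) in addition to
#' between-subject variability.
#'
#' @param table Data frame with columns `parameter`, `central`, `cv_pct`,
#'   `min`, `max`, `wsv` (logical).
#' @return An object of class `variability_spec`.
#' @export
variability_spec <- function(table) {
  need <- c("parameter", "central", "cv_pct", "min", "max", "wsv")
  stopifnot(all(need %in% names(table)))
  if (any(table$cv_pct < 0)) stop("CVs must be >= 0", call. = FALSE)
  if (any(table$min >= table$max)) stop("min must be < max for every limit pair",
                                        call. = FALSE)
  bad <- table$central <= table$min | table$central >= table$max
  if (any(bad)) {
    stop("specification error: central value outside (min, max) for ",
         paste(table$parameter[bad], collapse = ", "), call. = FALSE)
  }
  structure(table, class = c("variability_spec", "data.frame"))
}

#' Default variability table for fasted-state ibuprofen simulations
#'
#' The optimized variability settings: CV 150% on stomach and
#' small-intestinal mean residence times (fluid and fine particles) and CV
#' 10% on the steady-state volume of distribution, all carrying
#' within-subject variability (period-level redraws); GI pH (CV 6-16%) and
#' fluid volumes (CV 30%) carry between-subject variability only. Each
#' parameter is truncated to a physiologically plausible range by rejection
#' sampling.
#'
#' @return A [variability_spec()].
#' @export
variability_default <- function() {
  variability_spec(data.frame(
    parameter = c("mrt_stomach_fluid", "mrt_si_fluid",
                  "mrt_stomach_particles", "mrt_si_particles", "vss",
                  "ph_duodenum", "ph_jejunum1", "ph_jejunum2",
                  "ph_ileum1", "ph_ileum2", "ph_ileum3", "ph_ileum4",
                  "ph_colon", "vol_stomach", "vol_si", "vol_colon"),
    central = c(0.12, 3.4, 0.27, 3.4, 0.091249,
                6.4, 6.5, 6.6, 6.8, 7.0, 7.1, 7.3, 6.6, 50, 105, 13),
    cv_pct = c(150, 150, 150, 150, 10,
               16, 13, 11, 10, 10, 7, 6, 13, 30, 30, 0),
    min = c(0.01, 0.5, 0.01, 0.5, 0.05,
            0, 0, 0, 0, 0, 0, 0, 3.18, 20, 10, 1),
    max = c(12, 12, 12, 12, 1000,
            15, 15, 15, 15, 15, 15, 15, 9.8, 1000, 1000, 250),
    wsv = c(TRUE, TRUE, TRUE, TRUE, TRUE,
            rep(FALSE, 11)),
    stringsAsFactors = FALSE
  ))
}

# one truncated-lognormal draw vector: median `center`, CV `cv` (%), rejection
# sampling into (lo, hi); cv = 0 returns center exactly
rlnorm_trunc <- function(n, center, cv, lo, hi) {
  if (cv == 0) return(rep(center, n))
  s <- sqrt(log(1 + (cv / 100)^2))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- center * exp(stats::rnorm(length(todo), 0, s))
    ok <- x > lo & x < hi
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

#' Draw a virtual population for a crossover trial
#'
#' Subject-level parameter values are lognormal about the central value
#' (the central value is the population median) with the stated CV,
#' truncated to the plausible range by rejection sampling. Parameters
#' flagged `wsv` are redrawn each period with the same CV centred on the
#' subject's own value (hierarchical lognormal), again truncated.
#' Sequences alternate TR/RT by subject index for exact balance.
#' Demographics (sex, age) are drawn and recorded but do not enter the
#' disposition model unless body-weight scaling is enabled downstream.
#'
#' @param vspec A [variability_spec()].
#' @param design A [trial_design()].
#' @param female_proportion Fraction of female subjects (default 0.5).
#' @param age_range Two-element age range in years (default `c(20, 50)`).
#' @return A `virtual_population`: data frame with one row per subject and
#'   period; columns `subject`, `sequence`, `period`, `sex`, `age`, then
#'   one column per parameter.
#' @export
draw_population <- function(vspec, design, female_proportion = 0.5,
                            age_range = c(20, 50)) {
  stopifnot(inherits(vspec, "variability_spec"), inherits(design, "trial_design"))
  if (female_proportion < 0 || female_proportion > 1) {
    stop("female_proportion must lie in [0, 1]", call. = FALSE)
  }
  n <- design$n_subjects
  np <- design$n_periods
  local_seed(design$seed, {
    sex <- ifelse(stats::runif(n) < female_proportion, "F", "M")
    age <- stats::runif(n, age_range[1], age_range[2])
    subj <- lapply(seq_len(nrow(vspec)), function(i) {
      rlnorm_trunc(n, vspec$central[i], vspec$cv_pct[i],
                   vspec$min[i], vspec$max[i])
    })
    names(subj) <- vspec$parameter
    out <- data.frame(subject = rep(seq_len(n), each = np),
                      sequence = rep(rep(c("TR", "RT"), length.out = n), each = np),
                      period = rep(seq_len(np), times = n),
                      sex = rep(sex, each = np), age = rep(age, each = np))
    for (i in seq_len(nrow(vspec))) {
      base <- rep(subj[[i]], each = np)
      if (vspec$wsv[i] && vspec$cv_pct[i] > 0) {
        # period-level redraw with truncation, centred on the subject value
        out[[vspec$parameter[i]]] <- vapply(seq_along(base), function(j) {
          rlnorm_trunc(1, base[j], vspec$cv_pct[i], vspec$min[i], vspec$max[i])
        }, numeric(1))
      } else {
        out[[vspec$parameter[i]]] <- base
      }
    }
    class(out) <- c("virtual_population", "data.frame")
    out
  })
}

#' Simulate a crossover trial through the mechanistic model
#'
#' For every subject and period, runs [simulate_oral_dose()] with that
#' period's physiological parameter draw and the surface pH of the product
#' assigned by the subject's sequence, then extracts Cmax and tmax per
#' analyte (R, S, racemate).
#'
#' @param population A [draw_population()] result.
#' @param drug A [drug_substance()].
#' @param particles A [psd()].
#' @param surface_pH_test,surface_pH_ref Particle surface pH of the test and
#'   reference products, each in (3, 8).
#' @param gi Base [gi_default()]-style physiology table.
#' @param disp Base disposition pair from [disposition_default()].
#' @param Peff Effective permeability, 1e-4 cm/s.
#' @param h_max_um Diffusion-layer cap, micrometres.
#' @param schedule_h Sampling schedule, hours.
#' @param solver_opts Solver options forwarded to [simulate_oral_dose()].
#' @return A data frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `analyte`, `cmax`, `tmax`, `log_cmax`.
#' @export
run_crossover_trial <- function(population, drug, particles,
                                surface_pH_test, surface_pH_ref,
                                gi = gi_default(), disp = disposition_default(),
                                Peff = 5, h_max_um = 30,
                                schedule_h = clinical_schedule(),
                                solver_opts = list()) {
  for (ph in c(surface_pH_test, surface_pH_ref)) {
    if (ph <= 3 || ph >= 8) stop("surface pH must lie in (3, 8)", call. = FALSE)
  }
  rows <- vector("list", nrow(population) * 3L)
  k <- 0L
  for (j in seq_len(nrow(population))) {
    row <- population[j, ]
    trt <- crossover_pattern(row$sequence, max(population$period))[row$period]
    pH <- if (trt == "T") surface_pH_test else surface_pH_ref
    gi_j <- apply_physiology(gi, row)
    disp_j <- apply_disposition(disp, row)
    prof <- tryCatch(
      simulate_oral_dose(drug, particles, gi_j, pH, disp_j, Peff = Peff,
                         schedule_h = schedule_h, h_max_um = h_max_um,
                         solver_opts = solver_opts),
      error = function(e) {
        stop("simulation failed for subject ", row$subject, " period ",
             row$period, ": ", conditionMessage(e), call. = FALSE)
      })
    for (an in c("R", "S", "racemate")) {
      cm <- extract_cmax_tmax(prof, an)
      k <- k + 1L
      rows[[k]] <- data.frame(subject = row$subject, sequence = row$sequence,
                              period = row$period, treatment = trt,
                              analyte = an, cmax = cm$cmax, tmax = cm$tmax,
                              log_cmax = log(cm$cmax))
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

# map a population row's parameters onto the GI physiology table
apply_physiology <- function(gi, row) {
  g <- gi
  scl <- function(col, name, idx, total) {
    if (!is.null(row[[name]])) g[idx, col] <<- g[idx, col] * row[[name]] / total
  }
  i_st <- g$name == "stomach"
  i_si <- g$name %in% c("duodenum", "jejunum1", "jejunum2",
                        "ileum1", "ileum2", "ileum3", "ileum4")
  if (!is.null(row$mrt_stomach_fluid)) g$mrt_fluid_h[i_st] <- row$mrt_stomach_fluid
  if (!is.null(row$mrt_stomach_particles)) g$mrt_particle_h[i_st] <- row$mrt_stomach_particles
  scl("mrt_fluid_h", "mrt_si_fluid", i_si, 3.4)
  scl("mrt_particle_h", "mrt_si_particles", i_si, 3.4)
  if (!is.null(row$vol_stomach)) g$volume_mL[i_st] <- row$vol_stomach
  scl("volume_mL", "vol_si", g$name %in% c("jejunum1", "jejunum2", "ileum1",
                                           "ileum2", "ileum3", "ileum4"), 105)
  if (!is.null(row$vol_colon)) g$volume_mL[g$name == "colon"] <- row$vol_colon
  for (seg in c("duodenum", "jejunum1", "jejunum2", "ileum1", "ileum2",
                "ileum3", "ileum4", "colon")) {
    nm <- paste0("ph_", seg)
    if (!is.null(row[[nm]])) g$pH[g$name == seg] <- row[[nm]]
  }
  g
}

apply_disposition <- function(disp, row) {
  if (!is.null(row$vss)) {
    disp$R$Vss_L_kg <- row$vss
    disp$S$Vss_L_kg <- row$vss
  }
  disp
}
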