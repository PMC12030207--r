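#' Specify a synthetic dissolution experiment
#'
#' Describes one in vitro condition to emulate: the true particle surface
#' pH driving the forward model, the treatment medium pH, an optional
#' acidic pretreatment stage, the sampling times, and the additive
#' measurement noise on fraction dissolved.
#'
#' @param true_surface_pH True particle surface pH, in (0, 14).
#' @param medium_pH Treatment medium pH.
#' @param pretreatment_pH pH of the HCl pretreatment, or `NA` for none.
#' @param pretreatment_duration_h Pretreatment duration, h.
#' @param sampling_times_h Strictly increasing nonnegative sampling times, h.
#' @param noise_sd Additive Gaussian noise SD on fraction dissolved, percent.
#' @param seed Integer seed recorded with the spec.
#' @param volume_mL Vessel volume, mL.
#' @return An object of class `synthetic_dissolution_spec`.
#' @export
synthetic_dissolution_spec <- function(true_surface_pH, medium_pH = 6.5,
                                       pretreatment_pH = NA,
                                       pretreatment_duration_h = 0.5,
                                       sampling_times_h,
                                       noise_sd = 0, seed = 1L,
                                       volume_mL = 900) {
  if (!length(sampling_times_h)) {
    stop("invalid specification: sampling times must be non-empty", call. = FALSE)
  }
  if (any(sampling_times_h < 0) || any(diff(sampling_times_h) <= 0)) {
    stop("invalid specification: sampling times must be nonnegative and strictly increasing",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("invalid specification: noise_sd must be >= 0", call. = FALSE)
  if (true_surface_pH <= 0 || true_surface_pH >= 14) {
    stop("invalid specification: true_surface_pH must lie in (0, 14)", call. = FALSE)
  }
  if (!is.na(pretreatment_pH) && pretreatment_duration_h <= 0) {
    stop("invalid specification: pretreatment duration must be positive", call. = FALSE)
  }
  structure(list(true_surface_pH = true_surface_pH, medium_pH = medium_pH,
                 pretreatment_pH = pretreatment_pH,
                 pretreatment_duration_h = pretreatment_duration_h,
                 sampling_times_h = sampling_times_h, noise_sd = noise_sd,
                 seed = as.integer(seed), volume_mL = volume_mL),
            class = "synthetic_dissolution_spec")
}

#' Generate a synthetic dissolution profile with known true surface pH
#'
#' Forward-simulates the diffusion layer model at the spec's true surface
#' pH under the implied staged protocol, then adds additive Gaussian noise
#' (SD `noise_sd` percentage points) and clips to `[0, 100]`. With
#' `noise_sd = 0` the output equals the deterministic forward solution.
#'
#' @param spec A [synthetic_dissolution_spec()].
#' @param drug A [drug_substance()].
#' @param particles A [psd()] consistent with the drug dose.
#' @param product Product label stored on the profile.
#' @param h_max_um Diffusion-layer thickness cap, micrometres.
#' @return A `dissolution_profile` data frame (`time_h`,
#'   `f_dissolved_pct`, `stage`) with the generating spec attached as
#'   attribute `spec`.
#' @export
generate_dissolution_profile <- function(spec, drug, particles,
                                         product = "reference", h_max_um = 30) {
  stopifnot(inherits(spec, "synthetic_dissolution_spec"))
  pre_h <- if (is.na(spec$pretreatment_pH)) 0 else spec$pretreatment_duration_h
  horizon <- max(spec$sampling_times_h)
  if (horizon <= pre_h) {
    stop("invalid specification: sampling must extend beyond the pretreatment",
         call. = FALSE)
  }
  protocol <- two_stage_protocol(medium = "medium", medium_pH = spec$medium_pH,
                                 pretreatment_pH = spec$pretreatment_pH,
                                 pretreatment_h = pre_h,
                                 treatment_h = horizon - pre_h,
                                 volume_mL = spec$volume_mL)
  prof <- simulate_dissolution(drug, particles, protocol,
                               surface_pH = spec$true_surface_pH,
                               h_max_um = h_max_um,
                               times_h = spec$sampling_times_h,
                               product = product)
  if (spec$noise_sd > 0) {
    prof$f_dissolved_pct <- local_seed(spec$seed, {
      pmin(pmax(prof$f_dissolved_pct +
                  stats::rnorm(nrow(prof), 0, spec$noise_sd), 0), 100)
    })
  }
  attr(prof, "spec") <- spec
  prof
}

#' Generate a synthetic crossover Cmax dataset with known variance components
#'
#' Draws per-subject, per-period log-Cmax values from the lognormal
#' crossover model: subject effect with variance `ln(1 + BSV_CV^2)`, a
#' formulation effect `ln(GMR)` on test periods, and a residual with
#' variance `ln(1 + WSV_CV^2)`. Used to validate the bioequivalence
#' statistics independently of the mechanistic pipeline.
#'
#' @param design A [trial_design()]; `n_periods` 2 for a 2x2 crossover or
#'   4 for a full replicate (TRTR/RTRT) design.
#' @param true_GMR True test/reference geometric mean ratio (> 0).
#' @param WSV_CV Within-subject CV, percent.
#' @param BSV_CV Between-subject CV, percent.
#' @param mu_log Log geometric mean of the reference Cmax (default
#'   `log(20)` mg/L).
#' @return A data frame with columns `id`, `sequence`, `period`,
#'   `treatment`, `log_cmax`, `cmax`.
#' @export
generate_pk_dataset <- function(design, true_GMR, WSV_CV, BSV_CV,
                                mu_log = log(20)) {
  stopifnot(inherits(design, "trial_design"))
  if (true_GMR <= 0) stop("true_GMR must be > 0", call. = FALSE)
  if (WSV_CV < 0 || BSV_CV < 0) stop("CVs must be >= 0", call. = FALSE)
  if (design$n_subjects < 3) {
    stop("too few subjects: downstream confidence intervals need n >= 3",
         call. = FALSE)
  }
  n <- design$n_subjects
  np <- design$n_periods
  sw <- sqrt(log(1 + (WSV_CV / 100)^2))
  sb <- sqrt(log(1 + (BSV_CV / 100)^2))
  local_seed(design$seed, {
    subj_eff <- stats::rnorm(n, 0, sb)
    seqs <- rep(c("TR", "RT"), length.out = n)
    id <- rep(seq_len(n), each = np)
    period <- rep(seq_len(np), times = n)
    treatment <- unlist(lapply(seqs, crossover_pattern, np = np),
                        use.names = FALSE)
    lc <- mu_log + subj_eff[id] + (treatment == "T") * log(true_GMR) +
      stats::rnorm(n * np, 0, sw)
    data.frame(id = id, sequence = seqs[id], period = period,
               treatment = treatment, log_cmax = lc, cmax = exp(lc))
  })
}

# treatment pattern for a sequence label over np periods (TR -> TRTR...)
crossover_pattern <- function(sequence, np) {
  base <- strsplit(sequence, "")[[1]]
  rep(base, length.out = np)
}

# evaluate expr with a temporary RNG state seeded by `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
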