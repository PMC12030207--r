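#' Simulate polydisperse particle dissolution with the diffusion layer model
#'
#' Integrates the per-bin shrinking-particle equations
#' `dr_i/dt = -(D / (rho * h_i)) * (S_surf - C_bulk)` with effective
#' diffusion-layer thickness `h_i = min(r_i, h_max)`, surface solubility
#' fixed by the particle surface pH for the whole run (the surface pH is
#' assumed constant), and bulk concentration `C_bulk = dissolved / volume`.
#' Dissolved mass and remaining solid carry over across protocol stages.
#'
#' The driving force is clamped at zero when `S_surf <= C_bulk`
#' (precipitation/particle growth is not modeled); if the bulk concentration
#' exceeds the bulk solubility at the medium pH a supersaturation warning is
#' raised. Internally the solver integrates `u_i = r_i^2`, which removes the
#' `1/r` stiffness as particles vanish; bins with radius below `r_min_um`
#' are declared fully dissolved. Dissolved mass is computed algebraically as
#' dose minus remaining solid, so mass is conserved to solver precision.
#'
#' @param drug A [drug_substance()].
#' @param particles A [psd()] consistent with the drug dose.
#' @param protocol A [dissolution_protocol()].
#' @param surface_pH Particle surface pH, fixed for the whole run.
#' @param h_max_um Maximum diffusion-layer thickness, micrometres (default 30).
#' @param times_h Output times in hours (default: dense grid over the
#'   protocol). Times are clipped to the protocol duration.
#' @param product Product label, `"reference"` or `"test"` (metadata).
#' @param solver_opts List with `atol` (mg-scale absolute tolerance,
#'   default 1e-9), `rtol` (default 1e-6), `r_min_um` (default 1e-3).
#' @return A `dissolution_profile`: data frame with columns `time_h`,
#'   `f_dissolved_pct`, `stage`, plus attributes `surface_pH`, `product`,
#'   `final_radii_um`.
#' @export
simulate_dissolution <- function(drug, particles, protocol, surface_pH,
                                 h_max_um = 30, times_h = NULL,
                                 product = "reference",
                                 solver_opts = list()) {
  stopifnot(inherits(drug, "drug_substance"), inherits(particles, "psd"),
            inherits(protocol, "dissolution_protocol"))
  if (surface_pH <= 0 || surface_pH >= 14) {
    stop("surface_pH must lie in (0, 14)", call. = FALSE)
  }
  opts <- modify_defaults(list(atol = 1e-9, rtol = 1e-6, r_min_um = 1e-3),
                          solver_opts)
  total_h <- protocol_duration(protocol)
  if (is.null(times_h)) times_h <- seq(0, total_h, length.out = 121)
  if (!length(times_h) || any(times_h < 0)) {
    stop("invalid specification: sampling times must be nonnegative and non-empty",
         call. = FALSE)
  }
  times_h <- pmin(times_h, total_h)

  S_surf <- surface_solubility(drug, surface_pH)      # mg/mL
  r_cm <- particles$radius_um * 1e-4
  h_max_cm <- h_max_um * 1e-4
  r_min_cm <- opts$r_min_um * 1e-4
  N <- particles$number
  D_cmh <- drug$D * 60                                 # cm^2/min -> cm^2/h
  rho <- drug$rho                                      # g/cm^3
  dose <- drug$dose
  # mg of solid at radii r (cm): N * rho * 4/3 pi r^3 * 1000
  solid_mass <- function(r) sum(N * rho * (4 / 3) * pi * r^3 * 1e3)

  u0 <- r_cm^2
  out_t <- numeric(0); out_f <- numeric(0); out_stage <- character(0)
  supersat <- FALSE
  t_off <- 0
  u <- u0
  for (si in seq_along(protocol$stages)) {
    st <- protocol$stages[[si]]
    S_bulk_cap <- surface_solubility(drug, st$pH)
    vol <- st$volume_mL
    rhs <- function(t, u, p) {
      r <- sqrt(pmax(u, 0))
      diss <- dose - solid_mass(r)
      C_bulk <- diss / vol
      grad <- max(S_surf - C_bulk, 0) * 1e-3           # mg/mL -> g/cm^3
      # du/dt = 2 r dr/dt with dr/dt = -(D/(rho h)) grad and h = min(r, h_max):
      # for r < h_max this is the constant -2 D grad / rho, which stays smooth
      # through u = 0 (depleted bins contribute nothing to solid mass)
      du <- -2 * (D_cmh * grad / rho) * pmax(r / h_max_cm, 1)
      list(du)
    }
    t_local <- times_h[times_h >= t_off & times_h <= t_off + st$duration_h] - t_off
    t_grid <- sort(unique(c(0, t_local, st$duration_h)))
    sol <- deSolve::lsoda(y = u, times = t_grid, func = rhs, parms = NULL,
                          atol = pmax(opts$atol, 1e-6 * u0), rtol = opts$rtol,
                          maxsteps = 20000)
    if (attr(sol, "istate")[1] < 0) {
      stop("dissolution solver failed in stage ", si, call. = FALSE)
    }
    keep <- sol[, 1] %in% t_local
    if (any(keep)) {
      rs <- sqrt(pmax(sol[keep, -1, drop = FALSE], 0))
      f <- 100 * (dose - apply(rs, 1, solid_mass)) / dose
      out_t <- c(out_t, sol[keep, 1] + t_off)
      out_f <- c(out_f, f)
      out_stage <- c(out_stage, rep(st$medium, sum(keep)))
    }
    u <- pmax(sol[nrow(sol), -1], 0)
    u[sqrt(u) <= r_min_cm] <- 0
    C_end <- (dose - solid_mass(sqrt(u))) / vol
    if (C_end > S_bulk_cap * (1 + 1e-9)) supersat <- TRUE
    t_off <- t_off + st$duration_h
  }
  if (supersat) {
    warning("bulk concentration exceeds bulk solubility at medium pH; ",
            "supersaturation is not resolved (no precipitation model)",
            call. = FALSE)
  }
  ord <- order(out_t)
  prof <- data.frame(time_h = out_t[ord],
                     f_dissolved_pct = pmin(pmax(out_f[ord], 0), 100),
                     stage = out_stage[ord])
  # collapse duplicates from coincident stage-boundary requests
  prof <- prof[!duplicated(prof$time_h), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof,
            class = c("dissolution_profile", "data.frame"),
            surface_pH = surface_pH, product = product,
            final_radii_um = sqrt(pmax(u, 0)) * 1e4)
}

#' Closed-form monodisperse sink-condition dissolution
#'
#' Analytic solution of the single-bin DLM under perfect sink
#' (`C_bulk = 0`): while `r >= h_max` the radius shrinks linearly
#' (`dr/dt = -k / h_max`, the cube-root-law regime); once `r < h_max` the
#' layer tracks the radius and `r^2` decays linearly. Used as an
#' independent oracle for the numerical integrator.
#'
#' @param drug A [drug_substance()].
#' @param r0_um Initial particle radius, micrometres.
#' @param surface_pH Particle surface pH.
#' @param h_max_um Maximum diffusion-layer thickness, micrometres.
#' @param times_h Output times, hours.
#' @return Fraction dissolved (percent) at `times_h`.
#' @export
dissolution_sink_closed_form <- function(drug, r0_um, surface_pH, h_max_um,
                                         times_h) {
  S <- surface_solubility(drug, surface_pH) * 1e-3   # g/cm^3
  D_cmh <- drug$D * 60
  k <- D_cmh * S / drug$rho                          # cm^2/h scale factor
  r0 <- r0_um * 1e-4
  h <- h_max_um * 1e-4
  r_of_t <- function(t) {
    if (r0 <= h) {
      # pure r^2 regime from the start
      return(sqrt(pmax(r0^2 - 2 * k * t, 0)))
    }
    t_lin <- (r0 - h) * h / k        # time to shrink linearly down to r = h
    if (t <= t_lin) r0 - k * t / h
    else sqrt(pmax(h^2 - 2 * k * (t - t_lin), 0))
  }
  r <- vapply(times_h, r_of_t, numeric(1))
  100 * (1 - (r / r0)^3)
}

modify_defaults <- function(defaults, user) {
  stopifnot(is.list(user))
  defaults[names(user)] <- user
  defaults
}
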