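#' Squared Pearson correlation between observed and predicted profiles
#'
#' The goodness-of-fit statistic used to accept dissolution fits: the
#' squared linear correlation coefficient between observed and predicted
#' fraction dissolved. It is affine-invariant, so a fit is judged on the
#' shape of the profile.
#'
#' @param observed Observed fraction dissolved, percent.
#' @param predicted Predicted fraction dissolved, percent.
#' @return r-squared in `[0, 1]`.
#' @export
goodness_r2 <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3) {
    stop("observed and predicted must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(observed) == 0) {
    stop("degenerate profile: observed values have zero variance", call. = FALSE)
  }
  if (stats::sd(predicted) == 0) return(0)
  stats::cor(observed, predicted)^2
}

#' Estimate particle surface pH from a dissolution profile
#'
#' Fits the single surface-pH parameter of the diffusion layer model to an
#' observed fraction-dissolved profile by minimizing the sum of squared
#' residuals with a one-dimensional Nelder-Mead search. Proposals are
#' reflected back into the physiologically sensible pH interval
#' `bounds = (3, 8)`; the search stops when the simplex spread falls below
#' `tol` pH units. The fit is flagged acceptable when r-squared exceeds 0.90.
#'
#' @param profile A `dissolution_profile` (or data frame with `time_h` and
#'   `f_dissolved_pct`) holding at least 3 observed points.
#' @param drug A [drug_substance()].
#' @param particles A [psd()].
#' @param protocol The [dissolution_protocol()] the profile was measured under.
#' @param init Initial surface pH guess in (0, 14).
#' @param h_max_um Diffusion-layer thickness cap passed to the simulator.
#' @param bounds Search interval for surface pH (default `c(3, 8)`).
#' @param tol Simplex-spread convergence tolerance in pH units (default 1e-4).
#' @param max_iter Maximum Nelder-Mead iterations (default 200).
#' @param solver_opts Options forwarded to [simulate_dissolution()].
#' @return A list with `surface_pH`, `r2`, `sse`, `converged`, `acceptable`,
#'   `n_iter`. If the iteration limit is hit an estimation-failure condition
#'   (class `ibuvbe_estimation_failure`) is signalled carrying the
#'   best-so-far value in its `data` field.
#' @export
fit_surface_pH <- function(profile, drug, particles, protocol, init = 6,
                           h_max_um = 30, bounds = c(3, 8), tol = 1e-4,
                           max_iter = 200, solver_opts = list()) {
  obs_t <- profile$time_h
  obs_f <- profile$f_dissolved_pct
  if (length(obs_t) < 3) stop("need >= 3 observed time points", call. = FALSE)
  if (init <= 0 || init >= 14) stop("init must lie in (0, 14)", call. = FALSE)
  if (stats::sd(obs_f) == 0) {
    stop("degenerate profile: observed values have zero variance", call. = FALSE)
  }

  predict_f <- function(pH) {
    sim <- simulate_dissolution(drug, particles, protocol, pH,
                                h_max_um = h_max_um, times_h = obs_t,
                                solver_opts = solver_opts)
    sim$f_dissolved_pct[match(round(obs_t, 10), round(sim$time_h, 10))]
  }
  sse <- function(pH) {
    p <- predict_f(pH)
    sum((obs_f - p)^2)
  }
  fit <- nelder_mead_1d(sse, init, bounds = bounds, tol = tol,
                        max_iter = max_iter)
  pred <- predict_f(fit$x)
  r2 <- if (stats::sd(pred) == 0) 0 else stats::cor(obs_f, pred)^2
  res <- list(surface_pH = fit$x, r2 = r2, sse = fit$fx,
              converged = fit$converged, acceptable = r2 > 0.90,
              n_iter = fit$n_iter)
  if (!fit$converged) {
    cond <- structure(
      class = c("ibuvbe_estimation_failure", "error", "condition"),
      list(message = sprintf(
             "surface-pH estimation did not converge in %d iterations (best so far %.4f)",
             max_iter, fit$x),
           call = sys.call(-1), data = res))
    stop(cond)
  }
  res
}

# One-dimensional Nelder-Mead (two-point simplex) with mirror reflection of
# proposals into [lo, hi]. Convergence: simplex spread < tol.
nelder_mead_1d <- function(f, init, bounds, tol = 1e-4, max_iter = 200) {
  lo <- bounds[1]; hi <- bounds[2]
  mirror <- function(x) {
    span <- hi - lo
    # fold into [lo, lo + 2 span] then reflect
    x <- (x - lo) %% (2 * span)
    lo + ifelse(x > span, 2 * span - x, x)
  }
  x1 <- mirror(init)
  x2 <- mirror(init + max(0.25, tol * 10))
  if (abs(x2 - x1) < tol) x2 <- mirror(x1 + 0.5)
  f1 <- f(x1); f2 <- f(x2)
  n_iter <- 0L
  while (abs(x2 - x1) >= tol && n_iter < max_iter) {
    n_iter <- n_iter + 1L
    if (f2 < f1) { tmp <- x1; x1 <- x2; x2 <- tmp; tmp <- f1; f1 <- f2; f2 <- tmp }
    # reflect worst point through best
    xr <- mirror(x1 + (x1 - x2)); fr <- f(xr)
    if (fr < f1) {
      xe <- mirror(x1 + 2 * (x1 - x2)); fe <- f(xe)
      if (fe < fr) { x2 <- xe; f2 <- fe } else { x2 <- xr; f2 <- fr }
    } else if (fr < f2) {
      x2 <- xr; f2 <- fr
    } else {
      xc <- x1 + (x2 - x1) / 2; fc <- f(xc)   # inside contraction
      if (fc < f2) { x2 <- xc; f2 <- fc }
      else { x2 <- x1 + (x2 - x1) / 4; f2 <- f(x2) }  # shrink
    }
  }
  converged <- abs(x2 - x1) < tol
  if (f2 < f1) { x1 <- x2; f1 <- f2 }
  list(x = x1, fx = f1, converged = converged, n_iter = n_iter)
}
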