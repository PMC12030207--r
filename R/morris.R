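#' Plan a Morris elementary-effects screening
#'
#' @param parameters Data frame with columns `name`, `min`, `max`
#'   (parameter box; sampling is done on the unit-scaled box).
#' @param p Number of grid levels (even, >= 4; default 4).
#' @param r Number of random one-at-a-time trajectories (default 50).
#' @param seed Integer seed.
#' @return An object of class `morris_plan`.
#' @export
morris_plan <- function(parameters, p = 4, r = 50, seed = 1L) {
  stopifnot(all(c("name", "min", "max") %in% names(parameters)))
  if (p < 4 || p %% 2 != 0) stop("levels p must be even and >= 4", call. = FALSE)
  if (r < 2) stop("need r >= 2 trajectories", call. = FALSE)
  if (any(parameters$min >= parameters$max)) {
    stop("min must be < max for every parameter", call. = FALSE)
  }
  structure(list(parameters = parameters, p = as.integer(p), r = as.integer(r),
                 seed = as.integer(seed)),
            class = "morris_plan")
}

#' Morris elementary-effects screening
#'
#' One-at-a-time global sensitivity screening: `r` randomized trajectories
#' on a `p`-level grid in the unit-scaled parameter box, step
#' `Delta = p / (2 * (p - 1))`. Each trajectory perturbs every parameter
#' once in random order and random direction; the elementary effect of
#' parameter `i` is `(f(x + Delta e_i) - f(x)) / Delta` (sign-adjusted for
#' downward steps). Elementary effects are computed in unit-box scale so
#' that the mean absolute effect `mu*` is comparable across parameters
#' with different units. Uses `r * (k + 1)` model evaluations for `k`
#' parameters.
#'
#' @param model Function taking a named numeric vector (natural units) and
#'   returning a finite scalar.
#' @param plan A [morris_plan()].
#' @return A `morris_result`: data frame with columns `parameter`, `mu`,
#'   `mu_star`, `sigma`, `rank` (1 = largest `mu_star`), ordered by rank.
#' @export
morris_screen <- function(model, plan) {
  stopifnot(inherits(plan, "morris_plan"))
  pars <- plan$parameters
  k <- nrow(pars)
  p <- plan$p
  delta <- p / (2 * (p - 1))
  # base grid levels that keep x and x + delta inside [0, 1]
  base_levels <- seq(0, 1 - delta, length.out = p / 2)
  to_natural <- function(x) {
    stats::setNames(pars$min + x * (pars$max - pars$min), pars$name)
  }
  ee <- matrix(NA_real_, plan$r, k, dimnames = list(NULL, pars$name))
  local_seed(plan$seed, {
    for (tr in seq_len(plan$r)) {
      x <- base_levels[sample.int(length(base_levels), k, replace = TRUE)]
      dir <- sample(c(-1, 1), k, replace = TRUE)
      # shift down-steps so every point stays on the grid inside [0, 1]
      x <- ifelse(dir < 0, x + delta, x)
      ord <- sample.int(k)
      f0 <- model(to_natural(x))
      if (!is.finite(f0)) stop("non-finite model output at x = ",
                               paste(signif(x, 4), collapse = ", "),
                               call. = FALSE)
      for (i in ord) {
        x2 <- x
        x2[i] <- x[i] + dir[i] * delta
        f1 <- model(to_natural(x2))
        if (!is.finite(f1)) stop("non-finite model output at x = ",
                                 paste(signif(x2, 4), collapse = ", "),
                                 call. = FALSE)
        ee[tr, i] <- (f1 - f0) / (dir[i] * delta)
        x <- x2
        f0 <- f1
      }
    }
  })
  res <- data.frame(parameter = pars$name,
                    mu = colMeans(ee),
                    mu_star = colMeans(abs(ee)),
                    sigma = apply(ee, 2, stats::sd))
  res$rank <- rank(-res$mu_star, ties.method = "first")
  res <- res[order(res$rank), ]
  rownames(res) <- NULL
  class(res) <- c("morris_result", "data.frame")
  res
}

#' Select the driving parameter from a Morris screening
#'
#' Returns the parameter with the largest mean absolute elementary effect
#' `mu*`; exact ties are broken by the larger `sigma` (more interaction /
#' nonlinearity), then lexicographically.
#'
#' @param result A `morris_result` from [morris_screen()].
#' @return The selected parameter name (character scalar).
#' @export
select_driver <- function(result) {
  stopifnot(inherits(result, "morris_result"), nrow(result) >= 1)
  o <- order(-result$mu_star, -result$sigma, result$parameter)
  result$parameter[o[1]]
}
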