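#' Average bioequivalence analysis of a 2x2 crossover trial
#'
#' Log-scale analysis of per-subject test and reference Cmax: with
#' `d_j = ln(T_j) - ln(R_j)`, the geometric mean ratio is `exp(mean(d))`
#' and the 90% confidence interval is
#' `GMR * exp(-/+ t(0.95, df) * sd(d) / sqrt(n))`, with `df = n - 2` by
#' default (crossover ANOVA with a sequence term; `df = n - 1` gives the
#' paired analysis). Bioequivalence is declared when the CI lies within
#' 80.00-125.00% (two one-sided tests at alpha 0.05). The within-subject
#' CV is recovered from the paired-difference variance via
#' `sigma_w^2 = sd(d)^2 / 2` and `CV = sqrt(exp(sigma_w^2) - 1)`.
#'
#' @param records Data frame with columns `id`, `treatment` (`"T"`/`"R"`)
#'   and `log_cmax`; one T and one R record per subject.
#' @param analyte Label stored on the outcome (`"R"`, `"S"`, `"racemate"`).
#' @param df_method `"sequence"` (df = n - 2, default) or `"paired"`
#'   (df = n - 1).
#' @param limits BE acceptance limits as fractions (default `c(0.80, 1.25)`).
#' @return A `be_outcome` list: `analyte`, `GMR` (%), `CI90` (%, length 2),
#'   `decision` (`"BE"`/`"not-BE"`), `n`, `df`, `WSV_CV` (%), `sd_d`.
#' @export
crossover_be <- function(records, analyte = "racemate",
                         df_method = c("sequence", "paired"),
                         limits = c(0.80, 1.25)) {
  df_method <- match.arg(df_method)
  stopifnot(all(c("id", "treatment", "log_cmax") %in% names(records)))
  lt <- records[records$treatment == "T", ]
  lr <- records[records$treatment == "R", ]
  ids <- intersect(lt$id, lr$id)
  n <- length(ids)
  if (n < 3) stop("insufficient data: need >= 3 complete subjects", call. = FALSE)
  d <- tapply(lt$log_cmax, lt$id, mean)[as.character(ids)] -
       tapply(lr$log_cmax, lr$id, mean)[as.character(ids)]
  md <- mean(d); sdd <- stats::sd(d)
  df <- if (df_method == "sequence") n - 2 else n - 1
  half <- stats::qt(0.95, df) * sdd / sqrt(n)
  gmr <- 100 * exp(md)
  ci <- 100 * exp(c(md - half, md + half))
  decision <- if (ci[1] >= 100 * limits[1] && ci[2] <= 100 * limits[2]) "BE" else "not-BE"
  structure(list(analyte = analyte, GMR = gmr, CI90 = ci, decision = decision,
                 n = n, df = df,
                 WSV_CV = 100 * sqrt(exp(sdd^2 / 2) - 1), sd_d = sdd),
            class = "be_outcome")
}

#' Estimate within- and between-subject variance components
#'
#' One-way moment decomposition of replicated log-Cmax measurements:
#' log values are first centred by treatment (removing the formulation
#' effect), then the within-subject variance is the pooled within-subject
#' mean square and the between-subject variance is
#' `(MSB - MSW) / k` for `k` periods per subject. Variances convert to
#' lognormal CVs via `CV = sqrt(exp(sigma^2) - 1)`; negative moment
#' estimates are truncated at zero.
#'
#' @param records Data frame with columns `id`, `period`, `log_cmax` and
#'   optionally `treatment` (used for centring when present).
#' @return A list with `WSV_CV` and `BSV_CV` (percent), plus the raw
#'   `sigma2_w`, `sigma2_b`.
#' @export
estimate_variance_components <- function(records) {
  stopifnot(all(c("id", "period", "log_cmax") %in% names(records)))
  k_per <- table(records$id)
  if (any(k_per < 2)) {
    stop("WSV undefined: every subject needs >= 2 periods", call. = FALSE)
  }
  y <- records$log_cmax
  if (!is.null(records$treatment)) {
    y <- y - stats::ave(y, records$treatment)
  }
  id <- factor(records$id)
  n <- nlevels(id)
  k <- mean(k_per)
  subj_mean <- stats::ave(y, id)
  ssw <- sum((y - subj_mean)^2)
  msw <- ssw / (length(y) - n)
  grand <- mean(y)
  ssb <- sum(tapply(y, id, function(v) length(v) * (mean(v) - grand)^2))
  msb <- ssb / (n - 1)
  s2w <- max(msw, 0)
  s2b <- max((msb - msw) / k, 0)
  list(WSV_CV = 100 * sqrt(exp(s2w) - 1), BSV_CV = 100 * sqrt(exp(s2b) - 1),
       sigma2_w = s2w, sigma2_b = s2b)
}

#' Sample size for an average-bioequivalence crossover trial
#'
#' Closed-form normal-quantile sample size for the two one-sided tests
#' procedure on the log scale:
#' `n = 2 * (z[1-alpha] + z[1-beta])^2 * ln(1 + CV^2) / (ln GMR - ln theta)^2`
#' with `theta` the nearer acceptance limit on the log scale, rounded up to
#' the next even integer (balanced sequences). For `GMR = 1` the two-sided
#' quantile `z[1-beta/2]` is used. An iterative exact noncentral-t variant
#' is available via `method = "nct"`.
#'
#' @param GMR Assumed test/reference ratio as a fraction (e.g. 0.85).
#' @param WSV_CV Within-subject CV, percent.
#' @param power Target power as a fraction (e.g. 0.80).
#' @param alpha One-sided significance level (default 0.05).
#' @param limits Acceptance limits as fractions (default `c(0.80, 1.25)`).
#' @param method `"normal"` (default, closed form) or `"nct"` (iterate the
#'   exact TOST power to the smallest even n).
#' @return Total sample size, an even integer (minimum 4).
#' @export
sample_size <- function(GMR, WSV_CV, power, alpha = 0.05,
                        limits = c(0.80, 1.25),
                        method = c("normal", "nct")) {
  method <- match.arg(method)
  if (GMR <= limits[1] || GMR >= limits[2]) {
    stop("zero power: GMR must lie strictly inside the acceptance limits",
         call. = FALSE)
  }
  if (power <= 0 || power >= 1) stop("power must lie in (0, 1)", call. = FALSE)
  s2 <- log(1 + (WSV_CV / 100)^2)
  if (method == "normal") {
    za <- stats::qnorm(1 - alpha)
    zb <- if (GMR == 1) stats::qnorm(1 - (1 - power) / 2) else stats::qnorm(power)
    dl <- abs(log(GMR) - log(limits[1]))
    du <- abs(log(GMR) - log(limits[2]))
    delta <- min(dl, du)
    n <- 2 * (za + zb)^2 * s2 / delta^2
    as.integer(max(2 * ceiling(n / 2), 4))
  } else {
    n <- 4
    while (n < 4000 && tost_power(GMR, WSV_CV, n, alpha, limits) < power) {
      n <- n + 2
    }
    as.integer(n)
  }
}

#' Exact TOST power for a 2x2 crossover
#'
#' Power of the two one-sided tests procedure computed from the noncentral
#' t distribution (the usual conservative union bound
#' `P(pass lower) + P(pass upper) - 1`).
#'
#' @inheritParams sample_size
#' @param n Total number of subjects (even, >= 4).
#' @return Power as a fraction in `[0, 1]`.
#' @export
tost_power <- function(GMR, WSV_CV, n, alpha = 0.05, limits = c(0.80, 1.25)) {
  s2 <- log(1 + (WSV_CV / 100)^2)
  se <- sqrt(2 * s2 / n)
  df <- n - 2
  ta <- stats::qt(1 - alpha, df)
  ncp1 <- (log(GMR) - log(limits[1])) / se
  ncp2 <- (log(GMR) - log(limits[2])) / se
  p <- stats::pt(ta, df, ncp = ncp1, lower.tail = FALSE) +
       stats::pt(-ta, df, ncp = ncp2) - 1
  max(0, min(1, p))
}

#' Predicted 90% confidence interval at a planned sample size
#'
#' Planning-mode CI for an anticipated GMR, assuming the within-subject CV
#' observed in a reference study:
#' `CI = GMR * exp(-/+ t(0.95, n-2) * sqrt(ln(1 + CV^2)) * sqrt(2/n))`,
#' expressed in percent.
#'
#' @param GMR Anticipated ratio as a fraction.
#' @param WSV_CV Within-subject CV, percent.
#' @param n Planned total sample size (even, >= 4).
#' @return Named numeric `c(LL, UL)` in percent.
#' @export
predict_ci <- function(GMR, WSV_CV, n) {
  if (n < 4 || n %% 2 != 0) {
    stop("insufficient df: n must be an even integer >= 4", call. = FALSE)
  }
  s <- sqrt(log(1 + (WSV_CV / 100)^2))
  half <- stats::qt(0.95, n - 2) * s * sqrt(2 / n)
  c(LL = 100 * GMR * exp(-half), UL = 100 * GMR * exp(half))
}

#' Sample-size planning table over anticipated GMRs
#'
#' For each (analyte, GMR) planning scenario, computes the total sample
#' size at 80% and 90% power and the predicted 90% CI at the 80%-power
#' sample size, assuming the stated within-subject CV.
#'
#' @param scenarios Data frame with columns `analyte`, `GMR_pct` and
#'   `WSV_CV` (percent scales).
#' @return The input with columns `n_80`, `n_90`, `LL`, `UL` appended.
#' @export
sample_size_table <- function(scenarios) {
  stopifnot(all(c("analyte", "GMR_pct", "WSV_CV") %in% names(scenarios)))
  out <- scenarios
  out$n_80 <- mapply(function(g, cv) sample_size(g / 100, cv, 0.80),
                     scenarios$GMR_pct, scenarios$WSV_CV)
  out$n_90 <- mapply(function(g, cv) sample_size(g / 100, cv, 0.90),
                     scenarios$GMR_pct, scenarios$WSV_CV)
  ci <- mapply(function(g, cv, n) predict_ci(g / 100, cv, n),
               scenarios$GMR_pct, scenarios$WSV_CV, out$n_80)
  out$LL <- round(ci[1, ], 2)
  out$UL <- round(ci[2, ], 2)
  out
}
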