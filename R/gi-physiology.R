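#' Default fasted-state GI physiology table
#'
#' One row per gastrointestinal compartment (stomach, duodenum, two jejunum
#' and four ileum segments, colon) with the lumenal pH, resting fluid
#' volume, mean residence times (MRT) of fluid and of fine particles, and
#' the segment radius used to convert effective permeability into a
#' first-order absorption rate (`ka = 2 * Peff / radius`).
#'
#' Central values: stomach fluid MRT 0.12 h and fine-particle MRT 0.27 h,
#' total small-intestinal MRT 3.4 h (allocated uniformly over the seven
#' segments), stomach fluid volume 50 mL, total jejunum-through-ileum fluid
#' volume 105 mL (allocated uniformly), colon volume 13 mL, and segmental
#' pH 6.4 (duodenum) through 7.3 (ileum 4), colon 6.6. Stomach pH, duodenal
#' volume, segment radii and the colon MRT are standard fasted-human
#' assumptions. Absorption is enabled in the small intestine only (colon
#' off by default).
#'
#' @return A data frame of class `gi_physiology` with columns `name`, `pH`,
#'   `volume_mL`, `mrt_fluid_h`, `mrt_particle_h`, `radius_cm`, `absorb`.
#' @export
gi_default <- function() {
  si_names <- c("duodenum", "jejunum1", "jejunum2",
                "ileum1", "ileum2", "ileum3", "ileum4")
  gi <- data.frame(
    name = c("stomach", si_names, "colon"),
    pH = c(1.5, 6.4, 6.5, 6.6, 6.8, 7.0, 7.1, 7.3, 6.6),
    volume_mL = c(50, 15, rep(105 / 6, 6), 13),
    mrt_fluid_h = c(0.12, rep(3.4 / 7, 7), 13.5),
    mrt_particle_h = c(0.27, rep(3.4 / 7, 7), 13.5),
    radius_cm = c(10, 1.6, 1.5, 1.5, 1.4, 1.3, 1.3, 1.2, 2.5),
    absorb = c(FALSE, rep(TRUE, 7), FALSE),
    stringsAsFactors = FALSE
  )
  class(gi) <- c("gi_physiology", "data.frame")
  gi
}

#' Per-enantiomer disposition parameters
#'
#' One-compartment disposition per enantiomer: steady-state volume of
#' distribution `Vss` (L/kg), clearance `CL` (L/h), and for the
#' R-enantiomer a first-order unidirectional R-to-S chiral inversion rate
#' constant. `k_inversion` must be 0 for the S-enantiomer.
#'
#' @param analyte `"R"` or `"S"`.
#' @param Vss_L_kg Steady-state volume of distribution, L/kg (default
#'   0.091249, the highly protein-bound ibuprofen value).
#' @param CL_L_h Clearance, L/h.
#' @param k_inversion_h First-order R-to-S inversion rate, 1/h.
#' @param body_weight_kg Body weight, kg (default 70).
#' @return An object of class `enantiomer_disposition`.
#' @export
enantiomer_disposition <- function(analyte = c("R", "S"),
                                   Vss_L_kg = 0.091249, CL_L_h,
                                   k_inversion_h = 0, body_weight_kg = 70) {
  analyte <- match.arg(analyte)
  if (Vss_L_kg <= 0 || CL_L_h <= 0 || body_weight_kg <= 0) {
    stop("Vss, CL and body weight must be positive", call. = FALSE)
  }
  if (k_inversion_h < 0) stop("k_inversion must be >= 0", call. = FALSE)
  if (analyte == "S" && k_inversion_h != 0) {
    stop("chiral inversion is unidirectional R -> S: k_inversion must be 0 for S",
         call. = FALSE)
  }
  structure(list(analyte = analyte, Vss_L_kg = Vss_L_kg, CL_L_h = CL_L_h,
                 k_inversion_h = k_inversion_h,
                 body_weight_kg = body_weight_kg),
            class = "enantiomer_disposition")
}

#' Default ibuprofen enantiomer disposition pair
#'
#' Documented assumptions for a 70 kg fasted adult: both enantiomers share
#' `Vss = 0.091249` L/kg; the R-enantiomer has a lower direct clearance but
#' undergoes first-order R-to-S inversion (about 60% of an R dose is
#' inverted), giving both enantiomers terminal half-lives near 2 h.
#'
#' @param body_weight_kg Body weight, kg.
#' @param Vss_L_kg Steady-state volume of distribution, L/kg.
#' @return A list with elements `R` and `S`, each an
#'   [enantiomer_disposition()].
#' @export
disposition_default <- function(body_weight_kg = 70, Vss_L_kg = 0.091249) {
  list(
    R = enantiomer_disposition("R", Vss_L_kg = Vss_L_kg, CL_L_h = 1.0,
                               k_inversion_h = 0.20,
                               body_weight_kg = body_weight_kg),
    S = enantiomer_disposition("S", Vss_L_kg = Vss_L_kg, CL_L_h = 2.0,
                               k_inversion_h = 0,
                               body_weight_kg = body_weight_kg)
  )
}

#' Clinical plasma sampling schedule
#'
#' The post-dose sampling times (hours) of the crossover bioequivalence
#' study design: dense early sampling around the expected tmax of an
#' immediate-release tablet, then sparse sampling to 24 h.
#'
#' @return Numeric vector of times in hours.
#' @export
clinical_schedule <- function() {
  c(0, 0.33, 0.66, 1, 1.25, 1.5, 1.75, 2, 2.5, 3, 3.5, 4, 6, 8, 10, 12, 14, 24)
}
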