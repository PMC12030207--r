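#' Define a drug substance for the diffusion layer model
#'
#' Bundles the physicochemical parameters that the diffusion layer model
#' (DLM) needs for a monoprotic weak acid: intrinsic solubility of the
#' unionized species, acid dissociation constant, aqueous diffusion
#' coefficient, true (crystal) density, dose, and molecular weight.
#'
#' @param name Character label.
#' @param pKa Acid dissociation constant (pH units), must lie in (0, 14).
#' @param S0 Intrinsic solubility of the unionized acid, mg/mL.
#' @param D Aqueous diffusion coefficient, cm^2/min.
#' @param rho True density of the solid, g/mL.
#' @param dose Dose of drug substance in the dosage form, mg.
#' @param MW Molecular weight, g/mol.
#'
#' @return An object of class `drug_substance`.
#' @seealso [ibuprofen()] for the bundled racemic ibuprofen defaults,
#'   [surface_solubility()] for the pH-dependent solubility it drives.
#' @export
drug_substance <- function(name, pKa, S0, D, rho, dose, MW) {
  vals <- c(pKa = pKa, S0 = S0, D = D, rho = rho, dose = dose, MW = MW)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all drug-substance parameters must be positive and finite", call. = FALSE)
  }
  if (pKa <= 0 || pKa >= 14) stop("pKa must lie in (0, 14)", call. = FALSE)
  structure(
    list(name = name, pKa = pKa, S0 = S0, D = D, rho = rho, dose = dose, MW = MW),
    class = "drug_substance"
  )
}

#' Racemic ibuprofen drug-substance defaults
#'
#' Default physicochemical parameters for racemic ibuprofen, a BCS class IIa
#' weak acid. Intrinsic solubility and pKa are the widely used literature
#' values; diffusion coefficient, true density, and molecular weight are
#' textbook values for a small lipophilic acid. These are documented
#' assumptions, not fitted quantities.
#'
#' @param dose Dose in mg (default 200, one immediate-release tablet).
#' @return A [drug_substance()] object.
#' @export
ibuprofen <- function(dose = 200) {
  drug_substance(
    name = "ibuprofen",
    pKa  = 4.45,            # monoprotic carboxylic acid
    S0   = 0.068,           # mg/mL intrinsic (unionized) solubility
    D    = 4.5e-4,          # cm^2/min (~7.5e-6 cm^2/s)
    rho  = 1.06,            # g/mL true density
    dose = dose,
    MW   = 206.28
  )
}

#' pH-dependent surface solubility of a monoprotic weak acid
#'
#' Henderson-Hasselbalch total solubility at the particle surface:
#' `S(pH) = S0 * (1 + 10^(pH - pKa))`. For a self-buffering acid such as
#' ibuprofen the surface pH differs from the bulk medium pH and is the key
#' product-discriminating parameter of the DLM: it sets the solubility in
#' the diffusion layer and hence the dissolution driving force.
#'
#' @param drug A [drug_substance()] object.
#' @param surface_pH pH at the particle surface, in (0, 14). Vectorized.
#' @return Solubility in mg/mL, strictly increasing in `surface_pH`.
#' @export
surface_solubility <- function(drug, surface_pH) {
  stopifnot(inherits(drug, "drug_substance"))
  if (any(surface_pH <= 0 | surface_pH >= 14)) {
    stop("surface_pH must lie in (0, 14)", call. = FALSE)
  }
  drug$S0 * (1 + 10^(surface_pH - drug$pKa))
}

#' Construct a particle size distribution (PSD)
#'
#' A discrete particle population: per-bin particle radius (micrometres) and
#' particle count. The bin counts are scaled so that the total particle mass
#' `sum(N * 4/3 * pi * rho * r^3)` equals the dose exactly.
#'
#' @param radius_um Strictly increasing positive radii, micrometres.
#' @param number Relative particle numbers per bin (any positive scale; they
#'   are renormalized to the dose).
#' @param drug A [drug_substance()] whose `dose` and `rho` fix the mass scale.
#' @return An object of class `psd` with fields `radius_um`, `number`,
#'   `dispersion`.
#' @export
psd <- function(radius_um, number, drug) {
  stopifnot(inherits(drug, "drug_substance"))
  if (length(radius_um) != length(number) || length(radius_um) == 0) {
    stop("radius_um and number must be non-empty and of equal length", call. = FALSE)
  }
  if (any(radius_um <= 0) || any(diff(radius_um) <= 0)) {
    stop("radii must be strictly positive and increasing", call. = FALSE)
  }
  if (any(number < 0) || sum(number) == 0) {
    stop("particle numbers must be nonnegative with positive total", call. = FALSE)
  }
  # mass of one particle in mg: rho [g/mL] * volume [cm^3] * 1000
  m1 <- particle_mass_mg(radius_um, drug$rho)
  scale <- drug$dose / sum(number * m1)
  structure(
    list(
      radius_um  = as.numeric(radius_um),
      number     = as.numeric(number) * scale,
      dispersion = if (length(radius_um) == 1L) "monodisperse" else "polydisperse"
    ),
    class = "psd"
  )
}

# mass (mg) of one sphere of radius r um at density rho g/mL
particle_mass_mg <- function(radius_um, rho) {
  r_cm <- radius_um * 1e-4
  rho * (4 / 3) * pi * r_cm^3 * 1e3
}

#' Lognormal volume-weighted PSD on log-spaced bins
#'
#' Default particle population: a lognormal volume (mass) distribution
#' characterized by the volume-median diameter D50 and geometric standard
#' deviation, discretized on log-spaced radius bins. The same PSD is used
#' for reference and test products.
#'
#' The default D50 of 120 um (a coarse milled ibuprofen grade) is calibrated
#' so that the low end of the product range dissolves on the reported
#' timescale: roughly three quarters dissolved at 30 min and complete
#' release between 1 and 2 h at surface pH 5.64.
#'
#' @param drug A [drug_substance()].
#' @param d50_um Volume-median particle diameter, micrometres.
#' @param sigma_g Geometric standard deviation of the volume distribution.
#' @param n_bins Number of log-spaced bins (default 20).
#' @param width Half-width of the bin grid in geometric SDs (default 3).
#' @return A [psd()] object.
#' @export
psd_lognormal <- function(drug, d50_um = 120, sigma_g = 1.6, n_bins = 20, width = 3) {
  stopifnot(d50_um > 0, sigma_g > 1, n_bins >= 1)
  r50 <- d50_um / 2
  if (n_bins == 1L) return(psd(r50, 1, drug))
  lr <- seq(log(r50) - width * log(sigma_g), log(r50) + width * log(sigma_g),
            length.out = n_bins)
  r <- exp(lr)
  # volume fraction per bin ~ lognormal density on log-radius grid
  vol_frac <- stats::dnorm(lr, mean = log(r50), sd = log(sigma_g))
  vol_frac <- vol_frac / sum(vol_frac)
  number <- vol_frac / r^3          # counts carry mass vol_frac per bin
  psd(r, number, drug)
}

#' Total particle mass of a PSD
#' @param x A [psd()] object.
#' @param rho True density, g/mL.
#' @return Mass in mg.
#' @export
psd_mass <- function(x, rho) {
  stopifnot(inherits(x, "psd"))
  sum(x$number * particle_mass_mg(x$radius_um, rho))
}

#' Coarsen a PSD to fewer bins
#'
#' Resamples a PSD onto `n_bins` log-spaced radii spanning the original
#' range, preserving total mass. Used to trade dissolution-curve resolution
#' for speed in population-scale simulations.
#'
#' @param x A [psd()] object.
#' @param drug The owning [drug_substance()].
#' @param n_bins Target number of bins.
#' @return A [psd()] object.
#' @export
psd_coarsen <- function(x, drug, n_bins) {
  stopifnot(inherits(x, "psd"))
  if (length(x$radius_um) <= n_bins) return(x)
  lr <- seq(log(min(x$radius_um)), log(max(x$radius_um)), length.out = n_bins)
  r <- exp(lr)
  idx <- findInterval(log(x$radius_um), c(-Inf, (lr[-1] + lr[-n_bins]) / 2, Inf))
  mass_b <- tapply(x$number * particle_mass_mg(x$radius_um, drug$rho), idx, sum)
  num <- numeric(n_bins)
  num[as.integer(names(mass_b))] <- mass_b / particle_mass_mg(r, drug$rho)[as.integer(names(mass_b))]
  keep <- num > 0
  psd(r[keep], num[keep], drug)
}
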