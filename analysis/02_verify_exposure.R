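#!/usr/bin/env Rscript
# Stage 2: couple the fitted dissolution parameters to the absorption/
# disposition model and screen conditions with the prediction-error filter.
#
# Each condition's fitted reference and test surface pH feed the GI model;
# predicted racemate Cmax and tmax are compared against the anchor exposure
# (here the selected condition's reference simulation, standing in for the
# clinical observation that is not publicly tabulated) with acceptance
# windows 0.9-1.11 on the Cmax ratio and +/-30% on tmax.

suppressPackageStartupMessages(library(ibuvbe))

fits <- read.csv("results/dissolution_fits.csv")
drug <- ibuprofen()
particles <- psd_coarsen(psd_lognormal(drug), drug, 8)

sim_metrics <- function(ph) {
  prof <- simulate_oral_dose(drug, particles, gi_default(), ph,
                             disposition_default())
  list(cmax = extract_cmax_tmax(prof, "racemate")$cmax,
       tmax = extract_cmax_tmax(prof, "racemate")$tmax,
       cmax_R = extract_cmax_tmax(prof, "R")$cmax,
       cmax_S = extract_cmax_tmax(prof, "S")$cmax)
}

anchor_ph <- fits$fitted_surface_pH[fits$condition == "MB7 + HCl pH 2.0" &
                                      fits$product == "reference"]
anchor <- sim_metrics(anchor_ph)
message(sprintf("anchor exposure at reference surface pH %.2f: Cmax %.2f mg/L, tmax %.2f h",
                anchor_ph, anchor$cmax, anchor$tmax))

rows <- list()
for (cond in unique(fits$condition)) {
  ref_ph <- fits$fitted_surface_pH[fits$condition == cond &
                                     fits$product == "reference"]
  tst_ph <- fits$fitted_surface_pH[fits$condition == cond &
                                     fits$product == "test"]
  m <- sim_metrics(ref_ph)
  pe_c <- prediction_error(m$cmax, anchor$cmax, "cmax_ratio")
  pe_t <- prediction_error(m$tmax, anchor$tmax, "tmax_pct")
  rows[[length(rows) + 1L]] <- data.frame(
    condition = cond, ref_surface_pH = ref_ph, test_surface_pH = tst_ph,
    cmax_pred = round(m$cmax, 2), cmax_pe = round(pe_c$pe, 3),
    tmax_pe_pct = round(pe_t$pe, 1),
    accepted = pe_c$accepted && pe_t$accepted)
}
verif <- do.call(rbind, rows)
write.csv(verif, "results/verification.csv", row.names = FALSE)
message("\nPrediction-error screen (accept: Cmax PE in 0.9-1.11, |tmax PE| <= 30%):")
print(verif, row.names = FALSE)
sel <- verif[verif$accepted, ][1, ]
message("selected condition for safe-space work: ", sel$condition)
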