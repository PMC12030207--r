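# shared small fixtures; built in code so tests stay text-only

fix_drug <- ibuprofen()

# coarse particle populations: enough bins for shape, cheap to integrate
fix_psd8 <- psd_coarsen(psd_lognormal(fix_drug), fix_drug, 8)
fix_psd5 <- psd_coarsen(psd_lognormal(fix_drug), fix_drug, 5)

fix_protocol <- two_stage_protocol()            # HCl pH 2.0 then MB7 pH 6.5
fix_times <- c(0.083, 0.167, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2)

# sink-condition protocol: huge volume so C_bulk stays ~0
sink_protocol <- function(duration_h = 1) {
  dissolution_protocol(list(protocol_stage("sink", 6.5, 1e7, duration_h)))
}

# forward simulation with the supersaturation notice silenced (expected in
# acid-pretreatment stages, where the self-buffered particle keeps dissolving)
quiet_sim <- function(...) suppressWarnings(simulate_dissolution(...))
quiet_fit <- function(...) suppressWarnings(fit_surface_pH(...))

# a variability table with all CVs zero (degenerate population)
variability_none <- function() {
  v <- variability_default()
  v$cv_pct <- 0
  v
}

# small-but-variable table: keeps the optimized CVs only on the MRT/Vss rows
fast_solver <- list(atol = 1e-8, rtol = 1e-8)

# frozen planning-table reference (sample sizes at 80/90% power and the 90% CI
# at the 80%-power n) used by the regression and acceptance suites
fix_table4 <- data.frame(
  analyte = rep(c("R", "S"), each = 6),
  GMR_pct = c(84, 85, 87, 90, 93, 95, 85, 86, 87, 90, 93, 95),
  WSV_CV = rep(c(14.89, 13.65), each = 6),
  n_80 = as.integer(c(114, 74, 40, 20, 12, 10, 64, 44, 34, 18, 12, 8)),
  n_90 = as.integer(c(158, 104, 54, 28, 18, 14, 88, 62, 46, 24, 14, 12)),
  LL = c(81.31, 81.62, 82.28, 82.98, 83.35, 83.99,
         81.66, 81.91, 82.28, 83.16, 84.11, 83.25),
  UL = c(86.78, 88.52, 92.00, 97.61, 103.77, 107.45,
         88.48, 90.29, 91.99, 97.40, 102.84, 108.41)
)
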