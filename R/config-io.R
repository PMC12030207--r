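#' Default pipeline configuration
#'
#' The full configuration for the workflow, as a plain list that can be
#' round-tripped through YAML: drug substance, particle size distribution,
#' GI physiology, variability table, the dissolution conditions to emulate
#' and fit, trial design, safe-space and campaign settings. Every default
#' is tagged with its provenance (`"table"` for values taken from the
#' physiology/variability tables, `"assumption"` for documented
#' assumptions).
#'
#' @param seed Master seed.
#' @return A list of class `pipeline_config`.
#' @export
default_config <- function(seed = 20250324) {
  cfg <- list(
    seed = seed,
    drug = list(name = "ibuprofen", pKa = 4.45, S0 = 0.068, D = 4.5e-4,
                rho = 1.06, dose = 200, MW = 206.28),
    psd = list(d50_um = 120, sigma_g = 1.6, n_bins = 20),
    h_max_um = 30,
    Peff = 5,
    dissolution = list(
      volume_mL = 900,
      sampling_times_h = c(0.083, 0.167, 0.25, 0.33, 0.5, 0.75, 1, 1.5, 2, 3, 4),
      conditions = list(
        list(label = "MB7_HCl2.0", medium = "MB7", medium_pH = 6.5,
             pretreatment_pH = 2.0, ref_surface_pH = 6.02, test_surface_pH = 5.57),
        list(label = "PB5_none", medium = "PB5", medium_pH = 6.7,
             pretreatment_pH = NA, ref_surface_pH = 5.81, test_surface_pH = 5.58)
      ),
      noise_sd = 1.5
    ),
    observed = list(cmax_R = NA, cmax_S = NA, cmax_rac = NA, tmax_rac = NA),
    trial = list(n_subjects = 24, n_periods = 2),
    safe_space = list(grid = seq(5.4, 6.6, by = 0.2), analyte = "R"),
    campaign = list(n_subjects = 24, runs = 2, replicates = 5),
    provenance = list(
      drug = "assumption", psd = "assumption", h_max_um = "assumption",
      Peff = "assumption", physiology = "table", variability = "table"
    )
  )
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Reads the file, validates the schema (required fields, units and sign
#' constraints), and fills any missing entries from [default_config()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- default_config()
  for (nm in names(raw)) {
    cfg[[nm]] <- if (nm != "drug" && is.list(raw[[nm]]) && is.list(cfg[[nm]]) &&
                     !is.null(names(raw[[nm]]))) {
      # drug-substance fields are required as a block (no silent defaults);
      # everything else is merged over the package defaults
      utils::modifyList(cfg[[nm]], raw[[nm]])
    } else raw[[nm]]
  }
  validate_config(cfg)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Save a pipeline configuration to YAML
#' @param cfg A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

validate_config <- function(cfg) {
  need_drug <- c("pKa", "S0", "D", "rho", "dose", "MW")
  for (f in need_drug) {
    v <- cfg$drug[[f]]
    if (is.null(v) || !is.numeric(v) || !is.finite(v)) {
      stop("config schema violation: drug field \"", f,
           "\" is missing or non-numeric", call. = FALSE)
    }
    if (v <= 0) stop("config schema violation: drug field \"", f,
                     "\" must be positive", call. = FALSE)
  }
  if (cfg$psd$d50_um <= 0 || cfg$psd$sigma_g <= 1) {
    stop("config schema violation: psd needs d50_um > 0 and sigma_g > 1",
         call. = FALSE)
  }
  if (cfg$trial$n_subjects %% 2 != 0) {
    stop("config schema violation: trial n_subjects must be even", call. = FALSE)
  }
  st <- cfg$dissolution$sampling_times_h
  if (!length(st) || any(st < 0) || any(diff(st) <= 0)) {
    stop("config schema violation: dissolution sampling_times_h must be ",
         "nonnegative and strictly increasing", call. = FALSE)
  }
  invisible(cfg)
}

# realize R objects from a config list
config_objects <- function(cfg) {
  drug <- drug_substance(cfg$drug$name, cfg$drug$pKa, cfg$drug$S0, cfg$drug$D,
                         cfg$drug$rho, cfg$drug$dose, cfg$drug$MW)
  particles <- psd_lognormal(drug, cfg$psd$d50_um, cfg$psd$sigma_g,
                             cfg$psd$n_bins)
  list(drug = drug, particles = particles,
       model = model_config(drug = drug, particles = particles,
                            Peff = cfg$Peff, h_max_um = cfg$h_max_um))
}

#' Run the full workflow from a configuration
#'
#' Executes the pipeline stages in order: (1) generate (or load) and fit
#' the dissolution profiles per condition and product; (2) verify each
#' condition against observed Cmax/tmax with the prediction-error filter
#' (Cmax ratio 0.9-1.11, tmax within 30%), excluding failing conditions;
#' (3) map the safe space over test-product surface pH; (4) build the
#' sample-size table; (5) run the VBE campaign. Writes per-stage CSV/JSON
#' outputs and a run manifest (seeds, config hash, package version, stage
#' status) under `out_dir`. A stage failure halts the pipeline with the
#' stage name; completed stages stay on disk.
#'
#' @param cfg A `pipeline_config`.
#' @param out_dir Output directory (created if missing).
#' @param observed Optional named list of observed metrics
#'   (`cmax_rac`, `tmax_rac`) for the verification stage; when absent the
#'   reference simulation itself is used (self-verification smoke mode).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir, observed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- config_objects(cfg)
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   package_version = as.character(utils::packageVersion("ibuvbe")),
                   stages = list())
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest()
      stop("pipeline halted at stage \"", name, "\": ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "completed")
    write_manifest()
    res
  }

  fits <- stage("fit_dissolution", function() {
    out <- list()
    for (cond in cfg$dissolution$conditions) {
      for (prod in c("reference", "test")) {
        true_pH <- if (prod == "reference") cond$ref_surface_pH else cond$test_surface_pH
        spec <- synthetic_dissolution_spec(
          true_surface_pH = true_pH, medium_pH = cond$medium_pH,
          pretreatment_pH = cond$pretreatment_pH,
          sampling_times_h = cfg$dissolution$sampling_times_h,
          noise_sd = cfg$dissolution$noise_sd, seed = cfg$seed,
          volume_mL = cfg$dissolution$volume_mL)
        prof <- generate_dissolution_profile(spec, obj$drug, obj$particles,
                                             product = prod,
                                             h_max_um = cfg$h_max_um)
        fit <- fit_surface_pH(prof, obj$drug, obj$particles,
                              protocol_from_spec(spec), init = 6,
                              h_max_um = cfg$h_max_um)
        out[[paste(cond$label, prod, sep = "_")]] <-
          list(condition = cond$label, product = prod, true_pH = true_pH,
               fitted_pH = fit$surface_pH, r2 = fit$r2)
      }
    }
    df <- do.call(rbind, lapply(out, as.data.frame))
    utils::write.csv(df, file.path(out_dir, "dissolution_fits.csv"),
                     row.names = FALSE)
    out
  })

  verify <- stage("verify_pe", function() {
    keep <- list()
    for (cond in cfg$dissolution$conditions) {
      ref_fit <- fits[[paste(cond$label, "reference", sep = "_")]]
      tst_fit <- fits[[paste(cond$label, "test", sep = "_")]]
      prof_r <- simulate_oral_dose(obj$drug, obj$particles, gi_default(),
                                   ref_fit$fitted_pH, disposition_default(),
                                   Peff = cfg$Peff, h_max_um = cfg$h_max_um)
      cm <- extract_cmax_tmax(prof_r, "racemate")
      obs <- observed %||% list(cmax_rac = cm$cmax, tmax_rac = cm$tmax)
      pe_c <- prediction_error(cm$cmax, obs$cmax_rac, "cmax_ratio")
      pe_t <- prediction_error(cm$tmax, obs$tmax_rac, "tmax_pct")
      keep[[cond$label]] <- list(condition = cond$label,
                                 ref_pH = ref_fit$fitted_pH,
                                 test_pH = tst_fit$fitted_pH,
                                 cmax_pe = pe_c$pe, tmax_pe = pe_t$pe,
                                 accepted = pe_c$accepted && pe_t$accepted)
    }
    df <- do.call(rbind, lapply(keep, as.data.frame))
    utils::write.csv(df, file.path(out_dir, "verification.csv"),
                     row.names = FALSE)
    keep
  })

  accepted <- Filter(function(v) v$accepted, verify)
  if (!length(accepted)) {
    stop("pipeline halted at stage \"safe_space\": no dissolution condition ",
         "passed the prediction-error filter", call. = FALSE)
  }
  sel <- accepted[[1]]

  space <- stage("safe_space", function() {
    design <- trial_design(cfg$trial$n_subjects, cfg$trial$n_periods,
                           seed = cfg$seed)
    ss <- map_safe_space(sel$ref_pH, cfg$safe_space$grid, design, obj$model,
                         analyte = cfg$safe_space$analyte, refine = FALSE)
    utils::write.csv(ss$grid, file.path(out_dir, "safe_space.csv"),
                     row.names = FALSE)
    ss
  })

  sstab <- stage("sample_size", function() {
    ga <- space$grid[space$grid$analyte %in% c("R", "S"), ]
    scen <- data.frame(analyte = ga$analyte,
                       GMR_pct = pmin(pmax(ga$GMR, 80.5), 124.5),
                       WSV_CV = 14.89)
    tab <- sample_size_table(scen)
    tab$test_pH <- ga$test_pH
    utils::write.csv(tab, file.path(out_dir, "sample_size.csv"),
                     row.names = FALSE)
    tab
  })

  campaign <- stage("vbe_campaign", function() {
    camp <- run_vbe_campaign(cfg$campaign$n_subjects, cfg$campaign$runs,
                             cfg$campaign$replicates,
                             test_surface_pH = sel$test_pH,
                             reference_surface_pH = sel$ref_pH,
                             cfg = obj$model, seed = cfg$seed)
    utils::write.csv(camp$records, file.path(out_dir, "vbe_records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(camp$success_rate),
                         file.path(out_dir, "vbe_success.json"),
                         auto_unbox = TRUE, digits = NA)
    camp
  })

  manifest$selected_condition <- sel$condition
  write_manifest()
  invisible(list(manifest = manifest, fits = fits, verification = verify,
                 safe_space = space, sample_size = sstab,
                 campaign = campaign))
}

protocol_from_spec <- function(spec) {
  pre_h <- if (is.na(spec$pretreatment_pH)) 0 else spec$pretreatment_duration_h
  two_stage_protocol(medium = "medium", medium_pH = spec$medium_pH,
                     pretreatment_pH = spec$pretreatment_pH,
                     pretreatment_h = max(pre_h, 1e-6),
                     treatment_h = max(spec$sampling_times_h) - pre_h,
                     volume_mL = spec$volume_mL)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(cfg))), collapse = "\n")
  # small portable FNV-1a style hash; avoids a digest dependency
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(h, ch)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
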