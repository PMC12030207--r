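#' Write and read dissolution profiles as CSV
#'
#' The on-disk dialect is comma-separated with a dot decimal and a
#' mandatory header; times in hours, fractions in percent. Columns:
#' `time_h`, `f_dissolved_pct`, `product`, `stage`.
#'
#' @param profile A `dissolution_profile`.
#' @param path Output path.
#' @return `path` invisibly (write) or a `dissolution_profile` (read).
#' @export
write_dissolution_csv <- function(profile, path) {
  df <- data.frame(time_h = profile$time_h,
                   f_dissolved_pct = profile$f_dissolved_pct,
                   product = attr(profile, "product") %||% "reference",
                   stage = profile$stage %||% NA_character_)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dissolution_csv
#' @export
read_dissolution_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "f_dissolved_pct")
  if (!all(need %in% names(df))) {
    stop("dissolution CSV must have columns time_h and f_dissolved_pct",
         call. = FALSE)
  }
  if (any(df$f_dissolved_pct < 0 | df$f_dissolved_pct > 100)) {
    stop("fractions dissolved must lie in [0, 100] percent", call. = FALSE)
  }
  prod <- if ("product" %in% names(df)) df$product[1] else "reference"
  out <- df[order(df$time_h), c("time_h", "f_dissolved_pct",
                                intersect("stage", names(df)))]
  rownames(out) <- NULL
  structure(out, class = c("dissolution_profile", "data.frame"),
            product = prod)
}

#' Write a trial PK/Cmax dataset as CSV
#'
#' Long format: one row per subject, period, treatment, analyte and metric
#' (`id`, `period`, `treatment`, `analyte`, `cmax`, `tmax`, `log_cmax`).
#'
#' @param records Trial records from [run_crossover_trial()] or
#'   [generate_pk_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
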