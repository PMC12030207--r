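#' Define a staged in vitro dissolution protocol
#'
#' A protocol is an ordered list of stages (e.g. an acidic pretreatment
#' followed by the buffered treatment medium). Dissolved drug and remaining
#' solid carry over across stage boundaries; medium pH and volume switch
#' instantaneously.
#'
#' @param stages A list of stages created by [protocol_stage()].
#' @param temperature_C Bath temperature, degrees Celsius (recorded only).
#' @return An object of class `dissolution_protocol`.
#' @export
dissolution_protocol <- function(stages, temperature_C = 37) {
  if (!length(stages)) stop("protocol needs at least one stage", call. = FALSE)
  stages <- lapply(stages, function(s) {
    stopifnot(inherits(s, "protocol_stage"))
    s
  })
  structure(list(stages = stages, temperature_C = temperature_C),
            class = "dissolution_protocol")
}

#' Define one protocol stage
#'
#' @param medium Medium name, e.g. `"PB5"` (phosphate buffer 5 mM),
#'   `"MB7"` (maleate buffer 7 mM), `"HCl"`.
#' @param pH Bulk medium pH.
#' @param volume_mL Vessel volume, mL.
#' @param duration_h Stage duration, hours.
#' @return An object of class `protocol_stage`.
#' @export
protocol_stage <- function(medium, pH, volume_mL, duration_h) {
  if (volume_mL <= 0 || duration_h <= 0) {
    stop("stage volume and duration must be positive", call. = FALSE)
  }
  if (pH <= 0 || pH >= 14) stop("stage pH must lie in (0, 14)", call. = FALSE)
  structure(list(medium = medium, pH = pH, volume_mL = volume_mL,
                 duration_h = duration_h),
            class = "protocol_stage")
}

#' Two-stage acid-pretreatment protocol
#'
#' Convenience constructor for the assay design used for ibuprofen IR
#' tablets: an optional HCl pretreatment stage followed by the buffered
#' treatment medium (PB50, PB5 or MB7).
#'
#' @param medium Treatment medium label.
#' @param medium_pH Treatment medium pH.
#' @param pretreatment_pH pH of the HCl pretreatment, or `NA` for none.
#' @param pretreatment_h Pretreatment duration, h.
#' @param treatment_h Treatment duration, h.
#' @param volume_mL Vessel volume for both stages, mL.
#' @return A [dissolution_protocol()].
#' @export
two_stage_protocol <- function(medium = "MB7", medium_pH = 6.5,
                               pretreatment_pH = 2.0, pretreatment_h = 0.5,
                               treatment_h = 4, volume_mL = 900) {
  stages <- list()
  if (!is.na(pretreatment_pH)) {
    stages <- c(stages, list(protocol_stage("HCl", pretreatment_pH,
                                            volume_mL, pretreatment_h)))
  }
  stages <- c(stages, list(protocol_stage(medium, medium_pH,
                                          volume_mL, treatment_h)))
  dissolution_protocol(stages)
}

#' Total duration of a protocol in hours
#' @param protocol A [dissolution_protocol()].
#' @return Numeric, hours.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "dissolution_protocol"))
  sum(vapply(protocol$stages, `[[`, numeric(1), "duration_h"))
}
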