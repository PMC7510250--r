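#' Unit conversions
#'
#' The solver works internally in SI units (Pa, m, m^3/s); configuration
#' files and reports use the clinical units of the vascular literature
#' (mmHg, cm, mL, s). These helpers convert between the two and invert to
#' machine precision.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

# 1 mmHg in Pa
.MMHG_PA <- 133.322
# 1 mL in m^3
.ML_M3 <- 1e-6
# 1 mmHg.s/mL in Pa.s/m^3
.RES_SI <- .MMHG_PA / .ML_M3

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * .MMHG_PA

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / .MMHG_PA

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * .ML_M3

#' @rdname units
#' @export
m3_to_ml <- function(x) x / .ML_M3

# resistance: mmHg.s/mL <-> Pa.s/m^3 (internal helpers)
res_to_si <- function(x) x * .RES_SI
res_from_si <- function(x) x / .RES_SI

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("venapump_invalid_parameter", "venapump_error")))
}

check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_invalid("'", nm, "' must be a single positive finite number")
    }
  }
  invisible(TRUE)
}
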