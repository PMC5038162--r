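# All internal computation is in CGS (cm, g, s, dyn); pressures cross the API in
# mmHg and flows in mL/s (1 mL = 1 cm^3, so flow needs no conversion).

#' Unit conversions
#'
#' Helpers converting between the CGS units used internally and the clinical
#' units used at the interface: 1 mmHg = 1333.22 dyn cm^-2, 1 kPa =
#' 7.50062 mmHg, and 1 mmHg mL = 1.33322e-4 J = 1.33322e-2 cJ (stroke work is
#' reported in centijoules).
#'
#' @param x numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @name units
NULL

MMHG_DYN <- 1333.22      # dyn cm^-2 per mmHg
KPA_MMHG <- 7.500617     # mmHg per kPa
MMHG_ML_CJ <- 0.0133322  # cJ per mmHg*mL

#' @rdname units
#' @export
mmHg_to_cgs <- function(x) x * MMHG_DYN

#' @rdname units
#' @export
cgs_to_mmHg <- function(x) x / MMHG_DYN

#' @rdname units
#' @export
kPa_to_mmHg <- function(x) x * KPA_MMHG

#' @rdname units
#' @export
mmHg_to_kPa <- function(x) x / KPA_MMHG

#' @rdname units
#' @export
mmHg_mL_to_cJ <- function(x) x * MMHG_ML_CJ
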