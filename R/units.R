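# Unit conversions at the package boundary. SI internally:
# Pa, m, m^2, m^3, kg, s, Pa.s. Interfaces accept the bench units the
# case-study tables use: mbar, mm, mL, g, um.

#' Unit conversion helpers
#'
#' Convert between the bench units used at the package interfaces
#' (mbar, mL, g, um, mm) and the SI units used internally
#' (Pa, m3, kg, m).
#'
#' @param x Numeric vector to convert.
#' @return Numeric vector in the target unit.
#' @examples
#' mbar_to_pa(450)
#' ml_to_m3(50)
#' @name units
NULL

#' @rdname units
#' @export
mbar_to_pa <- function(x) x * 100

#' @rdname units
#' @export
pa_to_mbar <- function(x) x / 100

#' @rdname units
#' @export
ml_to_m3 <- function(x) x * 1e-6

#' @rdname units
#' @export
m3_to_ml <- function(x) x * 1e6

#' @rdname units
#' @export
g_to_kg <- function(x) x * 1e-3

#' @rdname units
#' @export
kg_to_g <- function(x) x * 1e3

#' @rdname units
#' @export
um_to_m <- function(x) x * 1e-6

#' @rdname units
#' @export
mm_to_m <- function(x) x * 1e-3

abort_cw <- function(msg, class) {
  rlang::abort(msg, class = c(class, "cakewash_error"))
}
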