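#' Pammenter sigmoid vulnerability model
#'
#' Percentage loss of hydraulic conductivity (or percentage of embolized
#' pixels) as a function of xylem pressure, under the two-parameter sigmoid
#' model standard in plant hydraulics:
#'
#' \deqn{PLC(\Psi) = 100 / (1 + \exp(S/25 \cdot (\Psi - \Psi_{50})))}
#'
#' `psi50` is the xylem pressure (MPa, negative) inducing 50% loss of
#' conductivity and `slope` (S, % MPa^-1) is the slope of the curve at the
#' inflexion point. PLC increases towards 100 as `psi` becomes more negative.
#'
#' @param psi Xylem pressure / water potential, MPa (negative under tension).
#' @param psi50 Pressure inducing 50% loss of conductivity, MPa.
#' @param slope Slope at the inflexion point, % MPa^-1 (> 0).
#' @return PLC in percent, same length as `psi`.
#' @examples
#' pammenter_plc(-2.5, psi50 = -2.5, slope = 50)  # exactly 50
#' @export
pammenter_plc <- function(psi, psi50, slope) {
  100 / (1 + exp(slope / 25 * (psi - psi50)))
}

#' Embolism onset and lethal thresholds from a fitted sigmoid
#'
#' The pressures inducing 12% and 88% loss of conductivity follow directly
#' from the sigmoid parameters: `psi12 = 50/S + psi50` and
#' `psi88 = -50/S + psi50`. At these pressures the model evaluates to
#' 100/(1+e^2) (about 11.92%) and 100/(1+e^-2) (about 88.08%).
#'
#' @param psi50 Pressure inducing 50% loss, MPa.
#' @param slope Sigmoid slope S, % MPa^-1; must be positive.
#' @return Named list with `psi12` and `psi88` (MPa); always
#'   `psi88 < psi50 < psi12`.
#' @examples
#' derive_thresholds(-2.0, 50)  # psi12 = -1, psi88 = -3
#' @export
derive_thresholds <- function(psi50, slope) {
  if (!is.numeric(slope) || any(slope <= 0)) {
    stop("`slope` must be positive to derive thresholds", call. = FALSE)
  }
  list(psi12 = 50 / slope + psi50, psi88 = -50 / slope + psi50)
}
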