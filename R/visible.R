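#' Predicted reduced fraction in a visible redox titration
#'
#' Forward model for a potentiometric titration followed by visible
#' spectroscopy. The alpha-band area integrates the contribution of all three
#' hemes with equal optical weight, so the observable is one minus the mean
#' of the three marginal heme oxidation fractions:
#' `(3 - sum_i f_ox(i)) / 3`.
#'
#' @inheritParams heme_oxidation_fraction
#' @return Reduced fraction(s) in \[0, 1\], nonincreasing in potential.
#' @examples
#' predicted_reduced_fraction(ppc_params("ppcA_Gu"),
#'                            potential = c(-250, -75, 50), ph = 7)
#' @export
predicted_reduced_fraction <- function(params, potential, ph) {
  stopifnot(inherits(params, "thermo_params"))
  fr <- fraction_matrix(params, potential, ph)
  ox <- t(.ox_matrix) %*% fr
  unname(1 - colMeans(ox))
}

#' Uncertainty of a visible-titration point
#'
#' The optical signal carries a relative error of 3%; the uncertainty of a
#' reduced-fraction point is therefore `0.03 * reduced_fraction`, floored at
#' a fraction of 0.05 (`sigma >= 0.0015`) so fully oxidized points do not
#' receive infinite weight in the fit.
#'
#' @param reduced_fraction Reduced fraction(s) in \[0, 1\].
#' @param rel_error Relative optical error; default 0.03.
#' @param floor Signal floor applied before scaling; default 0.05.
#' @return Uncertainty (same units as the fraction).
#' @export
visible_sigma <- function(reduced_fraction, rel_error = 0.03, floor = 0.05) {
  rel_error * pmax(reduced_fraction, floor)
}
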