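#' Banded squared loss
#'
#' Mean over observations of `max(0, |d - y| - band)^2`: residuals inside a
#' tolerance band of `band` cm contribute nothing, larger residuals are
#' penalised like a shifted squared error.  Height measurement itself
#' carries roughly half-centimetre error, so residuals that small are
#' treated as already correct; with `band = 0` the loss reduces exactly to
#' mean squared error.  The hinge `max(0, .)^2` is continuously
#' differentiable, including at the band boundary.
#'
#' @param y Predictions in cm.
#' @param d Targets in cm, same length as `y`.
#' @param band Half-width of the tolerance band in cm (>= 0, default 0.5).
#' @return A single non-negative number (cm^2); zero iff every residual has
#'   absolute value at most `band`.
#' @export
#' @examples
#' band_loss(170.4, 170)        # inside the band: 0
#' band_loss(168, 170)          # (2 - 0.5)^2 = 2.25
#' band_loss(c(169, 160.5), c(170, 160))  # (0.5^2 + 0)/2 = 0.125
band_loss <- function(y, d, band = 0.5) {
  if (length(y) == 0L || length(d) == 0L) stopf("empty loss inputs")
  if (length(y) != length(d)) stopf("y and d differ in length")
  if (any(!is.finite(y)) || any(!is.finite(d))) stopf("non-finite loss inputs")
  check_number(band, "band", lower = 0)
  mean(pmax(abs(d - y) - band, 0)^2)
}

#' Gradient of the banded squared loss with respect to predictions
#'
#' Per-element `(2/n) * sign(y_i - d_i) * max(0, |y_i - d_i| - band)`;
#' identically zero inside the band.  Matches central finite differences
#' away from the (measure-zero) band boundary.
#'
#' @inheritParams band_loss
#' @return Numeric vector `d loss / d y`, same length as `y`.
#' @export
band_loss_gradient <- function(y, d, band = 0.5) {
  if (length(y) == 0L || length(d) == 0L) stopf("empty loss inputs")
  if (length(y) != length(d)) stopf("y and d differ in length")
  check_number(band, "band", lower = 0)
  r <- y - d
  (2 / length(y)) * sign(r) * pmax(abs(r) - band, 0)
}
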