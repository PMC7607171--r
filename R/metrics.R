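# Combination-effect scoring outside the regression: Bliss independence
# for in-vivo fractions, synergy/additivity calls, and the caliper
# tumor-volume formula.

#' Bliss-independence inhibition rate of a drug combination
#'
#' Under Bliss independence each drug acts through an independent mechanism,
#' so the expected fraction of tumor volume (or viability) remaining after
#' the combination is the product of the single-drug fractions:
#' \code{IR = F1 * F2 * ... * Fk}. Fractions above 1 are allowed (a drug may
#' stimulate growth).
#'
#' The field convention sometimes quotes this product directly as a percent
#' "inhibition" even though, by construction, it is the predicted
#' *remaining* fraction. To keep the two readings from being confused, all
#' three quantities are returned under explicit names.
#'
#' @param fractions numeric vector (length >= 2) of single-drug fractions
#'   remaining versus 100% control, all > 0.
#' @return list: \code{product} (the raw IR), \code{paper_pct}
#'   (\code{100 * product}, the percent-scale convention used when quoting
#'   the IR), and \code{complement_pct} (\code{100 * (1 - product)}, the
#'   literal predicted percent inhibition).
#' @examples
#' bliss_ir(c(0.90, 0.82, 0.62, 1.06))$paper_pct   # 48.5
#' bliss_ir(c(0.65, 0.55, 0.74, 0.76))$paper_pct   # 20.1
#' @export
bliss_ir <- function(fractions) {
  fractions <- as.numeric(fractions)
  if (length(fractions) < 2L)
    stop("Bliss independence needs at least two single-drug fractions")
  if (any(!is.finite(fractions)) || any(fractions <= 0))
    stop("all fractions remaining must be finite and > 0")
  ir <- prod(fractions)
  list(product = ir, paper_pct = 100 * ir, complement_pct = 100 * (1 - ir))
}

#' Classify an observed combination effect against the Bliss prediction
#'
#' Compares the observed combination effect with the Bliss-independence
#' expectation: synergistic if the observed effect exceeds the prediction by
#' more than \code{tolerance} percentage points, antagonistic if it falls
#' short by more, additive within the band.
#'
#' @param observed observed combination effect.
#' @param predicted Bliss-predicted effect, on the same scale.
#' @param scale either \code{"inhibition_pct"} (percent inhibition; larger =
#'   stronger effect) or \code{"fraction_remaining"} (smaller = stronger
#'   effect). Both inputs must share it.
#' @param tolerance half-width of the additivity band, percentage points.
#' @return one of \code{"synergistic"}, \code{"additive"},
#'   \code{"antagonistic"}.
#' @examples
#' classify_combination_effect(64, 17)   # "synergistic"
#' @export
classify_combination_effect <- function(observed, predicted,
                                        scale = c("inhibition_pct",
                                                  "fraction_remaining"),
                                        tolerance = 5) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(observed), is.numeric(predicted), tolerance >= 0)
  if (scale == "fraction_remaining") {
    if (observed > 1.5 || predicted > 1.5)
      stop("values look like percentages, not fractions remaining: ",
           "declare scale = 'inhibition_pct'")
    observed <- 100 * (1 - observed)
    predicted <- 100 * (1 - predicted)
  }
  delta <- observed - predicted
  if (delta > tolerance) "synergistic"
  else if (delta < -tolerance) "antagonistic"
  else "additive"
}

#' Caliper tumor volume
#'
#' The standard ellipsoid approximation from two caliper diameters:
#' \deqn{V = d_{small}^2 \times d_{big} / 2.}
#' A literal sum reading (\code{d_small^2 + d_big / 2}), occasionally seen
#' in print, is available behind \code{formula = "sum"} but is not the
#' accepted volume formula.
#'
#' @param d_small,d_big smallest and biggest tumor diameters (mm),
#'   \code{0 < d_small <= d_big}.
#' @param formula \code{"product"} (default, ellipsoid approximation) or
#'   \code{"sum"} (literal reading).
#' @return tumor volume in mm^3.
#' @examples
#' tumor_volume(2, 2)   # 4
#' @export
tumor_volume <- function(d_small, d_big, formula = c("product", "sum")) {
  formula <- match.arg(formula)
  stopifnot(is.numeric(d_small), is.numeric(d_big))
  if (any(d_small <= 0)) stop("diameters must be positive")
  if (any(d_small > d_big))
    stop("d_small must not exceed d_big")
  if (formula == "product") d_small^2 * d_big / 2
  else d_small^2 + d_big / 2
}
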