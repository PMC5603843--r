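# Cost-effectiveness acceptability curves: convert net benefit
# regression fits into probabilities of cost-effectiveness across the
# willingness-to-pay grid.

#' Probability that a strategy is cost-effective
#'
#' Under the large-sample normal approximation, the probability that the
#' true incremental net benefit is positive is the standard normal CDF of
#' `inb / se`. This coincides exactly with the one-sided p-value rule:
#' for a negative INB the probability equals the one-sided p-value (half
#' the regression's two-sided p), and for a positive INB it equals one
#' minus the one-sided p-value. With `se = 0` the probability degenerates
#' to 1, 0 or 0.5 according to the sign of `inb`.
#'
#' @param inb incremental net benefit estimate(s).
#' @param se standard error(s), >= 0.
#' @return probability in \[0, 1\] (vectorised).
#' @export
ce_probability <- function(inb, se) {
  if (any(se < 0)) stop_field("se", "standard errors must be >= 0")
  ifelse(se > 0, pnorm(inb / se),
         ifelse(inb > 0, 1, ifelse(inb < 0, 0, 0.5)))
}

#' Assemble a cost-effectiveness acceptability curve
#'
#' Takes net benefit regression results for one strategy over a strictly
#' increasing willingness-to-pay grid and attaches the one-sided p-value
#' and the probability of cost-effectiveness at each grid point.
#'
#' @param fits a data frame with columns `lambda`, `inb`, `se` (e.g. the
#'   per-strategy rows of a pipeline's INB table), or a list of
#'   [fit_nbr()] results sharing one strategy.
#' @param strategy strategy label attached to the curve.
#' @return data frame of class `ceac_curve`: `strategy`, `lambda`, `inb`,
#'   `se`, `p_one_sided`, `probability`, ordered by `lambda`.
#' @export
build_ceac <- function(fits, strategy = attr(fits, "strategy") %||% "treatment") {
  if (!is.data.frame(fits))
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(lambda = f$lambda, inb = f$inb, se = f$se)))
  fits <- fits[order(fits$lambda), , drop = FALSE]
  if (anyDuplicated(fits$lambda))
    stop("duplicate willingness-to-pay values in the grid", call. = FALSE)
  prob <- ce_probability(fits$inb, fits$se)
  p_one <- ifelse(fits$se > 0, pnorm(-abs(fits$inb) / fits$se),
                  0.5 * (fits$inb == 0))
  structure(data.frame(strategy = strategy, lambda = fits$lambda,
                       inb = fits$inb, se = fits$se,
                       p_one_sided = p_one, probability = prob,
                       row.names = NULL),
            class = c("ceac_curve", "data.frame"))
}
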