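# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field, allow_one = TRUE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (any(!is.finite(x)) || any(x < 0) || any(!hi_ok))
    stop_field(field, if (allow_one) "must lie in [0, 1]" else "must lie in [0, 1)")
  invisible(x)
}

#' Ridge-penalised logistic regression by Newton iteration
#'
#' Small internal fitter used where an estimate *and* a parameter
#' covariance matrix are both needed under possible quasi-separation:
#' parameter draws for proper multiple imputation, and the stabilised
#' fallback of [fit_propensity()]. The penalty `ridge` is added to the
#' diagonal of the information matrix; at the default (1e-4) the fit is
#' numerically indistinguishable from the MLE away from separation.
#'
#' @param x numeric design matrix (including intercept column).
#' @param y 0/1 response.
#' @param ridge penalty on the squared coefficient norm.
#' @param max_iter,tol Newton iteration controls.
#' @return list with `coef`, `vcov` (inverse penalised information), and
#'   `converged`.
#' @keywords internal
ridge_logit <- function(x, y, ridge = 1e-4, max_iter = 60, tol = 1e-8) {
  x <- as.matrix(x)
  p <- ncol(x)
  beta <- numeric(p)
  converged <- FALSE
  h <- diag(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(x, y - mu)) - ridge * beta
    h <- crossprod(x, x * w) + ridge * diag(p)
    step <- solve(h, g)
    beta <- beta + step
    if (max(abs(g)) < tol * (1 + sum(abs(y)))) {
      converged <- TRUE
      break
    }
  }
  list(coef = setNames(drop(beta), colnames(x)),
       vcov = solve(h),
       converged = converged)
}

# Present value of a stream anchored at offsets `t` (years from reference).
pv_factor <- function(t, rate) (1 + rate)^(-t)

#' Report-formatting helpers
#'
#' Rounding rules used throughout the written tables: ICERs to whole
#' dollars, probabilities to 4 decimals, effects to 5 decimals, cohort
#' shares to one decimal percentage point.
#'
#' @param x numeric value(s).
#' @param n,total counts for a share.
#' @return character vector of formatted values (`fmt_share` returns the
#'   percentage with one decimal, e.g. `"10.5"`).
#' @examples
#' fmt_icer(2465.35)   # "2465"
#' fmt_prob(0.76223)   # "0.7622"
#' fmt_share(234, 2222) # "10.5"
#' @export
fmt_icer <- function(x) ifelse(is.na(x), "", sprintf("%.0f", round(x)))

#' @rdname fmt_icer
#' @export
fmt_prob <- function(x) sprintf("%.4f", x)

#' @rdname fmt_icer
#' @export
fmt_effect <- function(x) sprintf("%.5f", x)

#' @rdname fmt_icer
#' @export
fmt_share <- function(n, total) sprintf("%.1f", round(100 * n / total, 1))
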