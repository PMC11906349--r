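# Survival function of a positively weighted sum of 1-df chi-square
# variables, Q ~ sum_i lambda_i chi2_1. Primary route is numerical
# inversion of the characteristic function (Imhof's integral); a Kuonen
# saddlepoint approximation takes over in the far tail, where quadrature
# loses all relative accuracy, and is evaluated entirely in log space.

#' @noRd
imhof_p <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda, u)^2)))
    sin(theta) / (u * rho)
  }
  res <- try(stats::integrate(integrand, 0, Inf, rel.tol = 1e-6,
                              abs.tol = 1e-9, subdivisions = 500L),
             silent = TRUE)
  if (inherits(res, "try-error")) return(NA_real_)
  0.5 + res$value / pi
}

#' @noRd
saddlepoint_logp <- function(q, lambda) {
  lmax <- max(lambda)
  if (q <= sum(lambda)) return(log(0.5))   # left of the mean: not a tail
  Kp <- function(z) sum(lambda / (1 - 2 * z * lambda)) - q
  upper <- 1 / (2 * lmax) - 1e-12
  root <- stats::uniroot(Kp, lower = -1e4 / lmax, upper = upper,
                         tol = 1e-14)$root
  K <- -0.5 * sum(log1p(-2 * root * lambda))
  K2 <- 2 * sum(lambda^2 / (1 - 2 * root * lambda)^2)
  w <- sign(root) * sqrt(2 * (root * q - K))
  v <- root * sqrt(K2)
  if (abs(w) < 1e-8) return(log(0.5))
  stats::pnorm(w + log(v / w) / w, lower.tail = FALSE, log.p = TRUE)
}

#' Tail probability of a weighted sum of chi-squared(1) variables
#'
#' @param q observed statistic.
#' @param lambda positive eigenvalue weights.
#' @param method `"auto"` (integration in the body of the distribution,
#'   log-space saddlepoint below 1e-5 — beneath the quadrature's noise
#'   floor — or on quadrature failure), `"integration"` or
#'   `"saddlepoint"`.
#' @return list with `p` and `log10p`.
#' @export
pchisqsum <- function(q, lambda, method = c("auto", "integration",
                                            "saddlepoint")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 1e-12 * max(lambda)]
  assert_that(length(lambda) > 0, "no positive eigenvalues")
  if (length(lambda) == 1L) {
    lp <- stats::pchisq(q / lambda, df = 1, lower.tail = FALSE,
                        log.p = TRUE)
    return(list(p = exp(lp), log10p = lp / log(10)))
  }
  if (method != "saddlepoint") {
    p <- imhof_p(q, lambda)
    usable <- !is.na(p) && p > 0 &&
      (method == "integration" || p > 1e-5)
    if (usable) {
      p <- min(p, 1)
      return(list(p = p, log10p = log10(p)))
    }
  }
  lp <- saddlepoint_logp(q, lambda)
  list(p = exp(lp), log10p = lp / log(10))
}
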