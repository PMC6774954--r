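#' JZS Bayes factor for a one-sample design
#'
#' Jeffreys-Zellner-Siow Bayes factor comparing H1 (standardized effect
#' delta ~ Cauchy(0, scale)) against H0 (delta = 0), computed from the
#' one-sample t statistic by numerical integration over the mixing
#' parameter g (with g ~ inverse-gamma(1/2, scale^2/2) the Cauchy prior
#' arises as a scale mixture of normals):
#' \deqn{BF_{01} = \frac{(1+t^2/\nu)^{-(\nu+1)/2}}
#'   {\int_0^\infty (1+Ng)^{-1/2}\,(1+t^2/((1+Ng)\nu))^{-(\nu+1)/2}
#'    \,\pi(g)\,dg}}
#' with N = n x scale^2 and nu = n - 1. BF10 is its reciprocal, so
#' `jzs_bf_one_sample(x) * 1/jzs_bf_one_sample(x)` is always 1.
#'
#' @param values data vector (used to form t and n); alternatively pass
#'   `t` and `n` directly.
#' @param mu0 null location for the t statistic.
#' @param scale Cauchy prior scale, default `sqrt(2)/2`.
#' @param t,n t statistic and sample size, if `values` is NULL.
#' @return BF10, evidence for the alternative over the null.
#' @export
jzs_bf_one_sample <- function(values = NULL, mu0 = 0, scale = sqrt(2) / 2,
                              t = NULL, n = NULL) {
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    n <- length(values)
    if (n < 2) stop("need at least two observations")
    s <- sd(values)
    if (s == 0) stop("zero variance: t statistic undefined")
    t <- (mean(values) - mu0) / (s / sqrt(n))
  }
  stopifnot(is.numeric(t), is.numeric(n), n >= 2)
  nu <- n - 1
  nn <- n * scale^2
  null_lik <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + nn * g)^(-1 / 2) *
      (1 + t^2 / ((1 + nn * g) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt_lik <- integrate(integrand, 0, Inf, rel.tol = 1e-9,
                       subdivisions = 500L)$value
  alt_lik / null_lik
}

#' JZS Bayes factor for a Pearson correlation
#'
#' Bayes factor for a correlation via the JZS linear-regression prior
#' (one standardized predictor):
#' \deqn{BF_{10} = \int_0^\infty (1+g)^{(n-2)/2}
#'   \,(1+(1-r^2)g)^{-(n-1)/2}\,
#'   \sqrt{n/2}\,\Gamma(1/2)^{-1}\,g^{-3/2}\,e^{-n/(2g)}\,dg}
#'
#' @param r observed Pearson correlation.
#' @param n number of pairs.
#' @return BF10.
#' @export
jzs_bf_correlation <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3)
  if (abs(r) >= 1 - 1e-12) return(Inf)  # perfect correlation
  integrand <- function(g) {
    exp(((n - 2) / 2) * log1p(g) - ((n - 1) / 2) * log1p((1 - r^2) * g) +
          0.5 * log(n / 2) - lgamma(0.5) - 1.5 * log(g) - n / (2 * g))
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-9, subdivisions = 500L)$value
}
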