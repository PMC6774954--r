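# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# exact one-sample signed-rank p by full 2^n sign enumeration
# (requires distinct nonzero |x - mu0|)
enum_wilcoxon <- function(x, mu0 = 0,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d <- x - mu0
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  list(V = v_obs, p = p)
}

# JZS one-sample BF10 by direct quadrature over the effect-size prior
# (noncentral-t likelihood against the Cauchy prior; independent of the
# package's g-mixture route)
quad_jzs_bf <- function(t, n, scale = sqrt(2) / 2) {
  num <- suppressWarnings(integrate(function(delta)
    dt(t, df = n - 1, ncp = delta * sqrt(n)) *
      dcauchy(delta, 0, scale),
    -Inf, Inf, rel.tol = 1e-9)$value)
  num / dt(t, df = n - 1)
}

# brute-force max-|cluster-mass| null for a small participants x bins
# matrix: plain loops and stats::t.test per bin
brute_cluster_null <- function(diffs, threshold = 2) {
  n <- nrow(diffs)
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  out <- numeric(nrow(signs))
  for (s in seq_len(nrow(signs))) {
    d <- diffs * signs[s, ]
    tv <- rep(NA_real_, ncol(d))
    for (j in seq_len(ncol(d))) {
      col <- d[, j][!is.na(d[, j])]
      if (length(col) >= 2 && sd(col) > 0)
        tv[j] <- unname(t.test(col)$statistic)
    }
    best <- 0
    cur <- 0; cur_sign <- 0
    for (j in seq_along(tv)) {
      ok <- !is.na(tv[j]) && abs(tv[j]) > threshold
      sgn <- if (ok) sign(tv[j]) else 0
      if (ok && sgn == cur_sign) {
        cur <- cur + tv[j]
      } else if (ok) {
        cur <- tv[j]; cur_sign <- sgn
      } else {
        cur <- 0; cur_sign <- 0
      }
      best <- max(best, abs(cur))
    }
    out[s] <- best
  }
  out
}
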