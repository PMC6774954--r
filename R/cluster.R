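#' Cluster-permutation configuration
#'
#' @param t_threshold per-bin t threshold defining supra-threshold bins
#'   (|t| > threshold).
#' @param n_permutations Monte-Carlo permutations for the null.
#' @param alpha family-wise significance level.
#' @param chance_level chance target proportion; transformed with the
#'   series before differencing, so vs-chance tests are one-sample t
#'   tests against `arcsinsqrt(chance_level)`.
#' @param seed RNG seed for the permutation draw.
#' @return an object of class `cluster_config`.
#' @export
cluster_config <- function(t_threshold = 2, n_permutations = 1000,
                           alpha = 0.05, chance_level = 0.5, seed = 1L) {
  stopifnot(t_threshold > 0, n_permutations >= 1, alpha > 0, alpha < 1,
            chance_level >= 0, chance_level <= 1)
  structure(list(t_threshold = t_threshold,
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, chance_level = chance_level,
                 seed = as.integer(seed)),
            class = "cluster_config")
}

#' Per-bin one-sample t statistics
#'
#' One t per column of a participants x bins matrix, against `mu0`.
#' Columns with fewer than two non-missing values, or zero variance,
#' give NA.
#'
#' @param values numeric matrix, rows = participants, columns = bins.
#' @param mu0 null value.
#' @return numeric vector of t statistics, one per column.
#' @export
bin_tstats <- function(values, mu0 = 0) {
  values <- as.matrix(values)
  n <- colSums(!is.na(values))
  m <- colMeans(values, na.rm = TRUE) - mu0
  ss <- colSums(values^2, na.rm = TRUE) -
    n * (m + mu0)^2
  v <- ss / pmax(n - 1, 1)
  t <- m / sqrt(v / n)
  t[n < 2 | v <= 0] <- NA_real_
  unname(t)
}

#' Form clusters of supra-threshold bins
#'
#' Maximal runs of contiguous bins with |t| above the threshold and a
#' common sign; a sign change, a sub-threshold bin or a missing bin
#' breaks the run. Cluster mass is the sum of the t values in the run.
#'
#' @param t per-bin t statistics (NA allowed).
#' @param threshold positive threshold on |t|.
#' @return a `data.table` with `start_bin`, `end_bin` (indices into
#'   `t`), `mass` and `sign`; zero rows when no bin is supra-threshold.
#' @export
form_clusters <- function(t, threshold = 2) {
  stopifnot(threshold > 0)
  state <- ifelse(is.na(t) | abs(t) <= threshold, 0L, as.integer(sign(t)))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.table(start_bin = integer(), end_bin = integer(),
                      mass = numeric(), sign = integer()))
  data.table(start_bin = starts[keep], end_bin = ends[keep],
             mass = vapply(which(keep), function(i)
               sum(t[starts[i]:ends[i]]), numeric(1)),
             sign = r$values[keep])
}

# max |mass| for one t series; 0 when no cluster forms
max_cluster_mass <- function(t, threshold) {
  cl <- form_clusters(t, threshold)
  if (nrow(cl)) max(abs(cl$mass)) else 0
}

#' Permutation null of the maximum cluster mass
#'
#' Participant-level sign-flip null: each permutation flips the sign of
#' whole participant rows of the difference matrix (equivalently, swaps
#' the participant's condition labels, or reflects the participant's
#' series about chance), recomputes the per-bin t series, and records
#' the largest absolute cluster mass (0 when no cluster forms).
#' `exhaustive = TRUE` enumerates all `2^n` sign patterns instead of
#' sampling, exact for small n.
#'
#' @param diffs participants x bins matrix of differences from the null
#'   (series minus transformed chance, or matching minus related).
#' @param config a [cluster_config()].
#' @param exhaustive enumerate all sign patterns.
#' @return numeric vector of max |mass| values, one per permutation.
#' @export
permutation_null <- function(diffs, config = cluster_config(),
                             exhaustive = FALSE) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2) stop("at least two participants are required")
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    set.seed(config$seed)
    signs <- matrix(sample(c(1, -1), config$n_permutations * n,
                           replace = TRUE),
                    nrow = config$n_permutations)
  }
  d0 <- diffs; d0[is.na(d0)] <- 0
  n_j <- colSums(!is.na(diffs))
  ss_j <- colSums(diffs^2, na.rm = TRUE)  # invariant under sign flips
  num <- signs %*% d0                      # permutations x bins sums
  means <- sweep(num, 2, pmax(n_j, 1), "/")
  apply_row <- function(i) {
    m <- means[i, ]
    v <- (ss_j - n_j * m^2) / pmax(n_j - 1, 1)
    t <- m / sqrt(v / n_j)
    t[n_j < 2 | v <= 0] <- NA_real_
    max_cluster_mass(t, config$t_threshold)
  }
  vapply(seq_len(nrow(signs)), apply_row, numeric(1))
}

#' Cluster p values from a permutation null
#'
#' Family-wise p per observed cluster with the add-one rule:
#' `p = (1 + #(null >= |mass|)) / (1 + n_permutations)`, never exactly
#' zero.
#'
#' @param clusters output of [form_clusters()].
#' @param null output of [permutation_null()].
#' @return `clusters` with a `p` column.
#' @export
cluster_pvalues <- function(clusters, null) {
  cl <- copy(as.data.table(clusters))
  cl[, p := vapply(mass, function(m)
    (1 + sum(null >= abs(m))) / (1 + length(null)), numeric(1))]
  cl[]
}

#' Cluster-based permutation test on binned looking series
#'
#' The full procedure on participant-average binned target proportions:
#' arcsine-square-root transform, per-bin t statistics (one-sample
#' against transformed chance, or paired matching vs related), clusters
#' of contiguous supra-threshold bins, and family-wise p values from a
#' participant-level sign-flip permutation null of the maximum cluster
#' mass.
#'
#' @param series participant series ([participant_series()] schema) for
#'   one condition (or pooled), containing the trial types the
#'   comparison needs.
#' @param comparison `"matching_vs_chance"`, `"related_vs_chance"` or
#'   `"matching_vs_related"`.
#' @param config a [cluster_config()].
#' @param exhaustive exact enumeration of the sign-flip null.
#' @return an object of class `cluster_result`: `clusters` (with p),
#'   `t` per bin, `bin_start_ms`, `null`, `comparison`, `n`.
#' @export
cluster_test <- function(series, comparison = c("matching_vs_chance",
                                                "related_vs_chance",
                                                "matching_vs_related"),
                         config = cluster_config(), exhaustive = FALSE) {
  comparison <- match.arg(comparison)
  s <- as.data.table(series)
  bins <- sort(unique(s$bin_start_ms))
  pivot <- function(type) {
    w <- dcast(s[trial_type == type], participant_id ~ bin_start_ms,
               value.var = "prop")
    m <- as.matrix(w[, -1])
    rownames(m) <- w$participant_id
    m[, as.character(bins), drop = FALSE]
  }
  if (comparison == "matching_vs_related") {
    a <- pivot("matching"); b <- pivot("related")
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 2) stop("at least two participants are required")
    diffs <- arcsinsqrt(a[common, , drop = FALSE]) -
      arcsinsqrt(b[common, , drop = FALSE])
  } else {
    type <- sub("_vs_chance", "", comparison)
    a <- pivot(type)
    if (nrow(a) < 2) stop("at least two participants are required")
    diffs <- arcsinsqrt(a) - arcsinsqrt(config$chance_level)
  }
  t_obs <- bin_tstats(diffs, mu0 = 0)
  clusters <- form_clusters(t_obs, config$t_threshold)
  null <- permutation_null(diffs, config, exhaustive = exhaustive)
  clusters <- cluster_pvalues(clusters, null)
  clusters[, c("start_ms", "end_ms") := .(bins[start_bin],
                                          bins[end_bin] + diff(bins)[1])]
  structure(list(clusters = clusters[], t = t_obs, bin_start_ms = bins,
                 null = null, comparison = comparison, n = nrow(diffs),
                 config = config),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Cluster permutation test (", x$comparison, "), n = ", x$n, "\n",
      sep = "")
  if (!nrow(x$clusters)) {
    cat("No supra-threshold clusters (|t| > ", x$config$t_threshold,
        ")\n", sep = "")
  } else {
    cl <- x$clusters[, .(start_ms, end_ms, mass = round(mass, 2),
                         p = round(p, 4))]
    print(cl)
  }
  invisible(x)
}
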