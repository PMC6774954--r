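#' One-sample Wilcoxon signed-rank test with effect size and Bayes factor
#'
#' The battery's workhorse: signed-rank V against `mu0`, exact p for
#' n <= 25 without ties (normal approximation with continuity correction
#' otherwise; zero differences are dropped per the standard signed-rank
#' convention), the sample mean with a t-based 95% CI, Cohen's d
#' `(mean - mu0)/sd`, and the JZS Bayes factor computed from the same
#' values via the one-sample t BF (the conventional hybrid when V
#' statistics are reported alongside BF10).
#'
#' @param values data vector (NAs dropped).
#' @param mu0 null location.
#' @param alternative `"greater"` (the directional comprehension
#'   hypothesis: positive scores), `"less"` or `"two.sided"`.
#' @param conf_level CI level.
#' @param bf_scale Cauchy prior scale for the BF.
#' @return an object of class `ipl_stat` with fields `n`, `mean`,
#'   `ci`, `statistic` (V), `p`, `d`, `bf10`, `tail`, `degenerate`.
#' @examples
#' wilcoxon_one_sample(c(0.1, 0.3, -0.05, 0.2), alternative = "greater")
#' @export
wilcoxon_one_sample <- function(values, mu0 = 0,
                                alternative = c("greater", "two.sided",
                                                "less"),
                                conf_level = 0.95,
                                bf_scale = sqrt(2) / 2) {
  alternative <- match.arg(alternative)
  x <- values[!is.na(values)]
  if (!length(x)) stop("no data")
  d0 <- x - mu0
  nz <- d0[d0 != 0]
  degenerate <- length(nz) == 0L
  if (degenerate) {
    res <- list(statistic = c(V = 0), p.value = 1)
  } else {
    exact <- length(nz) <= 25 && !anyDuplicated(abs(nz)) && all(d0 != 0)
    res <- suppressWarnings(
      wilcox.test(x, mu = mu0, alternative = alternative, exact = exact,
                  correct = TRUE))
  }
  m <- mean(x); s <- sd(x); n <- length(x)
  ci <- if (n >= 2 && s > 0)
    m + qt(c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2), n - 1) *
      s / sqrt(n)
  else c(NA_real_, NA_real_)
  bf <- if (n >= 2 && s > 0)
    jzs_bf_one_sample(x, mu0 = mu0, scale = bf_scale) else NA_real_
  structure(list(n = n, mean = m, ci = ci,
                 statistic = unname(res$statistic), p = res$p.value,
                 d = if (n >= 2 && s > 0) abs(m - mu0) / s else NA_real_,
                 bf10 = bf, mu0 = mu0, tail = alternative,
                 degenerate = degenerate),
            class = "ipl_stat")
}

#' @export
print.ipl_stat <- function(x, digits = 3, ...) {
  cat(sprintf(
    "n = %d, mean = %.*f, 95%% CI [%.*f, %.*f], V = %s, p = %.3g, Cohen d = %.*f, BF10 = %.3g (%s)\n",
    x$n, digits, x$mean, digits, x$ci[1], digits, x$ci[2],
    format(x$statistic), x$p, digits, x$d, x$bf10, x$tail))
  if (isTRUE(x$degenerate)) cat("  (degenerate: all values equal null)\n")
  invisible(x)
}

# tidy one-row summary of an ipl_stat
stat_row <- function(x, ...) {
  data.table(..., n = x$n, mean = x$mean, ci_lo = x$ci[1], ci_hi = x$ci[2],
             V = x$statistic, p = x$p, d = x$d, bf10 = x$bf10,
             tail = x$tail)
}

#' Power of a one-sample t test
#'
#' Via the noncentral t distribution: noncentrality `d * sqrt(n)` with
#' `n - 1` degrees of freedom.
#'
#' @param d standardized effect size.
#' @param n sample size (>= 2).
#' @param alpha significance level.
#' @param tail `"two.sided"` or `"one.sided"`.
#' @return the power.
#' @examples
#' power_one_sample_t(d = 0.41, n = 50)  # ~0.81
#' @export
power_one_sample_t <- function(d, n, alpha = 0.05,
                               tail = c("two.sided", "one.sided")) {
  tail <- match.arg(tail)
  if (n < 2) stop("n must be at least 2")
  stopifnot(alpha > 0, alpha < 1)
  df <- n - 1
  ncp <- d * sqrt(n)
  if (tail == "two.sided") {
    tc <- qt(1 - alpha / 2, df)
    1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  } else {
    1 - pt(qt(1 - alpha, df), df, ncp)
  }
}

#' Minimum within-pair frequency ratio of a stimulus table
#'
#' For each picture-pair in the chosen condition/role subset, the ratio
#' of the higher to the lower child-directed-speech frequency; returns
#' the minimum over pairs (the design floor: frequency-condition pairs
#' are built so the label frequencies differ by at least 7:1).
#'
#' @param stimulus a stimulus table ([read_stimulus_table()]).
#' @param condition condition to check.
#' @param role word role to check.
#' @return the minimal high/low ratio.
#' @examples
#' min_frequency_ratio(read_stimulus_table())  # 107/15
#' @export
min_frequency_ratio <- function(stimulus, condition = "frequency",
                                role = "referent") {
  s <- as.data.table(stimulus)
  keep <- s$condition == condition & s$role == role
  s <- s[which(keep)]
  if (!nrow(s)) stop("no words in the requested subset")
  if (anyNA(s$cds_frequency) || any(s$cds_frequency <= 0))
    stop("subset contains missing or zero frequencies")
  ratios <- s[, max(cds_frequency) / min(cds_frequency), by = pair_id]$V1
  min(ratios)
}

#' Mixed-effects age-trajectory model on pair scores
#'
#' Fits `log(score + 2) ~ trial_type * condition + age_c` with random
#' intercepts for infant and word pair (the offset 2 keeps the log
#' argument >= 1 since scores lie in [-1, 1]; age is mean-centred in
#' days). F tests use Satterthwaite denominator degrees of freedom.
#' Optionally adds the trial-type x age interaction and reports
#' follow-up per-trial-type age slopes from subset refits.
#'
#' @param scores pair scores ([pair_difference_scores()]).
#' @param questionnaires questionnaire table supplying `age_days`.
#' @param trial_age_interaction include `trial_type:age_c`.
#' @param satterthwaite use lmerTest Satterthwaite F tests (slower);
#'   otherwise a plain lme4 fit with Wald machinery.
#' @return list: `model`, `anova` (when `satterthwaite`), `age`
#'   (estimate, SE, Wald 95% CI for the age slope), `simple` (per-trial-
#'   type age slopes when the interaction is requested), `singular`.
#' @export
fit_age_model <- function(scores, questionnaires,
                          trial_age_interaction = FALSE,
                          satterthwaite = TRUE) {
  s <- as.data.table(scores)
  ages <- unique(as.data.table(questionnaires)[, .(participant_id,
                                                   age_days)])
  s <- merge(s, ages, by = "participant_id")
  if (length(unique(s$participant_id)) < 2 ||
      length(unique(s$pair_id)) < 2)
    stop("need at least two infants and two word pairs")
  s[, age_c := age_days - mean(age_days)]
  s[, resp := log(score + 2)]
  fixed <- if (trial_age_interaction)
    "trial_type * condition + age_c + trial_type:age_c"
  else "trial_type * condition + age_c"
  form <- as.formula(paste(
    "resp ~", fixed, "+ (1 | participant_id) + (1 | pair_id)"))
  fitfun <- if (satterthwaite) lmerTest::lmer else lme4::lmer
  model <- suppressMessages(fitfun(form, data = s, REML = TRUE))
  singular <- lme4::isSingular(model)
  an <- if (satterthwaite)
    as.data.frame(stats::anova(model, type = 3)) else NULL
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(vcov(model))))
  i <- which(names(fe) == "age_c")
  age <- c(estimate = unname(fe[i]), se = unname(se[i]),
           ci_lo = unname(fe[i] - 1.96 * se[i]),
           ci_hi = unname(fe[i] + 1.96 * se[i]))
  simple <- NULL
  if (trial_age_interaction) {
    simple <- rbindlist(lapply(unique(s$trial_type), function(tt) {
      sub <- s[trial_type == tt]
      m <- suppressMessages(lme4::lmer(
        resp ~ condition + age_c + (1 | participant_id) + (1 | pair_id),
        data = sub, REML = TRUE))
      fe2 <- lme4::fixef(m); se2 <- sqrt(diag(as.matrix(vcov(m))))
      j <- which(names(fe2) == "age_c")
      data.table(trial_type = tt, estimate = unname(fe2[j]),
                 se = unname(se2[j]),
                 ci_lo = unname(fe2[j] - 1.96 * se2[j]),
                 ci_hi = unname(fe2[j] + 1.96 * se2[j]))
    }))
  }
  list(model = model, anova = an, age = age, simple = simple,
       singular = singular, data = s[])
}

#' Median-split paired battery
#'
#' Splits infants into age groups at `split_days` (an infant aged
#' exactly `split_days` joins the older group), then reruns the
#' by-subject one-sample Wilcoxon per group x trial type (pooling
#' conditions) and per group x trial type x condition. Empty cells are
#' skipped with a warning.
#'
#' @param scores pair scores.
#' @param questionnaires questionnaire table supplying ages.
#' @param split_days split point in days.
#' @param alternative test direction, passed to
#'   [wilcoxon_one_sample()].
#' @return a `data.table`, one row per tested cell.
#' @export
median_split_battery <- function(scores, questionnaires, split_days = 230,
                                 alternative = "greater") {
  s <- as.data.table(scores)
  ages <- unique(as.data.table(questionnaires)[, .(participant_id,
                                                   age_days)])
  s <- merge(s, ages, by = "participant_id")
  s[, age_group := ifelse(age_days >= split_days, "older", "younger")]
  cells <- rbind(
    unique(s[, .(age_group, trial_type, condition = "both")]),
    unique(s[, .(age_group, trial_type, condition)]))
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i]
    sub <- if (cell$condition == "both")
      s[age_group == cell$age_group & trial_type == cell$trial_type]
    else s[age_group == cell$age_group & trial_type == cell$trial_type &
             condition == cell$condition]
    agg <- aggregate_scores(sub, by = "subject", groups = "trial_type")
    if (!nrow(agg)) {
      warning("empty cell skipped: ", paste(unlist(cell), collapse = "/"))
      next
    }
    st <- wilcoxon_one_sample(agg$mean_score, mu0 = 0,
                              alternative = alternative)
    out[[i]] <- stat_row(st, age_group = cell$age_group,
                         trial_type = cell$trial_type,
                         condition = cell$condition)
  }
  rbindlist(out)
}

#' Correlation between frequency imbalance and pair effect size
#'
#' Pearson correlation between each word pair's mean matching-trial
#' difference score (by item) and the absolute difference in the pair's
#' referent-word child-directed-speech frequencies, with a one-sided p
#' (positive association) and a JZS correlation Bayes factor.
#'
#' @param pair_effects `data.table` with `pair_id` and `mean_score`
#'   (e.g. [aggregate_scores()] by item on matching trials).
#' @param stimulus a stimulus table.
#' @param alternative direction for the correlation test.
#' @return list: `r`, `p`, `t`, `df`, `bf10`, `n`, and the merged table.
#' @export
freq_imbalance_correlation <- function(pair_effects, stimulus,
                                       alternative = "greater") {
  pe <- as.data.table(pair_effects)
  s <- as.data.table(stimulus)[role == "referent"]
  imb <- s[, .(freq_imbalance = abs(diff(cds_frequency))), by = pair_id]
  m <- merge(pe[, .(pair_id, mean_score)], imb, by = "pair_id")
  m <- m[complete.cases(m)]
  if (nrow(m) < 3) stop("need at least three pairs with both quantities")
  ct <- stats::cor.test(m$freq_imbalance, m$mean_score,
                        method = "pearson", alternative = alternative)
  list(r = unname(ct$estimate), p = ct$p.value,
       t = unname(ct$statistic), df = unname(ct$parameter),
       bf10 = jzs_bf_correlation(unname(ct$estimate), nrow(m)),
       n = nrow(m), data = m[])
}

#' Baseline-corrected looking by reported comprehension
#'
#' Mixed-effects model on log-transformed baseline-corrected looking
#' (matching trials): fixed factors condition, CDI comprehension
#' (understood yes/no for the named word) and their interaction, random
#' intercepts for infant and word; plus per-cell one-sample Wilcoxon
#' tests (two-sided). If every word shares one comprehension status the
#' factor is dropped with a warning.
#'
#' @param bc_scores output of [baseline_corrected_scores()], matching
#'   trials.
#' @param questionnaires questionnaire table supplying
#'   `cdi_understands`.
#' @return list: `model`, `anova`, `cells` (per-cell Wilcoxon rows),
#'   `comprehension_dropped`.
#' @export
comprehension_split_analysis <- function(bc_scores, questionnaires) {
  b <- as.data.table(bc_scores)[trial_type == "matching"]
  q <- as.data.table(questionnaires)[, .(participant_id, word,
                                         cdi_understands)]
  b <- merge(b, q, by.x = c("participant_id", "target_word"),
             by.y = c("participant_id", "word"))
  if (!nrow(b)) stop("no matching trials with CDI data")
  b[, resp := log(value + 2)]
  # a boundary score of exactly -2 (all-target pre, all-distractor post)
  # has no finite log; such trials are dropped from the model
  b <- b[is.finite(resp)]
  if (!nrow(b)) stop("no finite responses after the log transform")
  b[, comprehension := ifelse(cdi_understands, "yes", "no")]
  dropped <- length(unique(b$comprehension)) < 2
  if (dropped) {
    warning("all CDI flags identical; comprehension factor dropped")
    model <- suppressMessages(lmerTest::lmer(
      resp ~ condition + (1 | participant_id) + (1 | target_word),
      data = b, REML = TRUE))
  } else {
    model <- suppressMessages(lmerTest::lmer(
      resp ~ condition * comprehension +
        (1 | participant_id) + (1 | target_word),
      data = b, REML = TRUE))
  }
  an <- as.data.frame(stats::anova(model, type = 3))
  cells <- b[, .(condition, comprehension, value)]
  cell_tests <- cells[, {
    if (.N >= 2 && sd(value) > 0) {
      st <- wilcoxon_one_sample(value, mu0 = 0,
                                alternative = "two.sided")
      as.list(stat_row(st))
    } else NULL
  }, by = .(condition, comprehension)]
  list(model = model, anova = an, cells = cell_tests,
       comprehension_dropped = dropped, data = b[])
}
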