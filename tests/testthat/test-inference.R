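test_that("signed-rank V and exact p match enumeration on anchor cases", {
  # {1, 2, 3} against 0, two-sided: V = 6, p = 2/8 = 0.25
  st <- wilcoxon_one_sample(c(1, 2, 3), 0, alternative = "two.sided")
  expect_equal(st$statistic, 6)
  expect_equal(st$p, 0.25)
  en <- enum_wilcoxon(c(1, 2, 3), 0, "two.sided")
  expect_equal(st$statistic, en$V)
  expect_equal(st$p, en$p)
  # 50 positive values: V is the maximal rank sum 50*51/2 = 1275
  set.seed(1)
  st50 <- wilcoxon_one_sample(runif(50, 0.1, 1), 0)
  expect_equal(st50$statistic, 1275)
  # values symmetric about the null sit at the null mean n(n+1)/4
  expect_equal(wilcoxon_one_sample(c(-2, -1, 1, 2), 0,
                                   "two.sided")$statistic, 5)
})

test_that("exact p equals full 2^n sign enumeration on random fixtures", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n, sd = 2), 3)
    while (anyDuplicated(abs(x)) || any(x == 0))
      x <- round(rnorm(n, sd = 2), 3)
    alt <- sample(c("two.sided", "greater", "less"), 1)
    st <- wilcoxon_one_sample(x, 0, alternative = alt)
    en <- enum_wilcoxon(x, 0, alt)
    expect_equal(st$statistic, en$V)
    expect_equal(st$p, en$p, tolerance = 1e-12)
  }
})

test_that("degenerate input is flagged instead of failing", {
  st <- wilcoxon_one_sample(rep(0.5, 4), 0.5, "two.sided")
  expect_true(st$degenerate)
  expect_equal(st$p, 1)
})

test_that("the JZS Bayes factor agrees with direct quadrature", {
  # small fixture, both integration routes to 4 significant digits
  x <- c(0.2, 0.5, -0.1, 0.4, 0.3)
  bf <- jzs_bf_one_sample(x)
  tstat <- mean(x) / (sd(x) / sqrt(5))
  oracle <- quad_jzs_bf(tstat, 5)
  expect_equal(bf, oracle, tolerance = 1e-4)
  for (tv in c(-2, 0.5, 3.2)) {
    expect_equal(jzs_bf_one_sample(t = tv, n = 20),
                 quad_jzs_bf(tv, 20), tolerance = 1e-4)
  }
  # no effect with plenty of data favours the null
  expect_lt(jzs_bf_one_sample(t = 0, n = 50), 1)
  # monotone increasing in |t| at fixed n
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, function(tv) jzs_bf_one_sample(t = tv, n = 30),
                numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_one_sample(rep(1, 5)), "variance")
})

test_that("noncentral-t power matches the design computation", {
  # the planned design: d = 0.41, n = 50, two-sided alpha = .05
  expect_gte(power_one_sample_t(0.41, 50), 0.80)
  # no effect: power equals alpha
  expect_equal(power_one_sample_t(0, 50), 0.05, tolerance = 1e-10)
  # increasing in d and in n
  ds <- seq(0.1, 0.8, by = 0.1)
  expect_true(all(diff(vapply(ds, power_one_sample_t, numeric(1),
                              n = 40)) > 0))
  ns <- c(10, 20, 40, 80, 160)
  expect_true(all(diff(vapply(ns, function(n)
    power_one_sample_t(0.3, n), numeric(1))) > 0))
  # large-n z limit
  n <- 5000; d <- 0.05
  z <- qnorm(0.975)
  closed <- pnorm(d * sqrt(n) - z) + pnorm(-d * sqrt(n) - z)
  expect_equal(power_one_sample_t(d, n), closed, tolerance = 1e-3)
  expect_error(power_one_sample_t(0.4, 1), "at least 2")
})

test_that("the stimulus design keeps a 7-fold frequency imbalance", {
  stim <- read_stimulus_table()
  ratio <- min_frequency_ratio(stim)
  expect_equal(ratio, 107 / 15)
  expect_gte(ratio, 7)
  # context referent pairs are deliberately more balanced
  ctx <- min_frequency_ratio(stim, condition = "context")
  expect_lt(ctx, 7)
  # NA frequencies in the subset are an error, not silently dropped
  expect_error(min_frequency_ratio(stim, condition = "context",
                                   role = "related"), "missing")
})

test_that("frequency-imbalance correlation matches the covariance formula", {
  stim <- read_stimulus_table()
  imb <- stim[role == "referent",
              .(imb = abs(diff(cds_frequency))), by = pair_id]
  # effects exactly proportional to the imbalance: r = 1
  pe <- data.table::data.table(pair_id = imb$pair_id,
                               mean_score = imb$imb * 0.001)
  r1 <- freq_imbalance_correlation(pe, stim)
  expect_equal(r1$r, 1, tolerance = 1e-12)
  # hand-computed covariance formula on an 8-pair fixture
  set.seed(8)
  pe2 <- data.table::data.table(pair_id = imb$pair_id,
                                mean_score = rnorm(8, 0, 0.1))
  r2 <- freq_imbalance_correlation(pe2, stim, alternative = "two.sided")
  x <- imb$imb; y <- pe2$mean_score
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r2$r, r_hand, tolerance = 1e-12)
  expect_equal(r2$n, 8)
  # permuting pair order changes nothing
  r3 <- freq_imbalance_correlation(pe2[sample(8)], stim,
                                   alternative = "two.sided")
  expect_equal(r3$r, r2$r)
  expect_equal(r3$bf10, r2$bf10)
  expect_error(freq_imbalance_correlation(pe2[1:2], stim), "three")
})

test_that("median split sends the boundary age to the older group", {
  sc <- data.table::data.table(
    participant_id = rep(c("p1", "p2", "p3", "p4"), each = 2),
    condition = "frequency", trial_type = "matching",
    pair_id = rep(c("a", "b"), 4),
    score = c(0.3, 0.4, 0.2, 0.1, -0.1, 0.05, 0.15, 0.2))
  q <- data.table::data.table(
    participant_id = c("p1", "p2", "p3", "p4"),
    age_days = c(229, 230, 200, 260), list_id = 1L,
    word = "eple", familiarity = 5, cdi_understands = FALSE)
  ms <- median_split_battery(sc, q)
  older <- ms[condition == "both" & age_group == "older"]
  expect_equal(older$n, 2)   # ages 230 (boundary) and 260
  younger <- ms[condition == "both" & age_group == "younger"]
  expect_equal(younger$n + older$n, 4)
  expect_true(all(c("younger", "older") %in% ms$age_group))
})

test_that("the age model recovers an injected positive age slope", {
  # construct pair scores with a known linear age trend on matching
  # trials only; the fitted interaction model's matching-slope CI should
  # cover the truth on the response scale
  set.seed(42)
  n <- 60
  ages <- sample(184:274, n, replace = TRUE)
  slope <- 0.004
  grid <- data.table::CJ(participant_id = sprintf("p%02d", 1:n),
                         pair_id = c("a", "b", "c", "d"),
                         trial_type = c("matching", "related"))
  grid[, condition := ifelse(pair_id %in% c("a", "b"), "context",
                             "frequency")]
  grid[, age_days := ages[as.integer(substr(participant_id, 2, 3))]]
  grid[, score := ifelse(trial_type == "matching",
                         slope * (age_days - 229), 0) +
         rnorm(.N, 0, 0.25)]
  grid[, score := pmin(pmax(score, -1), 1)]
  q <- unique(grid[, .(participant_id, age_days)])
  q[, c("list_id", "word", "familiarity", "cdi_understands") :=
      .(1L, "eple", 5, FALSE)]
  fit <- fit_age_model(grid[, .(participant_id, condition, trial_type,
                                pair_id, score)],
                       q, trial_age_interaction = TRUE)
  msl <- fit$simple[trial_type == "matching"]
  rsl <- fit$simple[trial_type == "related"]
  # response slope is roughly score slope / 2 (log(2 + s) around s = 0)
  expected <- slope / 2
  expect_true(msl$ci_lo < expected && expected < msl$ci_hi)
  expect_gt(msl$estimate, rsl$estimate)
  # Satterthwaite table reports the age main effect
  expect_true("age_c" %in% rownames(fit$anova))
})

test_that("the comprehension split handles degenerate CDI flags", {
  fx <- get_fixture()
  bc <- baseline_corrected_scores(fx$labeled, fx$report)
  q <- data.table::copy(fx$cohort$questionnaires)
  q[, cdi_understands := FALSE]
  expect_warning(res <- comprehension_split_analysis(bc, q),
                 "dropped")
  expect_true(res$comprehension_dropped)
  # mixed flags fit the full interaction model
  res2 <- comprehension_split_analysis(bc, fx$cohort$questionnaires)
  if (!res2$comprehension_dropped)
    expect_true(any(grepl("comprehension", rownames(res2$anova))))
})
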