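#' End-to-end IPL analysis run
#'
#' Orchestrates the full chain on one dataset: AOI labelling, trial and
#' participant screening, the control quality check, pair difference
#' scores with by-subject/by-item Wilcoxon batteries, cluster-based
#' permutation tests per condition, the mixed-effects age model, the
#' median-split battery, the frequency-imbalance correlation and the
#' CDI comprehension split. Deterministic given `seed`. The input is
#' either a simulated cohort or the three data files; the truth sidecar
#' of a synthetic cohort is never consumed.
#'
#' @param cohort an `ipl_cohort`, or a list with paths `gaze`, `trials`,
#'   `questionnaires` to read from disk.
#' @param stimulus stimulus table.
#' @param layout an [aoi_layout()].
#' @param exclusion an [exclusion_config()].
#' @param cluster a [cluster_config()].
#' @param alternative direction for the vs-chance Wilcoxon battery.
#' @param seed integer; seeds the cluster permutations.
#' @param out_dir optional directory; when given, scores, series,
#'   cluster summaries, the battery and the screening report are
#'   written as CSV plus a `config.txt` archive carrying a hash of the
#'   resolved configuration.
#' @param run_cluster,run_models toggles for the expensive stages.
#' @return a list of stage results (class `ipl_run`).
#' @export
run_pipeline <- function(cohort, stimulus = read_stimulus_table(),
                         layout = aoi_layout(),
                         exclusion = exclusion_config(),
                         cluster = cluster_config(),
                         alternative = "greater",
                         seed = 1L, out_dir = NULL,
                         run_cluster = TRUE, run_models = TRUE) {
  if (!inherits(cohort, "ipl_cohort") && is.list(cohort) &&
      !is.null(cohort$gaze) && is.character(cohort$gaze)) {
    cohort <- list(gaze = read_gaze_table(cohort$gaze),
                   trials = read_trial_sheet(cohort$trials),
                   questionnaires = read_questionnaires(
                     cohort$questionnaires))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cluster$seed <- as.integer(seed)

  labeled <- stage("label", label_gaze(cohort$gaze, cohort$trials, layout))
  screening <- stage("screen", {
    r <- screen_trials(cohort$trials, labeled, cohort$questionnaires,
                       exclusion)
    screen_participants(r, labeled, exclusion)
  })
  control <- stage("control_quality",
                   control_quality(labeled, null = 0,
                                   alternative = "greater"))
  scores <- stage("score", pair_difference_scores(labeled, screening))

  battery <- stage("battery", {
    rows <- list()
    for (tt in unique(scores$trial_type)) {
      for (cond in c("both", unique(scores$condition))) {
        sub <- if (cond == "both") scores[trial_type == tt]
               else scores[trial_type == tt & condition == cond]
        bysub <- aggregate_scores(sub, by = "subject",
                                  groups = "trial_type")
        if (nrow(bysub) >= 2 && sd(bysub$mean_score) > 0)
          rows[[length(rows) + 1L]] <- stat_row(
            wilcoxon_one_sample(bysub$mean_score, 0, alternative),
            grouping = "subject", trial_type = tt, condition = cond)
        byitem <- aggregate_scores(sub, by = "item",
                                   groups = "trial_type")
        if (nrow(byitem) >= 2 && sd(byitem$mean_score) > 0)
          rows[[length(rows) + 1L]] <- stat_row(
            wilcoxon_one_sample(byitem$mean_score, 0, alternative),
            grouping = "item", trial_type = tt, condition = cond)
      }
    }
    rbindlist(rows)
  })

  series <- stage("series", {
    binned <- binned_target_proportion(labeled, screening,
                                       bin_ms = 50)
    participant_series(binned)
  })
  clusters <- NULL
  if (run_cluster) {
    clusters <- stage("cluster", {
      out <- list()
      for (cond in c("context", "frequency")) {
        sub <- series[condition == cond]
        for (cmp in c("matching_vs_chance", "related_vs_chance",
                      "matching_vs_related")) {
          out[[paste(cond, cmp, sep = ".")]] <-
            tryCatch(cluster_test(sub, cmp, cluster),
                     error = function(e) NULL)
        }
      }
      out
    })
  }

  age_model <- median_split <- freq_cor <- comp_split <- NULL
  if (run_models) {
    age_model <- stage("age_model", tryCatch(
      fit_age_model(scores, cohort$questionnaires,
                    trial_age_interaction = TRUE),
      error = function(e) NULL))
    median_split <- stage("median_split", tryCatch(
      median_split_battery(scores, cohort$questionnaires,
                           alternative = alternative),
      error = function(e) NULL))
    freq_cor <- stage("freq_correlation", tryCatch({
      # all eight pairs, both conditions
      byitem <- aggregate_scores(scores[trial_type == "matching"],
                                 by = "item", groups = "trial_type")
      freq_imbalance_correlation(byitem, stimulus)
    }, error = function(e) NULL))
    comp_split <- stage("comprehension_split", tryCatch({
      bc <- baseline_corrected_scores(labeled, screening)
      comprehension_split_analysis(bc, cohort$questionnaires)
    }, error = function(e) NULL))
  }

  run <- structure(list(
    screening = screening, control = control, scores = scores,
    battery = battery, series = series, clusters = clusters,
    age_model = age_model, median_split = median_split,
    freq_cor = freq_cor, comp_split = comp_split,
    seed = seed), class = "ipl_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cfg <- list(exclusion = unclass(exclusion),
                cluster = unclass(cluster), alternative = alternative,
                seed = seed)
    cfg_text <- paste(deparse(cfg), collapse = "\n")
    hash <- config_hash(cfg_text)
    writeLines(c(paste0("# config hash: ", hash), cfg_text),
               file.path(out_dir, "config.txt"))
    stamp <- function(dt) {
      d <- copy(as.data.table(dt)); d[, config_hash := hash]; d
    }
    fwrite(stamp(screening$trials),
           file.path(out_dir, "screening_trials.csv"))
    fwrite(stamp(screening$participants),
           file.path(out_dir, "screening_participants.csv"))
    fwrite(stamp(scores), file.path(out_dir, "pair_scores.csv"))
    fwrite(stamp(battery), file.path(out_dir, "battery.csv"))
    fwrite(stamp(series), file.path(out_dir, "binned_series.csv"))
    if (!is.null(clusters)) {
      cl <- rbindlist(lapply(names(clusters), function(nm) {
        x <- clusters[[nm]]
        if (is.null(x) || !nrow(x$clusters)) return(NULL)
        cbind(analysis = nm, x$clusters)
      }), fill = TRUE)
      if (is.null(cl) || !nrow(cl))
        cl <- data.table(analysis = character(), mass = numeric(),
                         p = numeric())
      fwrite(stamp(cl), file.path(out_dir, "clusters.csv"))
    }
  }
  run
}

# small stable polynomial hash over the serialized config
config_hash <- function(text) {
  bytes <- utf8ToInt(text)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.ipl_run <- function(x, ...) {
  cat("IPL pipeline run (seed ", x$seed, ")\n", sep = "")
  print(x$screening)
  cat(sprintf("Control: mean target fixation %.2f s (%.0f%% of trial)\n",
              x$control$mean_fixation_s,
              100 * x$control$mean_prop_of_trial))
  cat("Battery (by-subject/by-item Wilcoxon):\n")
  print(x$battery[, .(grouping, trial_type, condition, n,
                      mean = round(mean, 3), V, p = signif(p, 3),
                      bf10 = signif(bf10, 3))])
  invisible(x)
}

#' Binned time-course plot
#'
#' Mean target-looking proportion per 50 ms bin with standard-error
#' ribbons, by trial type — the standard looking-while-listening time
#' course figure. Requires ggplot2.
#'
#' @param series participant series ([participant_series()]).
#' @return a ggplot object.
#' @export
plot_timecourse <- function(series) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  s <- as.data.table(series)
  agg <- s[!is.na(prop),
           .(mean_prop = mean(prop), se = sd(prop) / sqrt(.N)),
           by = .(condition, trial_type, bin_start_ms)]
  ggplot2::ggplot(agg, ggplot2::aes(x = bin_start_ms, y = mean_prop,
                                    colour = trial_type,
                                    fill = trial_type)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = c(0, 367), linetype = 3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean_prop - se,
                                      ymax = mean_prop + se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = "time from word onset (ms)",
                  y = "target looking proportion") +
    ggplot2::theme_minimal()
}
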