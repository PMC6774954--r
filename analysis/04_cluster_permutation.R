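#!/usr/bin/env Rscript
# Cluster-based permutation analyses on the binned (50 ms) target-looking
# time course: matching vs chance, related vs chance and matching vs
# related, per condition, with 1000 participant-level sign-flip
# permutations of the maximum cluster mass.

suppressMessages({library(iplgaze); library(data.table)})

gaze <- read_gaze_table("results/cohort/gaze.tsv")
trials <- read_trial_sheet("results/cohort/trial_sheet.csv")
quest <- read_questionnaires("results/cohort/questionnaires.csv")
labeled <- label_gaze(gaze, trials)
report <- screen_participants(
  screen_trials(trials, labeled, quest), labeled)

series <- participant_series(binned_target_proportion(labeled, report))
fwrite(series, "results/binned_series.csv")

rows <- list()
for (cond in c("context", "frequency")) {
  for (cmp in c("matching_vs_chance", "related_vs_chance",
                "matching_vs_related")) {
    res <- tryCatch(
      cluster_test(series[condition == cond], cmp,
                   cluster_config(n_permutations = 1000, seed = 1)),
      error = function(e) NULL)
    if (is.null(res)) next
    cat("\n", cond, "-- ", sep = "")
    print(res)
    if (nrow(res$clusters))
      rows[[paste(cond, cmp)]] <- cbind(condition = cond,
                                        comparison = cmp, res$clusters)
  }
}
out <- if (length(rows)) rbindlist(rows) else
  data.table(condition = character(), comparison = character())
fwrite(out, "results/clusters.csv")
cat("\nwrote results/clusters.csv (", nrow(out), "clusters )\n")
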