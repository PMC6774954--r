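#!/usr/bin/env Rscript
# Pair difference-in-looking-proportion scores and the planned paired
# battery: by-subject and by-item one-sample Wilcoxon tests against
# chance per trial type and condition, with effect sizes and JZS Bayes
# factors. Also the design-stage numbers the study reports: power of
# the planned design and the stimulus table's frequency-ratio
# floor.

suppressMessages({library(iplgaze); library(data.table)})

gaze <- read_gaze_table("results/cohort/gaze.tsv")
trials <- read_trial_sheet("results/cohort/trial_sheet.csv")
quest <- read_questionnaires("results/cohort/questionnaires.csv")
labeled <- label_gaze(gaze, trials)
report <- screen_participants(
  screen_trials(trials, labeled, quest), labeled)

cat(sprintf("design power (d = 0.41, n = 50, two-sided): %.3f\n",
            power_one_sample_t(0.41, 50)))
cat(sprintf("min within-pair CDS frequency ratio: %.2f\n",
            min_frequency_ratio(read_stimulus_table())))

run <- run_pipeline(
  list(gaze = "results/cohort/gaze.tsv",
       trials = "results/cohort/trial_sheet.csv",
       questionnaires = "results/cohort/questionnaires.csv"),
  seed = 1, run_cluster = FALSE, run_models = FALSE)

cat("\npaired battery:\n")
print(run$battery[, .(grouping, trial_type, condition, n,
                      mean = round(mean, 3), V, p = signif(p, 3),
                      d = round(d, 2), bf10 = signif(bf10, 3))])

scores <- run$scores
fwrite(scores, "results/pair_scores.csv")
fwrite(run$battery, "results/battery.csv")
cat("\nwrote results/pair_scores.csv (", nrow(scores), "pair scores )\n")
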