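#!/usr/bin/env Rscript
# Trial- and participant-level exclusion screening plus the control-trial
# engagement check, reading the cohort files written by 01_simulate_cohort.R.
# Writes the per-trial screening report and the exclusion audit.

suppressMessages({library(iplgaze); library(data.table)})

gaze <- read_gaze_table("results/cohort/gaze.tsv")
trials <- read_trial_sheet("results/cohort/trial_sheet.csv")
quest <- read_questionnaires("results/cohort/questionnaires.csv")

labeled <- label_gaze(gaze, trials)
report <- screen_trials(trials, labeled, quest)
report <- screen_participants(report, labeled)
print(report)

cq <- control_quality(labeled)
cat(sprintf(
  "control trials: mean target fixation %.2f s (%.0f%% of the trial);\n",
  cq$mean_fixation_s, 100 * cq$mean_prop_of_trial))
cat("  post-naming target proportion ")
print(cq$test)

dir.create("results", showWarnings = FALSE)
fwrite(report$trials, "results/screening_trials.csv")
fwrite(report$participants, "results/screening_participants.csv")
fwrite(report$reason_counts, "results/screening_reasons.csv")
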