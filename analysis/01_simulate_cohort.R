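#!/usr/bin/env Rscript
# Generate the synthetic study cohort used throughout the analysis:
# 50 infants aged 184-274 days, two counterbalancing lists, 32
# experimental + 4 control trials each, with the default age-graded
# matching-trial effect and realistic missingness. Writes the three
# analysis inputs plus the truth sidecar under results/cohort/.

suppressMessages(library(iplgaze))

seed <- 1L
cfg <- cohort_config(n_infants = 50, seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, "results/cohort")

cat("cohort written to results/cohort (seed ", seed, ")\n", sep = "")
cat("  infants:", cfg$n_infants, "\n")
cat("  gaze samples:", nrow(cohort$gaze), "at", cfg$sampling_hz, "Hz\n")
cat("  trials:", nrow(cohort$trials), "(",
    nrow(cohort$trials[cohort$trials$trial_type != "control"]),
    "experimental )\n")
ages <- unique(cohort$questionnaires[, c("participant_id", "age_days")])
cat("  ages:", min(ages$age_days), "-", max(ages$age_days), "days\n")
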