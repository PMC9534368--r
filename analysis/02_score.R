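#!/usr/bin/env Rscript
# Score the simulated cohort: load the raw session CSVs, retain complete
# sessions (both tonic test stimuli, the cold-pressor series and a
# determinable T50), and compute every per-participant indicator: heat
# pain threshold, T50, TS means, signed TSP over the last 60 s of each
# test stimulus, conditioning-stimulus mean pain with withdrawal
# imputation, CPM efficiency and the category labels.

suppressPackageStartupMessages(library(cpmcluster))

in_dir <- "results/cohort"
out_dir <- "results"

cohort <- read_cohort(file.path(in_dir, "cohort.csv"),
                      file.path(in_dir, "traces.csv"))
scored <- score_cohort(cohort)
write_scores(scored$scores, file.path(out_dir, "scores.csv"))
utils::write.csv(scored$exclusions, file.path(out_dir, "exclusions.csv"),
                 row.names = FALSE)

pat <- scored$scores[scored$scores$group == "PATIENT", ]
ctl <- scored$scores[scored$scores$group == "CONTROL", ]
cat(sprintf("Scored %d of %d sessions (%d excluded: %s)\n",
            nrow(scored$scores), length(cohort$sessions),
            nrow(scored$exclusions),
            paste(substr(scored$exclusions$reason, 1, 12), collapse = "; ") |>
              substr(1, 60)))
cat(sprintf("Patients: n=%d, CPM %% mean %.2f (SD %.2f); controls: n=%d, mean %.2f\n",
            nrow(pat), mean(pat$cpm_pct), stats::sd(pat$cpm_pct),
            nrow(ctl), mean(ctl$cpm_pct)))
cat(sprintf("Patient CPM categories: %s\n",
            paste(sprintf("%s=%d", names(table(pat$cpm_class)),
                          as.integer(table(pat$cpm_class))), collapse = ", ")))
cat(sprintf("Cold-pressor withdrawals: %d patients, %d controls\n",
            sum(pat$withdrawal), sum(ctl$withdrawal)))
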