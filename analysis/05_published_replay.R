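#!/usr/bin/env Rscript
# Stage 5 — replay the published blind-study results.
#
# Scores the published 15-donor presumptive/actual table and re-derives the
# summary-versus-literature comparisons from the published cohort summaries
# (female 96.4 +/- 5.1 uM over 33 prints; male 55.3 +/- 5.3 uM over 12),
# using the pooled-SEM normal test.

suppressMessages({
  library(optparse)
  library(argmark)
})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--out", type = "character", default = "results/published_replay.json")
)))

tbl <- blind_study_table()
score <- score_blind_study(tbl)
cat(sprintf("blind study replay: %d/%d correct (%d%% accuracy)\n",
            score$matches, score$total, score$accuracy))

ref <- literature_reference()
female <- compare_summary_to_reference(96.4, 5.1, ref$mu_female, ref$sem_female)
male <- compare_summary_to_reference(55.3, 5.3, ref$mu_male, ref$sem_male)
cat("female cohort vs literature: "); print(female)
cat("male cohort vs literature:   "); print(male)

dir.create(dirname(opts$out), recursive = TRUE, showWarnings = FALSE)
jsonlite::write_json(
  list(blind_score = score,
       female_vs_literature = unclass(female),
       male_vs_literature = unclass(male)),
  opts$out, auto_unbox = TRUE, digits = NA)
cat("wrote", opts$out, "\n")
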