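#!/usr/bin/env Rscript
# Step 3: correlational validation of the coherence scores.
#
# Renders the validation layer computed by the pipeline: the score-score
# correlation matrix (the four metrics are expected to be highly
# intercorrelated), the score-outcome matrix against the simulated clinical
# variables, partial correlations of T2 outcomes controlling for T1, mean
# differences by sex and medication, and the nuisance screen (age,
# education, verbal IQ, transcript length). With a 71-participant cohort,
# planted effects of |rho| ~ 0.3 sit near the edge of detectability — the
# same regime as the clinical studies this design emulates.
#
# Reads:  results/run/ (from 02_score_coherence.R)
# Writes: results/validation_summary.txt

suppressMessages(library(semcoh))

scores <- read_stamped_csv("results/run/scores.csv")
clinical <- readr::read_csv("results/study/clinical.csv",
                            show_col_types = FALSE)
rep <- validation_report(scores, clinical)

lines <- c(
  "== Coherence scores x coherence scores ==",
  format_cor_table(rep$score_score), "",
  "== Coherence scores x clinical outcomes (T1) ==",
  format_cor_table(rep$score_outcome), "",
  "== Scores x T2 outcomes, controlling for the T1 outcome ==",
  format_cor_table(rep$partial), "",
  "== Group differences (Welch t) ==",
  utils::capture.output(print(as.data.frame(rep$t_tests), digits = 3)), "",
  "== Nuisance screen ==",
  format_cor_table(rep$control_screen))
writeLines(lines, "results/validation_summary.txt")
cat(lines, sep = "\n")
cat("\nwrote results/validation_summary.txt\n")
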