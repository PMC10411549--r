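#!/usr/bin/env Rscript
# Step 1: simulate the study materials.
#
# Patient interview recordings from coherence studies are not publicly
# deposited, so the whole analysis runs on synthetic materials with known
# ground truth: a topic-structured toy embedding space (two models, to
# mirror the two-embedding comparison design), and a 71-participant cohort
# of topic-drift transcripts whose clinical outcome table is linked to the
# latent coherence trait at stated effect sizes.
#
# Writes: results/study/{transcripts/, clinical.csv, ground_truth.csv,
#         modelA.vec, modelB.txt}

suppressMessages(library(semcoh))

ROOT_SEED <- 1137L
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

space <- topic_space()            # 8 topics x 60 words, dim 50
profile <- drift_profile()        # ~240 raw words per transcript

modelA <- make_embedding_model(space, seed = stream_seed(ROOT_SEED, "modelA"),
                               name = "modelA")
modelB <- make_embedding_model(topic_space(dim = 25, dispersion = 25),
                               seed = stream_seed(ROOT_SEED, "modelB"),
                               name = "modelB")
write_embeddings(modelA, file.path(out, "modelA.vec"),
                 dialect = "word2vec_text")
write_embeddings(modelB, file.path(out, "modelB.txt"), dialect = "glove_text")
gap <- attr(modelA, "cosine_gap")
cat(sprintf("modelA topic structure: within-topic cosine %.3f, between %.3f\n",
            gap$within, gap$between))

cohort <- generate_cohort(
  cohort_spec(n_participants = 71, seed = stream_seed(ROOT_SEED, "cohort")),
  space, profile)
write_cohort(cohort, out)

stats <- do.call(rbind, lapply(cohort$transcripts, function(t)
  transcript_word_stats(annotate_transcript(t))))
cat(sprintf("transcripts: mean %.0f words (range %d-%d), mean %.0f unique\n",
            mean(stats$words), min(stats$words), max(stats$words),
            mean(stats$unique_words)))
rr <- attr(cohort$ground_truth, "realized_rho")
cat("planted latent-outcome correlations (target vs realized):\n")
print(as.data.frame(rr), row.names = FALSE)
cat("wrote study materials to", out, "\n")
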