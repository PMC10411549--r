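test_that("embedding-model generation is deterministic and topic-structured", {
  sp <- topic_space(n_topics = 3, dim = 10, vocab_per_topic = 12,
                    n_stopwords = 8)
  m1 <- make_embedding_model(sp, seed = 21)
  m2 <- make_embedding_model(sp, seed = 21)
  expect_identical(m1$vectors, m2$vectors)
  m3 <- make_embedding_model(sp, seed = 22)
  expect_false(identical(m1$vectors, m3$vectors))
  # written vector files are byte-identical for the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_embeddings(m1, f1); write_embeddings(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  gap <- attr(m1, "cosine_gap")
  expect_gt(gap$within, gap$between)
  # the reported gap matches an independent pairwise-loop computation
  topic_of <- attr(m1, "topic_of")
  content <- which(topic_of > 0)
  within <- c(); between <- c()
  for (i in content) {
    for (j in content) {
      if (j <= i) next
      cs <- oracle_cos(m1$vectors[i, ], m1$vectors[j, ])
      if (topic_of[i] == topic_of[j]) within <- c(within, cs)
      else between <- c(between, cs)
    }
  }
  expect_equal(gap$within, mean(within), tolerance = 1e-9)
  expect_equal(gap$between, mean(between), tolerance = 1e-9)
})

test_that("infeasible topic geometry is rejected", {
  sp <- topic_space(n_topics = 12, dim = 2, vocab_per_topic = 3,
                    max_center_cosine = 0.1)
  expect_error(make_embedding_model(sp, seed = 1), "infeasible")
})

test_that("transcript generation respects the drift profile extremes", {
  sp <- topic_space(n_topics = 6, dim = 10, vocab_per_topic = 10)
  prof <- drift_profile()
  t0 <- generate_transcript(sp, prof, seed = 31, p_switch = 0)
  for (topics in attr(t0, "topics")) {
    expect_equal(length(unique(topics)), 1L)   # no drift: one topic throughout
  }
  t1 <- generate_transcript(sp, prof, seed = 32, p_switch = 1)
  for (topics in attr(t1, "topics")) {
    if (length(topics) > 1) {
      expect_true(all(diff(topics) != 0))      # maximal drift: always jumps
    }
  }
})

test_that("transcript generation is deterministic and pipeline-valid", {
  sp <- topic_space(n_topics = 4, dim = 12, vocab_per_topic = 15)
  a <- generate_transcript(sp, drift_profile(), seed = 33)
  b <- generate_transcript(sp, drift_profile(), seed = 33)
  expect_identical(a, b)
  # generated transcripts ingest, annotate, preprocess and score end-to-end
  f <- withr::local_tempfile(fileext = ".json")
  write_transcript(a, f)
  back <- read_transcript(f)
  expect_identical(back$sections$fear$answer, a$sections$fear$answer)
  m <- make_embedding_model(sp, seed = 34)
  pp <- preprocess_transcript(annotate_transcript(back),
                              lex = space_lexicons(sp))
  sc <- score_participant(pp, list(m))
  expect_equal(sc$sections_contributing, 4L)
  expect_true(sc$local >= -1 && sc$local <= 1)
})

test_that("generated transcripts match the target surface statistics", {
  sp <- topic_space()
  prof <- drift_profile()
  stats <- dplyr::bind_rows(lapply(1:60, function(i) {
    transcript_word_stats(annotate_transcript(
      generate_transcript(sp, prof, seed = 500 + i)))
  }))
  expect_gt(mean(stats$words), 200)
  expect_lt(mean(stats$words), 290)
  expect_gt(mean(stats$unique_words), 110)
  expect_lt(mean(stats$unique_words), 185)
})

test_that("cohort generation links outcomes to latent coherence as specified", {
  spec <- cohort_spec(n_participants = 400, seed = 41)
  sp <- topic_space(n_topics = 4, dim = 10, vocab_per_topic = 10)
  coh <- generate_cohort(spec, sp, drift_profile())
  expect_length(coh$transcripts, 400)
  expect_equal(coh$clinical$participant_id, coh$ground_truth$participant_id)
  rr <- attr(coh$ground_truth, "realized_rho")
  # realized latent-outcome correlations sit near their targets
  neg <- rr[rr$outcome == "panss_negative", ]
  expect_lt(abs(neg$realized_rho - neg$target_rho), 0.1)
  null_links <- rr[rr$target_rho == 0, ]
  expect_true(all(abs(null_links$realized_rho) < 0.12))
  # clinical marginals respect the declared invariants
  days <- coh$clinical$inpatient_days_0_5y_before
  expect_true(all(days >= 0) && all(days == round(days)))
  expect_true(all(coh$clinical$panss_negative >= 1 &
                    coh$clinical$panss_negative <= 60))
  expect_true(all(coh$ground_truth$p_switch >= 0 &
                    coh$ground_truth$p_switch <= 1))
  # T2 columns: autocorrelated with T1, with missing follow-ups
  t1 <- coh$clinical$panss_negative
  t2 <- coh$clinical$panss_negative_t2
  expect_true(anyNA(t2))
  expect_gt(cor(t1, t2, use = "complete.obs"), 0.4)
  # determinism
  coh2 <- generate_cohort(spec, sp, drift_profile())
  expect_identical(coh$clinical, coh2$clinical)
  expect_identical(coh$transcripts[[17]], coh2$transcripts[[17]])
})

test_that("an unachievable T2 correlation structure raises an error", {
  links <- default_outcome_links()[2, ]
  links$rho <- 0.9
  spec <- cohort_spec(n_participants = 20, seed = 42, outcome_links = links,
                      t1_t2_autocorr = -0.95, t2_coherence_rho = 0.9)
  sp <- topic_space(n_topics = 2, dim = 6, vocab_per_topic = 5)
  expect_error(generate_cohort(spec, sp, drift_profile()),
               "not positive definite")
})

test_that("cohort_spec requires a seed and validates link magnitudes", {
  expect_error(cohort_spec(n_participants = 10), "seed")
  bad <- default_outcome_links()
  bad$rho[1] <- 1.2
  expect_error(cohort_spec(n_participants = 10, seed = 1,
                           outcome_links = bad))
})

test_that("seed streams are stable and independent of generator order", {
  expect_identical(stream_seed(7, "transcripts"), stream_seed(7, "transcripts"))
  expect_false(stream_seed(7, "transcripts") == stream_seed(7, "outcomes"))
  expect_false(stream_seed(7, "transcripts") == stream_seed(8, "transcripts"))
  expect_true(stream_seed(.Machine$integer.max, "x") < 2^31)
})
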