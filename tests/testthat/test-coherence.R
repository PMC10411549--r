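test_that("local coherence matches hand computations in both modes", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  ident <- rbind(e1, e1, e1)
  expect_equal(local_coherence(ident, "pairs"), 1.0)
  expect_equal(local_coherence(ident, "verbatim_n"), 2 / 3)
  m <- rbind(e1, e1, e2)
  expect_equal(local_coherence(m, "pairs"), 0.5)       # (1 + 0) / 2
  expect_equal(local_coherence(m, "verbatim_n"), 1 / 3)
  expect_true(is.na(local_coherence(rbind(e1))))       # no adjacent pair
  expect_true(is.na(local_coherence(matrix(numeric(0), 0, 2))))
})

test_that("global coherence matches hand computations in both modes", {
  e1 <- c(1, 0); e2 <- c(0, 1)
  expect_equal(global_coherence(rbind(e1)), 1.0)       # centroid = sentence
  expect_equal(global_coherence(rbind(e1, e2)), sqrt(2) / 2,
               tolerance = 1e-12)
  ident5 <- matrix(rep(c(0.3, 0.4), each = 5), 5)
  expect_equal(global_coherence(ident5), 1.0)
  expect_equal(global_coherence(ident5, "verbatim_n"), 4 / 5)
  # opposed vectors: centroid has zero norm, score undefined
  expect_true(is.na(global_coherence(rbind(e1, -e1))))
  expect_true(is.na(global_coherence(matrix(numeric(0), 0, 2))))
})

test_that("both metrics agree with independent brute-force loops", {
  set.seed(402)
  for (rep in 1:60) {
    m <- random_vector_sequence(sample(2:20, 1), sample(2:10, 1))
    expect_equal(local_coherence(m, "pairs"), oracle_local(m, "pairs"),
                 tolerance = 1e-9)
    expect_equal(local_coherence(m, "verbatim_n"),
                 oracle_local(m, "verbatim_n"), tolerance = 1e-9)
    expect_equal(global_coherence(m, "terms"), oracle_global(m, "terms"),
                 tolerance = 1e-9)
    expect_equal(global_coherence(m, "verbatim_n"),
                 oracle_global(m, "verbatim_n"), tolerance = 1e-9)
  }
})

test_that("global coherence is permutation-invariant, local is not", {
  set.seed(7)
  # structured sequence: two blocks of similar vectors, so order matters
  block <- function(center) {
    t(replicate(6, center + rnorm(4, sd = 0.1)))
  }
  m <- rbind(block(c(5, 0, 0, 0)), block(c(0, 5, 0, 0)))
  changed <- FALSE
  for (rep in 1:10) {
    perm <- sample(nrow(m))
    expect_equal(global_coherence(m[perm, ]), global_coherence(m),
                 tolerance = 1e-12)
    if (abs(local_coherence(m[perm, ]) - local_coherence(m)) > 1e-6) {
      changed <- TRUE
    }
  }
  expect_true(changed)
})

test_that("metrics are invariant to positive rescaling of sentence vectors", {
  set.seed(8)
  m <- random_vector_sequence(8, 5)
  # local: invariant even under independent per-sentence scales
  scales <- runif(8, 0.1, 9)
  expect_equal(local_coherence(m * scales), local_coherence(m),
               tolerance = 1e-12)
  # global: invariant under a common scale; independent scales redirect the
  # centroid, so invariance is not expected there
  expect_equal(global_coherence(m * 4.2), global_coherence(m),
               tolerance = 1e-12)
})

test_that("participant scoring reproduces a full-chain hand computation", {
  m <- toy_model_2d()
  t <- annotate_transcript(toy_transcript())
  pp <- preprocess_transcript(t, lex = toy_lexicons())
  sc <- score_participant(pp, list(m))
  # independent recomputation: look up vectors and run the loop oracles
  expected <- list()
  for (emo in net_emotions()) {
    vecs <- do.call(rbind, lapply(pp[[emo]]$sentences, function(s) {
      rows <- m$vectors[s, , drop = FALSE]
      colMeans(rows)
    }))
    expected[[emo]] <- c(local = oracle_local(vecs),
                         global = oracle_global(vecs))
  }
  exp_local <- mean(vapply(expected, `[[`, numeric(1), "local"),
                    na.rm = TRUE)
  exp_global <- mean(vapply(expected, `[[`, numeric(1), "global"))
  expect_equal(sc$local, exp_local, tolerance = 1e-12)
  expect_equal(sc$global, exp_global, tolerance = 1e-12)
  expect_equal(sc$sections_contributing, 4L)
  secs <- attr(sc, "sections")
  expect_equal(nrow(secs), 4L)
  # single-sentence section: local missing, global defined
  expect_true(is.na(secs$local[secs$emotion == "anger"]))
  expect_equal(secs$global[secs$emotion == "anger"], 1.0)
})

test_that("identical repeated sentences propagate a perfect score", {
  m <- toy_model_2d()
  t <- annotate_transcript(transcript("P", lapply(net_emotions(), function(e)
    emotion_section(e, answer = "sonne licht. sonne licht. sonne licht."))))
  pp <- preprocess_transcript(t, lex = toy_lexicons())
  sc <- score_participant(pp, list(m))
  expect_equal(sc$local, 1.0)
  expect_equal(sc$global, 1.0)
})

test_that("an all-OOV section is excluded from the participant mean", {
  m <- toy_model_2d()
  t <- annotate_transcript(transcript("P", list(
    emotion_section("sadness", answer = "sonne licht. regen wolke."),
    emotion_section("fear", answer = "sonne regen. licht wolke."),
    emotion_section("anger", answer = "zzz qqq. www vvv."),
    emotion_section("happiness", answer = "mitte sonne. mitte licht.")
  )))
  pp <- preprocess_transcript(t, lex = toy_lexicons())
  sc <- score_participant(pp, list(m))
  secs <- attr(sc, "sections")
  anger <- secs[secs$emotion == "anger", ]
  expect_true(is.na(anger$local) && is.na(anger$global))
  expect_equal(anger$skipped, 2L)
  expect_equal(sc$sections_contributing, 3L)
  others <- secs[secs$emotion != "anger", ]
  expect_equal(sc$local, mean(others$local), tolerance = 1e-12)
})

test_that("score_transcripts emits the wide four-metric table per participant", {
  mA <- toy_model_2d("modelA")
  mB <- embedding_model(toy_model_2d()$vectors * 2, name = "modelB")
  ts <- list(toy_transcript("P01"), toy_transcript("P02"))
  wide <- score_transcripts(ts, list(mA, mB), lex = toy_lexicons())
  expect_equal(nrow(wide), 2L)
  expect_true(all(c("modelA_local", "modelA_global",
                    "modelB_local", "modelB_global",
                    "words", "unique_words") %in% names(wide)))
  # modelB is a positive rescaling of modelA: identical scores
  expect_equal(wide$modelA_local, wide$modelB_local, tolerance = 1e-12)
  expect_equal(wide$modelA_global, wide$modelB_global, tolerance = 1e-12)
})
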