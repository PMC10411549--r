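# Synthetic study materials: topic-structured embedding spaces, topic-drift
# transcripts with ground-truth incoherence, and simulated clinical cohorts.
# Everything is a pure function of (specification, seed); per-component seeds
# are derived with stream_seed() so adding one generator never perturbs the
# random numbers of another.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a topic-structured toy embedding space
#'
#' The space emulates the one property of a trained embedding model the
#' coherence metrics rely on: words of the same topic have nearby vectors,
#' words of different topics distant ones. Each topic has a unit center
#' vector; word vectors scatter around their center with spherical Gaussian
#' noise of standard deviation `1/sqrt(dispersion)` per component before
#' renormalization, so larger `dispersion` means tighter topics (a
#' concentration parameter in the von Mises-Fisher spirit). A shared
#' stopword vocabulary (real German stopwords, so the shipped lexicons catch
#' them) and a filler inventory are carried alongside; they appear in
#' transcripts but are removed by preprocessing. This is a geometric
#' stand-in constructed for controlled experiments, not a language model.
#'
#' @param n_topics Number of topics.
#' @param dim Vector dimension (>= 2).
#' @param vocab_per_topic Content words per topic.
#' @param dispersion Concentration of word vectors around their topic
#'   center; noise sd per component is `1/sqrt(dispersion)`.
#' @param max_center_cosine Ceiling on pairwise cosine between topic
#'   centers.
#' @param n_stopwords Size of the shared stopword vocabulary (taken from the
#'   shipped German list).
#' @param fillers Filler inventory (subset of the shipped filler list).
#' @return A `semcoh_topic_space` object.
#' @export
topic_space <- function(n_topics = 8, dim = 50, vocab_per_topic = 60,
                        dispersion = 40, max_center_cosine = 0.5,
                        n_stopwords = 40,
                        fillers = c("ehm", "äh", "ähm", "hm", "mhm")) {
  stopifnot(n_topics >= 1, dim >= 2, vocab_per_topic >= 1, dispersion > 0,
            n_stopwords >= 1)
  all_sw <- read_lexicon(system.file("extdata", "stopwords_de.txt",
                                     package = "semcoh", mustWork = TRUE))
  if (n_stopwords > length(all_sw)) n_stopwords <- length(all_sw)
  topic_vocab <- lapply(seq_len(n_topics), function(k) {
    sprintf("t%02dw%02d", k, seq_len(vocab_per_topic))
  })
  structure(
    list(n_topics = n_topics, dim = dim, vocab_per_topic = vocab_per_topic,
         dispersion = dispersion, max_center_cosine = max_center_cosine,
         topic_vocab = topic_vocab, stopwords = all_sw[seq_len(n_stopwords)],
         fillers = fillers),
    class = "semcoh_topic_space"
  )
}

#' Lexicons matching a topic space
#'
#' @param space A `semcoh_topic_space`.
#' @return A `semcoh_lexicons` covering exactly the space's stopwords and
#'   fillers.
#' @export
space_lexicons <- function(space) {
  lexicons(fillers = space$fillers, stopwords = space$stopwords)
}

random_unit <- function(dim) {
  v <- stats::rnorm(dim)
  v / sqrt(sum(v^2))
}

#' Materialize the embedding model of a topic space
#'
#' Draws topic centers as random unit vectors subject to the pairwise-cosine
#' ceiling (rejection sampling; an unsatisfiable geometry — too many
#' near-orthogonal centers for the dimension — raises an error), then
#' scatters each topic's word vectors around its center and renormalizes.
#' Stopwords get their own unrelated unit vectors; fillers are deliberately
#' out of vocabulary. Deterministic for a fixed seed. The achieved
#' within-topic versus between-topic mean pairwise cosine is computed and
#' attached as attribute `"cosine_gap"`.
#'
#' @param space A `semcoh_topic_space`.
#' @param seed Integer seed.
#' @param name Model name.
#' @return A `semcoh_embedding` with attributes `"cosine_gap"` (list:
#'   `within`, `between`, `gap`) and `"topic_of"` (topic index per vocabulary
#'   word, 0 for stopwords).
#' @export
make_embedding_model <- function(space, seed, name = "toy") {
  stopifnot(inherits(space, "semcoh_topic_space"))
  with_seed(seed, {
    centers <- matrix(NA_real_, space$n_topics, space$dim)
    for (k in seq_len(space$n_topics)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        cand <- random_unit(space$dim)
        if (k == 1L ||
            max(abs(centers[seq_len(k - 1L), , drop = FALSE] %*% cand)) <=
              space$max_center_cosine) {
          centers[k, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("infeasible topic geometry: cannot place ", space$n_topics,
             " centers with pairwise cosine <= ", space$max_center_cosine,
             " in ", space$dim, " dimensions", call. = FALSE)
      }
    }
    sd <- 1 / sqrt(space$dispersion)
    vecs <- list()
    topic_of <- integer(0)
    for (k in seq_len(space$n_topics)) {
      w <- matrix(stats::rnorm(space$vocab_per_topic * space$dim, sd = sd),
                  space$vocab_per_topic, space$dim)
      w <- sweep(w, 2L, centers[k, ], "+")
      w <- w / sqrt(rowSums(w^2))
      rownames(w) <- space$topic_vocab[[k]]
      vecs[[k]] <- w
      topic_of <- c(topic_of, rep(k, space$vocab_per_topic))
    }
    sw <- t(vapply(space$stopwords, function(s) random_unit(space$dim),
                   numeric(space$dim)))
    mat <- rbind(do.call(rbind, vecs), sw)
    topic_of <- c(topic_of, rep(0L, nrow(sw)))
    model <- embedding_model(mat, name = name)
    content <- topic_of > 0L
    cm <- mat[content, , drop = FALSE]
    cm <- cm / sqrt(rowSums(cm^2))
    cosm <- tcrossprod(cm)
    same <- outer(topic_of[content], topic_of[content], "==")
    diag(same) <- NA
    within <- mean(cosm[same & upper.tri(cosm)], na.rm = TRUE)
    between <- mean(cosm[!same & upper.tri(cosm)], na.rm = TRUE)
    attr(model, "cosine_gap") <- list(within = within, between = between,
                                      gap = within - between)
    attr(model, "topic_of") <- topic_of
    model
  })
}

#' Define a topic-drift profile for transcript generation
#'
#' Controls the latent-topic dynamics and surface statistics of generated
#' speech. Each sentence keeps the previous sentence's topic with
#' probability `1 - p_switch` and otherwise jumps to a uniformly random
#' other topic; content words are drawn from the current topic's vocabulary,
#' interleaved with stopwords and fillers at the stated rates. The default
#' sizes target the surface statistics of emotion-interview speech: four
#' sections of 6-14 sentences of 3-9 words give raw transcripts averaging
#' about 240 words with about 145 unique words.
#'
#' @param p_switch Per-sentence probability of jumping to another topic, in
#'   `[0, 1]`.
#' @param sentences_per_section Integer range `c(min, max)`.
#' @param words_per_sentence Integer range `c(min, max)` of word slots per
#'   sentence (before any slot becomes a stopword or filler).
#' @param stopword_rate,filler_rate Per-slot probabilities.
#' @return A `semcoh_drift_profile` object.
#' @export
drift_profile <- function(p_switch = 0.2,
                          sentences_per_section = c(6L, 14L),
                          words_per_sentence = c(3L, 9L),
                          stopword_rate = 0.35, filler_rate = 0.04) {
  stopifnot(p_switch >= 0, p_switch <= 1,
            length(sentences_per_section) == 2L,
            all(sentences_per_section >= 1L),
            length(words_per_sentence) == 2L, all(words_per_sentence >= 1L),
            stopword_rate >= 0, filler_rate >= 0,
            stopword_rate + filler_rate < 1)
  structure(
    list(p_switch = p_switch,
         sentences_per_section = as.integer(sentences_per_section),
         words_per_sentence = as.integer(words_per_sentence),
         stopword_rate = stopword_rate, filler_rate = filler_rate),
    class = "semcoh_drift_profile"
  )
}

net_questions <- function(emotion) {
  de <- c(sadness = "Traurigkeit", fear = "Angst", anger = "Wut",
          happiness = "Freude")[[emotion]]
  c(paste0("Was bedeutet ", de, " für Sie?"),
    paste0("Beschreiben Sie eine Situation, in der Sie ", de,
           " gefühlt haben."),
    paste0("Warum, denken Sie, haben Sie in dieser Situation ", de,
           " gefühlt?"))
}

#' Generate one topic-drift transcript
#'
#' Produces a four-emotion transcript whose sentences follow a latent topic
#' chain with the profile's switch probability. Sentence boundaries are
#' encoded as sentence-final periods (marker-mode annotation applies
#' directly), and the true topic label of every sentence is attached for
#' evaluation. Deterministic for a fixed seed.
#'
#' @param space A `semcoh_topic_space`.
#' @param profile A `semcoh_drift_profile`.
#' @param seed Integer seed.
#' @param participant_id Identifier for the generated transcript.
#' @param p_switch Optional per-participant override of the profile's switch
#'   probability (used by cohort generation).
#' @return A `semcoh_transcript` with attributes `"topics"` (list of integer
#'   topic vectors per section) and `"p_switch"`.
#' @export
generate_transcript <- function(space, profile, seed,
                                participant_id = "SYN01", p_switch = NULL) {
  stopifnot(inherits(space, "semcoh_topic_space"),
            inherits(profile, "semcoh_drift_profile"))
  ps <- p_switch %||% profile$p_switch
  stopifnot(ps >= 0, ps <= 1)
  with_seed(seed, {
    sections <- list()
    truth <- list()
    for (emo in NET_EMOTIONS) {
      n_sent <- sample(seq(profile$sentences_per_section[1],
                           profile$sentences_per_section[2]), 1L)
      topic <- sample.int(space$n_topics, 1L)
      topics <- integer(n_sent)
      sent_texts <- character(n_sent)
      for (i in seq_len(n_sent)) {
        if (i > 1L && space$n_topics > 1L && stats::runif(1) < ps) {
          topic <- sample(setdiff(seq_len(space$n_topics), topic), 1L)
        }
        topics[i] <- topic
        n_words <- sample(seq(profile$words_per_sentence[1],
                              profile$words_per_sentence[2]), 1L)
        u <- stats::runif(n_words)
        words <- character(n_words)
        for (j in seq_len(n_words)) {
          words[j] <- if (u[j] < profile$filler_rate) {
            sample(space$fillers, 1L)
          } else if (u[j] < profile$filler_rate + profile$stopword_rate) {
            sample(space$stopwords, 1L)
          } else {
            sample(space$topic_vocab[[topic]], 1L)
          }
        }
        sent_texts[i] <- paste0(paste(words, collapse = " "), ".")
      }
      sections[[emo]] <- emotion_section(
        emo, questions = net_questions(emo),
        answer = paste(sent_texts, collapse = " "))
      truth[[emo]] <- topics
    }
    t <- transcript(participant_id, unname(sections), language = "de")
    attr(t, "topics") <- truth
    attr(t, "p_switch") <- ps
    t
  })
}

#' Default outcome links for a simulated clinical cohort
#'
#' One row per clinical outcome: the target Pearson correlation `rho`
#' between the participant's latent coherence and the outcome, the scale
#' (`mean`, `sd`) on which the outcome is emitted, plausibility clamps, an
#' integer flag, and whether a follow-up (T2) copy is generated. The default
#' magnitudes and scales emulate a chronic non-affective-psychosis cohort in
#' which lower speech coherence accompanies more severe negative and
#' disorganized symptoms (|rho| around 0.1-0.35) and day-count outcomes are
#' strongly floor-skewed.
#'
#' @return A tibble of outcome-link definitions.
#' @export
default_outcome_links <- function() {
  tibble::tribble(
    ~outcome,                     ~rho,  ~mean,  ~sd,   ~min, ~max, ~integer, ~t2,
    "panss_positive",            -0.19,  13.34,  6.25,  1,    60,   FALSE,  TRUE,
    "panss_negative",            -0.30,  15.66,  6.86,  1,    60,   FALSE,  TRUE,
    "panss_disorganized",        -0.33,  16.87,  5.91,  1,    60,   FALSE,  TRUE,
    "panss_excitement",          -0.30,  12.62,  3.97,  1,    60,   FALSE,  TRUE,
    "panss_emotional_distress",  -0.14,  17.32,  5.85,  1,    60,   FALSE,  TRUE,
    "mini_icf_sum",              -0.24,  16.30,  9.34,  0,    52,   FALSE,  TRUE,
    "onset_age",                  0.00,  25.36,  7.63,  12,   60,   FALSE, FALSE,
    "illness_duration",           0.00,  13.47,  9.05,  0.5,  45,   FALSE, FALSE,
    "inpatient_days_2_5y_before",-0.12,  39.84, 68.43,  0,    912,  TRUE,  FALSE,
    "inpatient_days_0_5y_before",-0.25,  10.07, 34.39,  0,    182,  TRUE,  FALSE,
    "inpatient_days_0_5y_after", -0.05,   5.74, 16.16,  0,    182,  TRUE,  FALSE
  )
}

#' Specify a simulated clinical cohort
#'
#' Each participant's incoherence is a latent trait: the per-sentence topic
#' switch probability `p_switch`, drawn from a Beta distribution. The
#' standardized negative of that trait is the latent coherence; every
#' clinical outcome is generated as a linear-Gaussian link to it at its
#' stated target correlation. Follow-up (T2) outcomes additionally carry a
#' stated T1-T2 autocorrelation.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed (mandatory; cohorts are only meaningful as
#'   reproducible objects).
#' @param p_switch_beta `c(shape1, shape2)` of the Beta distribution of
#'   `p_switch`. The default `c(1.5, 6)` has mean 0.2 and SD about 0.14:
#'   wide enough between-participant heterogeneity that a ~40-sentence
#'   transcript measures the trait with high reliability.
#' @param outcome_links Tibble per [default_outcome_links()].
#' @param t1_t2_autocorr Target correlation between an outcome at T1 and its
#'   T2 copy.
#' @param t2_coherence_rho Target correlation between latent coherence and
#'   T2 outcomes (default 0: follow-up outcomes carry no direct coherence
#'   signal beyond their T1 autocorrelation).
#' @param t2_completion Fraction of participants with T2 data (the rest get
#'   missing T2 cells).
#' @return A `semcoh_cohort_spec` object.
#' @export
cohort_spec <- function(n_participants = 71, seed,
                        p_switch_beta = c(1.5, 6),
                        outcome_links = default_outcome_links(),
                        t1_t2_autocorr = 0.6,
                        t2_coherence_rho = 0,
                        t2_completion = 54 / 71) {
  if (missing(seed)) stop("cohort_spec() requires an explicit seed",
                          call. = FALSE)
  stopifnot(n_participants >= 1, length(p_switch_beta) == 2L,
            all(p_switch_beta > 0),
            all(abs(outcome_links$rho) < 1),
            abs(t1_t2_autocorr) < 1, abs(t2_coherence_rho) < 1,
            t2_completion >= 0, t2_completion <= 1)
  structure(
    list(n_participants = as.integer(n_participants), seed = as.integer(seed),
         p_switch_beta = p_switch_beta, outcome_links = outcome_links,
         t1_t2_autocorr = t1_t2_autocorr, t2_coherence_rho = t2_coherence_rho,
         t2_completion = t2_completion),
    class = "semcoh_cohort_spec"
  )
}

#' Generate a simulated cohort: transcripts, clinical table, ground truth
#'
#' Draws each participant's latent switch probability from the spec's Beta
#' distribution, generates their topic-drift transcript with it, and emits a
#' clinical outcome table whose columns are linked to the standardized
#' latent coherence at the spec's target correlations (plus covariates:
#' age, sex, education, verbal IQ, medication). T2 outcome columns satisfy
#' both their latent-coherence target and the stated T1-T2 autocorrelation;
#' a target pair that no linear-Gaussian structure can realize (the implied
#' correlation matrix is not positive definite) raises an error. Day-count
#' outcomes are clamped at zero and rounded, which slightly attenuates their
#' realized correlations — the realized values are recorded in the
#' ground-truth table's `"realized_rho"` attribute. Deterministic per seed.
#'
#' @param spec A `semcoh_cohort_spec`.
#' @param space A `semcoh_topic_space`.
#' @param profile A `semcoh_drift_profile` (its `p_switch` is overridden per
#'   participant).
#' @return A list: `transcripts` (list of `semcoh_transcript`), `clinical`
#'   (tibble), `ground_truth` (tibble: `participant_id`, `p_switch`,
#'   `latent_coherence`) with attribute `"realized_rho"`.
#' @export
generate_cohort <- function(spec, space = topic_space(),
                            profile = drift_profile()) {
  stopifnot(inherits(spec, "semcoh_cohort_spec"))
  n <- spec$n_participants
  ids <- sprintf("S%03d", seq_len(n))
  a <- spec$p_switch_beta[1]; b <- spec$p_switch_beta[2]
  beta_mean <- a / (a + b)
  beta_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))

  p_switch <- with_seed(stream_seed(spec$seed, "p_switch"),
                        stats::rbeta(n, a, b))
  z <- (beta_mean - p_switch) / beta_sd  # latent coherence, higher = better

  links <- spec$outcome_links
  clinical <- tibble::tibble(participant_id = ids)
  realized <- list()
  with_seed(stream_seed(spec$seed, "outcomes"), {
    t2_alive <- stats::runif(n) < spec$t2_completion
    for (i in seq_len(nrow(links))) {
      L <- links[i, ]
      z1 <- L$rho * z + sqrt(1 - L$rho^2) * stats::rnorm(n)
      v1 <- scale_outcome(z1, L)
      clinical[[L$outcome]] <- v1
      realized[[length(realized) + 1L]] <- tibble::tibble(
        outcome = L$outcome, target_rho = L$rho, realized_rho = stats::cor(z, v1))
      if (isTRUE(L$t2)) {
        ab <- solve(matrix(c(1, L$rho, L$rho, 1), 2),
                    c(spec$t1_t2_autocorr, spec$t2_coherence_rho))
        resid_var <- 1 - ab[1]^2 - ab[2]^2 - 2 * ab[1] * ab[2] * L$rho
        if (resid_var < 0) {
          stop("infeasible correlation structure for T2 outcome '",
               L$outcome, "': implied matrix not positive definite",
               call. = FALSE)
        }
        z2 <- ab[1] * z1 + ab[2] * z + sqrt(resid_var) * stats::rnorm(n)
        v2 <- scale_outcome(z2, L)
        v2[!t2_alive] <- NA
        clinical[[paste0(L$outcome, "_t2")]] <- v2
      }
    }
  })

  clinical <- with_seed(stream_seed(spec$seed, "covariates"), {
    dplyr::mutate(
      clinical,
      age = pmin(65, pmax(18, round(stats::rnorm(n, 38.8, 10.4), 1))),
      sex = ifelse(stats::runif(n) < 0.634, "male", "female"),
      education_years = pmax(8, round(stats::rnorm(n, 15.3, 3.4), 1)),
      verbal_iq = round(stats::rnorm(n, 105.4, 12.2), 1),
      medication = stats::runif(n) < 0.873
    )
  })

  transcripts <- lapply(seq_len(n), function(i) {
    generate_transcript(space, profile,
                        seed = stream_seed(spec$seed, paste0("transcript_", ids[i])),
                        participant_id = ids[i], p_switch = p_switch[i])
  })

  gt <- tibble::tibble(participant_id = ids, p_switch = p_switch,
                       latent_coherence = z)
  attr(gt, "realized_rho") <- dplyr::bind_rows(realized)
  list(transcripts = transcripts, clinical = clinical, ground_truth = gt)
}

scale_outcome <- function(zscores, link) {
  v <- link$mean + link$sd * zscores
  v <- pmin(link$max, pmax(link$min, v))
  if (isTRUE(link$integer)) round(v) else round(v, 2)
}

#' Write a generated cohort to disk
#'
#' Transcripts go to `<dir>/transcripts/<id>.json` (structured format), the
#' clinical table to `<dir>/clinical.csv`, the ground truth to
#' `<dir>/ground_truth.csv`.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (t in cohort$transcripts) {
    write_transcript(t, file.path(tdir, paste0(t$participant_id, ".json")))
  }
  readr::write_csv(cohort$clinical, file.path(dir, "clinical.csv"))
  readr::write_csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"))
  invisible(dir)
}
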