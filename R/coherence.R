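#' Local (first-order) semantic coherence
#'
#' The cosine similarities between embedding vectors of adjacent sentences,
#' summed over the N-1 adjacent pairs of an N-sentence sequence. Two
#' denominator conventions are provided. `"pairs"` (default) divides by the
#' number of summed terms, N-1, so a perfectly self-similar text scores
#' exactly 1; this matches the prose definition of the metric as the
#' similarity *averaged across all sentence pairs*. `"verbatim_n"` divides
#' the same (N-1)-term sum by N, reproducing a displayed-equation convention
#' sometimes seen in the literature in which the identity case scores
#' (N-1)/N. Fewer than two sentences leave no adjacent pair: the score is
#' missing (`NA`), never 0.
#'
#' @param vectors Numeric N x d matrix of sentence vectors in text order
#'   (rows with no defined vector must already be removed), or the list
#'   returned by [section_vectors()].
#' @param denominator `"pairs"` or `"verbatim_n"`.
#' @return Numeric score in `[-1, 1]`, or `NA_real_` when N < 2.
#' @export
#' @examples
#' m <- rbind(c(1, 0), c(1, 0), c(0, 1))
#' local_coherence(m)               # (1 + 0) / 2
#' local_coherence(m, "verbatim_n") # (1 + 0) / 3
local_coherence <- function(vectors, denominator = c("pairs", "verbatim_n")) {
  denominator <- match.arg(denominator)
  m <- as_vector_matrix(vectors)
  n <- nrow(m)
  if (n < 2L) return(NA_real_)
  sims <- vapply(seq_len(n - 1L), function(i) {
    cosine_similarity(m[i, ], m[i + 1L, ])
  }, numeric(1))
  sum(sims) / if (denominator == "pairs") (n - 1L) else n
}

#' Global semantic coherence
#'
#' The cosine similarity between each sentence vector and the centroid (the
#' arithmetic mean) of all sentence vectors in the sequence. `"terms"`
#' (default) averages the similarity over all N sentences, matching the
#' prose definition (*each* sentence against the average); `"verbatim_n"`
#' sums only the first N-1 similarities and divides by N, reproducing the
#' displayed-equation convention whose identity case scores (N-1)/N. A
#' single-sentence sequence has centroid equal to the sentence, so the
#' default-mode score is exactly 1. An empty sequence, or one whose centroid
#' has zero norm (exactly opposed vectors), has no defined score: `NA`.
#'
#' @inheritParams local_coherence
#' @param denominator `"terms"` or `"verbatim_n"`.
#' @return Numeric score in `[-1, 1]`, or `NA_real_`.
#' @export
#' @examples
#' global_coherence(rbind(c(1, 0), c(0, 1)))  # sqrt(2)/2
global_coherence <- function(vectors, denominator = c("terms", "verbatim_n")) {
  denominator <- match.arg(denominator)
  m <- as_vector_matrix(vectors)
  n <- nrow(m)
  if (n < 1L) return(NA_real_)
  centroid <- colMeans(m)
  if (sum(centroid^2) == 0) return(NA_real_)
  k <- if (denominator == "terms") n else n - 1L
  if (k < 1L) return(NA_real_)
  sims <- vapply(seq_len(k), function(i) {
    cosine_similarity(m[i, ], centroid)
  }, numeric(1))
  sum(sims) / n
}

as_vector_matrix <- function(vectors) {
  if (is.list(vectors) && !is.null(vectors$vectors)) vectors <- vectors$vectors
  if (!is.matrix(vectors)) {
    stop("`vectors` must be a matrix or a section_vectors() result",
         call. = FALSE)
  }
  vectors
}

#' Coherence scores per emotion section
#'
#' @param pp A `semcoh_preprocessed` transcript.
#' @param models List of `semcoh_embedding` models (names taken from the
#'   models).
#' @param local_mode,global_mode Denominator conventions; see
#'   [local_coherence()] and [global_coherence()].
#' @return A tibble with one row per section x model: `participant_id`,
#'   `emotion`, `model`, `local`, `global`, `n_sentences_used`, `skipped`.
#' @export
coherence_by_section <- function(pp, models,
                                 local_mode = c("pairs", "verbatim_n"),
                                 global_mode = c("terms", "verbatim_n")) {
  stopifnot(inherits(pp, "semcoh_preprocessed"))
  local_mode <- match.arg(local_mode)
  global_mode <- match.arg(global_mode)
  if (inherits(models, "semcoh_embedding")) models <- list(models)
  rows <- list()
  for (model in models) {
    for (s in pp) {
      sv <- section_vectors(s$sentences, model)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = attr(pp, "participant_id"),
        emotion = s$emotion,
        model = model$name,
        local = local_coherence(sv, local_mode),
        global = global_coherence(sv, global_mode),
        n_sentences_used = sv$n,
        skipped = sv$skipped
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-participant coherence metrics
#'
#' Section scores are averaged, unweighted, over the emotion sections with a
#' defined score (missing sections contribute nothing; they are counted, not
#' zero-filled). With two embedding models this yields the four-metric
#' design: local and global coherence, once per model.
#'
#' @inheritParams coherence_by_section
#' @return A tibble with one row per model: `participant_id`, `model`,
#'   `local`, `global`, `sections_contributing`. The section-level table is
#'   attached as attribute `"sections"`.
#' @export
score_participant <- function(pp, models,
                              local_mode = c("pairs", "verbatim_n"),
                              global_mode = c("terms", "verbatim_n")) {
  secs <- coherence_by_section(pp, models, local_mode, global_mode)
  agg <- secs |>
    dplyr::group_by(.data$participant_id, .data$model) |>
    dplyr::summarise(
      sections_contributing = sum(!is.na(.data$local) | !is.na(.data$global)),
      local = mean_or_na(.data$local),
      global = mean_or_na(.data$global),
      .groups = "drop"
    ) |>
    dplyr::relocate("sections_contributing", .after = "global")
  attr(agg, "sections") <- secs
  agg
}

mean_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else mean(x)
}

#' Score a set of transcripts with one or more embedding models
#'
#' Runs annotation (if needed), preprocessing and coherence scoring over a
#' list of transcripts and returns the participant-level score table in wide
#' layout — one row per participant, a `<model>_local` and `<model>_global`
#' column per model — plus transcript-length provenance columns.
#'
#' @param transcripts List of `semcoh_transcript` objects.
#' @param models List of `semcoh_embedding` models.
#' @param lex,lemmatizer Passed to [preprocess_transcript()].
#' @param annotate_mode Sentence-boundary mode for unannotated transcripts.
#' @inheritParams coherence_by_section
#' @return A wide tibble; section-level scores attached as attribute
#'   `"sections"`.
#' @export
score_transcripts <- function(transcripts, models,
                              lex = default_lexicons(),
                              lemmatizer = identity_lemmatizer(),
                              annotate_mode = c("marker", "automatic"),
                              local_mode = c("pairs", "verbatim_n"),
                              global_mode = c("terms", "verbatim_n")) {
  annotate_mode <- match.arg(annotate_mode)
  local_mode <- match.arg(local_mode)
  global_mode <- match.arg(global_mode)
  if (inherits(models, "semcoh_embedding")) models <- list(models)
  per_part <- list()
  all_secs <- list()
  for (t in transcripts) {
    if (any(vapply(t$sections, function(s) is.null(s$sentences), logical(1)))) {
      t <- annotate_transcript(t, mode = annotate_mode)
    }
    pp <- preprocess_transcript(t, lex = lex, lemmatizer = lemmatizer)
    sc <- score_participant(pp, models, local_mode, global_mode)
    all_secs[[length(all_secs) + 1L]] <- attr(sc, "sections")
    wide <- sc |>
      tidyr::pivot_wider(id_cols = "participant_id", names_from = "model",
                         values_from = c("local", "global"),
                         names_glue = "{model}_{.value}")
    wide$sections_contributing <- max(sc$sections_contributing)
    wide$words <- attr(pp, "words_raw")
    wide$unique_words <- attr(pp, "unique_words_raw")
    per_part[[length(per_part) + 1L]] <- wide
  }
  out <- dplyr::bind_rows(per_part)
  attr(out, "sections") <- dplyr::bind_rows(all_secs)
  out
}
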