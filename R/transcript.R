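#' Construct an interview transcript
#'
#' A transcript holds one participant's semi-structured emotion interview:
#' up to four sections (sadness, fear, anger, happiness — always in that
#' order), each with the interviewer's question texts and the participant's
#' raw answer text. Questions are kept only for provenance; they are excluded
#' from all downstream analysis.
#'
#' @param participant_id Non-empty participant identifier.
#' @param sections List of [emotion_section()] objects, at most one per
#'   emotion. Stored in canonical emotion order regardless of input order.
#' @param language BCP-47-ish language tag, default `"de"`.
#' @return A `semcoh_transcript` object.
#' @export
transcript <- function(participant_id, sections = list(), language = "de") {
  if (!is.character(participant_id) || length(participant_id) != 1L ||
      !nzchar(participant_id)) {
    stop("`participant_id` must be a non-empty string", call. = FALSE)
  }
  emos <- vapply(sections, function(s) s$emotion, character(1))
  if (anyDuplicated(emos)) {
    stop("duplicate emotion section(s): ",
         paste(unique(emos[duplicated(emos)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(emos, NET_EMOTIONS)
  if (length(bad)) {
    stop("unknown emotion label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ord <- order(match(emos, NET_EMOTIONS))
  sections <- sections[ord]
  names(sections) <- emos[ord]
  structure(
    list(participant_id = participant_id, language = language,
         sections = sections),
    class = "semcoh_transcript"
  )
}

#' Construct one emotion section of a transcript
#'
#' @param emotion One of `"sadness"`, `"fear"`, `"anger"`, `"happiness"`.
#' @param questions Character vector of question texts (excluded from
#'   analysis).
#' @param answer Raw answer text; preserved byte-for-byte by the structured
#'   reader/writer.
#' @param sentences Optional list of token vectors, normally populated by
#'   [annotate_sentences()].
#' @return A `semcoh_section` object.
#' @export
emotion_section <- function(emotion, questions = character(), answer = "",
                            sentences = NULL) {
  emotion <- match.arg(emotion, NET_EMOTIONS)
  stopifnot(is.character(questions), is.character(answer), length(answer) == 1L)
  structure(
    list(emotion = emotion, questions = questions, answer = answer,
         sentences = sentences, boundary_source = NA_character_),
    class = "semcoh_section"
  )
}

#' @export
print.semcoh_transcript <- function(x, ...) {
  cat("<semcoh_transcript> participant", x$participant_id,
      sprintf("[%s]", x$language), "\n")
  for (s in x$sections) {
    n_sent <- if (is.null(s$sentences)) "unannotated" else
      paste(length(s$sentences), "sentences")
    cat(sprintf("  %-10s %4d chars, %s\n", s$emotion, nchar(s$answer), n_sent))
  }
  ms <- missing_sections(x)
  if (length(ms)) cat("  missing:", paste(ms, collapse = ", "), "\n")
  invisible(x)
}

#' Emotions absent from a transcript
#'
#' @param t A `semcoh_transcript`.
#' @return Character vector of emotion labels with no section in `t`.
#' @export
missing_sections <- function(t) {
  setdiff(NET_EMOTIONS, names(t$sections))
}

#' Tokenize raw text
#'
#' Whitespace tokenization with Unicode NFC normalization and stripping of
#' leading/trailing punctuation and symbols. Case is preserved (German nouns
#' are case-bearing and some embedding models are case-sensitive); word-
#' internal hyphens and apostrophes survive.
#'
#' @param x Character scalar or vector.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize_text("Der Hund bellt, und die Katze schläft.")
tokenize_text <- function(x) {
  x <- stringi::stri_trans_nfc(x)
  toks <- unlist(stringi::stri_split_regex(x, "\\s+"), use.names = FALSE)
  toks <- stringi::stri_replace_all_regex(
    toks, "^[\\p{P}\\p{S}]+|[\\p{P}\\p{S}]+$", "")
  toks[nzchar(toks)]
}

#' Default coordinating-conjunction list for the automatic splitter
#'
#' Coordinating conjunctions that join independent main clauses; in automatic
#' annotation mode a comma or semicolon followed by one of these triggers a
#' sentence split. Subordinating conjunctions (weil, wenn, dass, ...) are
#' deliberately absent: main clauses stay joined to their subordinate clauses.
#'
#' @return Character vector of conjunctions.
#' @export
coordinating_conjunctions <- function() {
  c("und", "oder", "aber", "denn", "sondern", "doch",
    "and", "or", "but", "so")
}

#' Annotate sentence boundaries in a section
#'
#' In `marker` mode (the reference path) splits occur exactly at sentence-
#' final punctuation (`.`, `!`, `?`) placed during manual annotation; this is
#' the mode under which the annotation guidelines' worked examples hold
#' (subordinate clauses never split off; coordinated main clauses separated
#' by annotator-inserted periods; incomplete clauses ended on a period). In
#' `automatic` mode, a rule-based convenience splitter additionally splits at
#' a comma/semicolon followed by a listed coordinating conjunction; it is an
#' approximation of the manual guidelines, not a replacement.
#'
#' @param section A `semcoh_section`.
#' @param mode `"marker"` (default) or `"automatic"`.
#' @param conjunctions Conjunction list for automatic mode; see
#'   [coordinating_conjunctions()].
#' @return The section with `sentences` populated (list of token vectors)
#'   and `boundary_source` recorded. An empty answer yields zero sentences
#'   with a warning, not an error.
#' @export
#' @examples
#' s <- emotion_section("sadness", answer = "John eats when he is hungry.")
#' length(annotate_sentences(s)$sentences)  # 1
annotate_sentences <- function(section, mode = c("marker", "automatic"),
                               conjunctions = coordinating_conjunctions()) {
  mode <- match.arg(mode)
  stopifnot(inherits(section, "semcoh_section"))
  txt <- section$answer
  if (!nzchar(trimws(txt))) {
    warning(sprintf("section '%s': empty answer text, zero sentences",
                    section$emotion), call. = FALSE)
    section$sentences <- list()
    section$boundary_source <- mode
    return(section)
  }
  pieces <- stringi::stri_split_regex(txt, "(?<=[.!?])\\s+")[[1]]
  if (mode == "automatic" && length(conjunctions)) {
    conj_re <- sprintf("(?<=[,;])\\s+(?=(?:%s)\\b)",
                       paste(stringi::stri_trans_tolower(conjunctions),
                             collapse = "|"))
    pieces <- unlist(stringi::stri_split_regex(
      pieces, conj_re, case_insensitive = TRUE), use.names = FALSE)
  }
  sent_tokens <- lapply(pieces, tokenize_text)
  sent_tokens <- sent_tokens[lengths(sent_tokens) > 0]
  section$sentences <- sent_tokens
  section$boundary_source <- if (mode == "marker") "manual_marker"
                             else "automatic_split"
  section
}

#' Annotate all sections of a transcript
#'
#' @inheritParams annotate_sentences
#' @param t A `semcoh_transcript`.
#' @return The transcript with every section annotated.
#' @export
annotate_transcript <- function(t, mode = c("marker", "automatic"),
                                conjunctions = coordinating_conjunctions()) {
  mode <- match.arg(mode)
  t$sections <- lapply(t$sections, annotate_sentences, mode = mode,
                       conjunctions = conjunctions)
  t
}

# ---- file formats -----------------------------------------------------------

PLAIN_ESCAPE_RE <- "^(## |# |\\? |\\\\)"

#' Read a transcript file
#'
#' Two on-disk formats are supported. `structured` is a JSON record with
#' fields `participant_id`, `language` and a `sections` array of
#' `{emotion, questions, answer}` objects; answer text round-trips
#' byte-for-byte. `plain` is UTF-8 text with `# participant:` / `# language:`
#' header lines, one `## <emotion>` header per section, `? `-prefixed
#' question lines, and free answer lines. In plain files an answer line that
#' would itself read as a marker (`## `, `# `, `? `, or a leading backslash)
#' is escaped with a single leading backslash; the reader strips it.
#'
#' @param path File path.
#' @param format `"structured"`, `"plain"`, or `"auto"` (sniffs a leading
#'   `{`).
#' @return A `semcoh_transcript`. Emotions absent from the file are reported
#'   via [missing_sections()], not invented.
#' @export
read_transcript <- function(path, format = c("auto", "structured", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readr::read_lines(path, n_max = 1L)
    format <- if (length(first) && grepl("^\\s*\\{", first)) "structured"
              else "plain"
  }
  if (format == "structured") read_transcript_structured(path)
  else read_transcript_plain(path)
}

read_transcript_structured <- function(path) {
  rec <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed structured transcript '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  for (field in c("participant_id", "sections")) {
    if (is.null(rec[[field]])) {
      stop("structured transcript '", path, "': missing field '", field, "'",
           call. = FALSE)
    }
  }
  sections <- lapply(rec$sections, function(s) {
    if (is.null(s$emotion)) {
      stop("structured transcript '", path,
           "': section without 'emotion' field", call. = FALSE)
    }
    if (!s$emotion %in% NET_EMOTIONS) {
      stop("structured transcript '", path, "': unknown emotion label '",
           s$emotion, "'", call. = FALSE)
    }
    emotion_section(s$emotion,
                    questions = as.character(unlist(s$questions %||% list())),
                    answer = s$answer %||% "")
  })
  transcript(rec$participant_id, sections,
             language = rec$language %||% "de")
}

read_transcript_plain <- function(path) {
  lines <- readr::read_lines(path)
  pid <- NA_character_
  lang <- "de"
  sections <- list()
  cur_emotion <- NULL
  cur_q <- character()
  cur_a <- character()
  flush_section <- function() {
    if (is.null(cur_emotion)) return()
    # drop a single trailing blank separator line the writer emits
    a <- cur_a
    while (length(a) && !nzchar(a[length(a)])) a <- a[-length(a)]
    sections[[length(sections) + 1L]] <<-
      emotion_section(cur_emotion, questions = cur_q,
                      answer = paste(a, collapse = "\n"))
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^## ", line)) {
      flush_section()
      emo <- trimws(sub("^## ", "", line))
      if (!emo %in% NET_EMOTIONS) {
        stop("plain transcript '", path, "' line ", i,
             ": unknown emotion header '", emo, "'", call. = FALSE)
      }
      cur_emotion <- emo
      cur_q <- character()
      cur_a <- character()
    } else if (is.null(cur_emotion) && grepl("^# participant:", line)) {
      pid <- trimws(sub("^# participant:", "", line))
    } else if (is.null(cur_emotion) && grepl("^# language:", line)) {
      lang <- trimws(sub("^# language:", "", line))
    } else if (is.null(cur_emotion)) {
      if (nzchar(trimws(line))) {
        stop("plain transcript '", path, "' line ", i,
             ": unexpected content before first '## <emotion>' header",
             call. = FALSE)
      }
    } else if (grepl("^\\? ", line)) {
      cur_q <- c(cur_q, sub("^\\? ", "", line))
    } else {
      cur_a <- c(cur_a, sub("^\\\\", "", line))  # unescape
    }
  }
  flush_section()
  if (is.na(pid)) {
    stop("plain transcript '", path, "': missing '# participant:' header",
         call. = FALSE)
  }
  transcript(pid, sections, language = lang)
}

#' Write a transcript file
#'
#' Inverse of [read_transcript()]; `write_transcript()` then
#' [read_transcript()] is content-identical for valid transcripts.
#'
#' @param t A `semcoh_transcript`.
#' @param path Output path.
#' @param format `"structured"` (JSON, default) or `"plain"`.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(t, path, format = c("structured", "plain")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "semcoh_transcript"))
  if (format == "structured") {
    rec <- list(
      participant_id = t$participant_id,
      language = t$language,
      sections = lapply(unname(t$sections), function(s) {
        list(emotion = s$emotion, questions = as.list(s$questions),
             answer = s$answer)
      })
    )
    jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    esc <- function(x) ifelse(grepl(PLAIN_ESCAPE_RE, x), paste0("\\", x), x)
    out <- c(paste0("# participant: ", t$participant_id),
             paste0("# language: ", t$language))
    for (s in t$sections) {
      out <- c(out, "", paste0("## ", s$emotion))
      if (length(s$questions)) out <- c(out, paste0("? ", esc(s$questions)))
      if (nzchar(s$answer)) {
        out <- c(out, esc(strsplit(s$answer, "\n", fixed = TRUE)[[1]]))
      }
    }
    readr::write_lines(out, path)
  }
  invisible(path)
}

#' Word-count statistics of a transcript
#'
#' Raw counts are taken over all annotated answer tokens (questions excluded);
#' processed counts, when a preprocessed transcript is supplied, are taken
#' after filler/stopword removal and lemmatization.
#'
#' @param t An annotated `semcoh_transcript`.
#' @return A tibble with `participant_id`, `words`, `unique_words`.
#' @export
transcript_word_stats <- function(t) {
  stopifnot(inherits(t, "semcoh_transcript"))
  toks <- unlist(lapply(t$sections, function(s) {
    if (is.null(s$sentences)) tokenize_text(s$answer) else unlist(s$sentences)
  }), use.names = FALSE)
  tibble::tibble(
    participant_id = t$participant_id,
    words = length(toks),
    unique_words = length(unique(toks))
  )
}
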