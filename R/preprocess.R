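#' Build a lexicon set for preprocessing
#'
#' Holds the filler inventory, the stopword inventory and the conjunction
#' list for the automatic splitter. Matching against fillers and stopwords is
#' case-insensitive (both sides lowercased); emitted tokens keep their
#' original casing. German stopwords routinely appear sentence-initially
#' capitalized, which is why matching must not be case-sensitive.
#'
#' @param fillers Character vector of verbal fillers (e.g. "ehm").
#' @param stopwords Character vector of stopwords.
#' @param conjunction_splitters Conjunctions for automatic sentence
#'   splitting.
#' @return A `semcoh_lexicons` object.
#' @export
lexicons <- function(fillers = character(), stopwords = character(),
                     conjunction_splitters = coordinating_conjunctions()) {
  structure(
    list(fillers = unique(stringi::stri_trans_tolower(fillers)),
         stopwords = unique(stringi::stri_trans_tolower(stopwords)),
         conjunction_splitters = conjunction_splitters),
    class = "semcoh_lexicons"
  )
}

#' Read a one-token-per-line lexicon file
#'
#' UTF-8, one entry per line; blank lines and `#` comment lines are ignored.
#'
#' @param path File path.
#' @return Character vector of entries.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("no such lexicon file: ", path, call. = FALSE)
  x <- readr::read_lines(path)
  x <- trimws(sub("#.*$", "", x))
  x[nzchar(x)]
}

#' Default German lexicons shipped with the package
#'
#' A general-purpose German stopword list and a verbal-filler list, stored as
#' versioned resource files under `extdata/`. The exact inventories used in
#' any given study are rarely published and coherence scores are sensitive to
#' them, so analyses that must match an external pipeline should pass their
#' own lists to [lexicons()] instead.
#'
#' @return A `semcoh_lexicons` object.
#' @export
default_lexicons <- function() {
  lexicons(
    fillers = read_lexicon(system.file("extdata", "fillers_de.txt",
                                       package = "semcoh", mustWork = TRUE)),
    stopwords = read_lexicon(system.file("extdata", "stopwords_de.txt",
                                         package = "semcoh", mustWork = TRUE))
  )
}

match_lexicon <- function(tokens, entries) {
  stringi::stri_trans_tolower(tokens) %in% entries
}

#' Remove verbal fillers from a token list
#'
#' @param tokens Character vector of tokens.
#' @param lex A `semcoh_lexicons`.
#' @return `tokens` with filler members removed, order preserved. May be
#'   empty.
#' @export
#' @examples
#' remove_fillers(c("ehm", "ich", "bin", "ehm", "traurig"),
#'                lexicons(fillers = "ehm"))
remove_fillers <- function(tokens, lex) {
  tokens[!match_lexicon(tokens, lex$fillers)]
}

#' Remove stopwords from a token list
#'
#' @inheritParams remove_fillers
#' @return `tokens` with stopword members removed, order preserved.
#' @export
remove_stopwords <- function(tokens, lex) {
  tokens[!match_lexicon(tokens, lex$stopwords)]
}

#' Lemmatizer constructors
#'
#' The lemmatizer contract is a total function from a token vector to a
#' same-length lemma vector. `identity_lemmatizer()` maps every token to
#' itself; `table_lemmatizer()` looks surface forms up in a table (matching
#' case-insensitively) and passes unknown tokens through unchanged.
#' `read_lemma_table()` loads a two-column tab-separated `surface<TAB>lemma`
#' file.
#'
#' @return A function `character(n) -> character(n)`.
#' @export
identity_lemmatizer <- function() {
  function(tokens) tokens
}

#' @param table Named character vector, `names` = surface forms, values =
#'   lemmas.
#' @rdname identity_lemmatizer
#' @export
table_lemmatizer <- function(table) {
  stopifnot(is.character(table), !is.null(names(table)))
  names(table) <- stringi::stri_trans_tolower(names(table))
  function(tokens) {
    hit <- table[stringi::stri_trans_tolower(tokens)]
    unname(ifelse(is.na(hit), tokens, hit))
  }
}

#' @param path Path to a `surface<TAB>lemma` file; `#` comments allowed.
#' @rdname identity_lemmatizer
#' @export
read_lemma_table <- function(path) {
  rows <- read_lexicon(path)
  parts <- stringi::stri_split_fixed(rows, "\t", n = 2L)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("lemma table '", path, "': entry ", bad[1],
         " is not 'surface<TAB>lemma'", call. = FALSE)
  }
  stats::setNames(vapply(parts, `[`, character(1), 2L),
                  vapply(parts, `[`, character(1), 1L))
}

#' Apply a lemmatizer to a token list
#'
#' Element-wise; order and length preserved. If the lemmatizer fails or
#' returns a malformed result, surface forms are kept and a warning is
#' issued.
#'
#' @param tokens Character vector.
#' @param lemmatizer A function per the lemmatizer contract.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
lemmatize_tokens <- function(tokens, lemmatizer = identity_lemmatizer()) {
  if (!length(tokens)) return(tokens)
  out <- tryCatch(lemmatizer(tokens), error = function(e) e)
  if (inherits(out, "error") || !is.character(out) ||
      length(out) != length(tokens) || anyNA(out)) {
    warning("lemmatizer failed; keeping surface forms", call. = FALSE)
    return(tokens)
  }
  out
}

#' Preprocess an annotated transcript
#'
#' Applies the preprocessing chain in a fixed order — verbal-filler removal,
#' then stopword removal, then lemmatization — to every annotated sentence of
#' every section. The order is deliberate and not configurable: lemmatizing
#' before stopword removal could change stopword membership (e.g. an
#' inflected article lemmatized to its citation form), and a silent
#' divergence there is worse than a fixed documented convention. Question
#' texts are never part of the token stream. Sentences whose every token is
#' removed are dropped and counted, not carried as empty husks.
#'
#' @param t An annotated `semcoh_transcript` (see [annotate_transcript()]).
#' @param lex A `semcoh_lexicons`.
#' @param lemmatizer Lemmatizer function; default identity.
#' @return A `semcoh_preprocessed` object: list of per-emotion elements,
#'   each with `emotion`, `sentences` (list of non-empty token vectors),
#'   `dropped_sentence_count`, `removed_token_count`; plus the transcript's
#'   id, raw and processed word counts as attributes.
#' @export
preprocess_transcript <- function(t, lex = default_lexicons(),
                                  lemmatizer = identity_lemmatizer()) {
  stopifnot(inherits(t, "semcoh_transcript"), inherits(lex, "semcoh_lexicons"))
  if (any(vapply(t$sections, function(s) is.null(s$sentences), logical(1)))) {
    stop("transcript must be annotated before preprocessing; ",
         "see annotate_transcript()", call. = FALSE)
  }
  raw_tokens <- unlist(lapply(t$sections, function(s) unlist(s$sentences)),
                       use.names = FALSE)
  out <- lapply(t$sections, function(s) {
    kept <- list()
    dropped <- 0L
    removed <- 0L
    for (sent in s$sentences) {
      toks <- remove_fillers(sent, lex)
      toks <- remove_stopwords(toks, lex)
      removed <- removed + (length(sent) - length(toks))
      toks <- lemmatize_tokens(toks, lemmatizer)
      if (length(toks)) kept[[length(kept) + 1L]] <- toks
      else dropped <- dropped + 1L
    }
    if (!length(kept) && length(s$sentences)) {
      warning(sprintf("section '%s': no sentence survived preprocessing",
                      s$emotion), call. = FALSE)
    }
    list(emotion = s$emotion, sentences = kept,
         dropped_sentence_count = dropped, removed_token_count = removed)
  })
  proc_tokens <- unlist(lapply(out, function(s) unlist(s$sentences)),
                        use.names = FALSE)
  structure(out,
            class = "semcoh_preprocessed",
            participant_id = t$participant_id,
            words_raw = length(raw_tokens),
            unique_words_raw = length(unique(raw_tokens)),
            words_processed = length(proc_tokens),
            unique_words_processed = length(unique(proc_tokens)))
}

#' @export
print.semcoh_preprocessed <- function(x, ...) {
  cat("<semcoh_preprocessed> participant", attr(x, "participant_id"),
      sprintf("(%d raw words, %d unique)\n",
              attr(x, "words_raw"), attr(x, "unique_words_raw")))
  for (s in x) {
    cat(sprintf("  %-10s %3d sentences kept, %d dropped, %d tokens removed\n",
                s$emotion, length(s$sentences), s$dropped_sentence_count,
                s$removed_token_count))
  }
  invisible(x)
}
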