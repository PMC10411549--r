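#' Construct a word-embedding model
#'
#' A static word-to-vector map of fixed dimension. Lookup policy for
#' case-sensitive models: exact match first, then (if `lowercase_fallback`)
#' a single fallback to the lowercased form; both misses make the token
#' out-of-vocabulary.
#'
#' @param vectors Numeric matrix, one row per word, rownames = vocabulary.
#' @param name Model name used in score tables.
#' @param case_sensitive Whether lookups distinguish case.
#' @param lowercase_fallback Try the lowercased form before declaring a
#'   token OOV (only meaningful for case-sensitive models).
#' @return A `semcoh_embedding` object.
#' @export
embedding_model <- function(vectors, name = "model",
                            case_sensitive = TRUE,
                            lowercase_fallback = TRUE) {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (!nrow(vectors)) stop("embedding vocabulary is empty", call. = FALSE)
  if (is.null(rownames(vectors))) {
    stop("embedding matrix must carry the vocabulary as rownames",
         call. = FALSE)
  }
  if (!all(is.finite(vectors))) {
    stop("embedding vectors contain NaN/Inf components", call. = FALSE)
  }
  structure(
    list(name = name, dimension = ncol(vectors), vectors = vectors,
         case_sensitive = case_sensitive,
         lowercase_fallback = lowercase_fallback),
    class = "semcoh_embedding"
  )
}

#' @export
print.semcoh_embedding <- function(x, ...) {
  cat(sprintf("<semcoh_embedding> '%s': %d words x %d dims\n",
              x$name, nrow(x$vectors), x$dimension))
  invisible(x)
}

#' Read a word-vector file in word2vec-text or GloVe-text dialect
#'
#' Both dialects are UTF-8, space-separated, one word plus its vector
#' components per line; word2vec-text carries a `<vocab> <dim>` header line,
#' GloVe-text does not. In `auto` mode the dialect is detected by whether the
#' first line is exactly two integers. Duplicate words keep the first
#' occurrence (with a warning); the dimension is inferred from the first data
#' line and enforced on all others. Binary word2vec files are not supported.
#'
#' @param path File path.
#' @param dialect `"auto"` (default), `"word2vec_text"`, or `"glove_text"`.
#' @param name Model name; defaults to the file name sans extension.
#' @inheritParams embedding_model
#' @return A `semcoh_embedding`.
#' @export
read_embeddings <- function(path,
                            dialect = c("auto", "word2vec_text", "glove_text"),
                            name = NULL, case_sensitive = TRUE,
                            lowercase_fallback = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such vector file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty vector file: ", path, call. = FALSE)
  if (dialect == "auto") {
    first <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
    two_ints <- length(first) == 2L &&
      all(grepl("^[0-9]+$", first))
    dialect <- if (two_ints) "word2vec_text" else "glove_text"
  }
  offset <- 0L
  declared <- NULL
  if (dialect == "word2vec_text") {
    hdr <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
    if (length(hdr) != 2L || !all(grepl("^[0-9]+$", hdr))) {
      stop("vector file '", path,
           "': word2vec_text requires a '<vocab> <dim>' header line",
           call. = FALSE)
    }
    declared <- as.integer(hdr)
    offset <- 1L
  }
  data <- lines[(offset + 1L):length(lines)]
  if (!length(data)) stop("vector file '", path, "': no data lines",
                          call. = FALSE)
  parts <- stringi::stri_split_regex(trimws(data), "\\s+")
  dim <- length(parts[[1]]) - 1L
  if (dim < 1L) stop("vector file '", path, "': line ", offset + 1L,
                     " has no vector components", call. = FALSE)
  ragged <- which(lengths(parts) != dim + 1L)
  if (length(ragged)) {
    stop("vector file '", path, "': line ", ragged[1] + offset,
         " has ", lengths(parts)[ragged[1]] - 1L,
         " components, expected ", dim, call. = FALSE)
  }
  words <- vapply(parts, `[`, character(1), 1L)
  mat <- matrix(as.numeric(unlist(lapply(parts, `[`, -1L))),
                nrow = length(parts), ncol = dim, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1]
    stop("vector file '", path, "': line ", bad + offset,
         " has non-numeric components", call. = FALSE)
  }
  dup <- duplicated(words)
  if (any(dup)) {
    warning("vector file '", path, "': ", sum(dup),
            " duplicate word(s); first occurrence kept", call. = FALSE)
    mat <- mat[!dup, , drop = FALSE]
    words <- words[!dup]
  }
  if (!is.null(declared) && declared[2] != dim) {
    stop("vector file '", path, "': header declares dimension ", declared[2],
         " but data lines have ", dim, call. = FALSE)
  }
  rownames(mat) <- words
  embedding_model(mat,
                  name = name %||% sub("\\.[^.]*$", "", basename(path)),
                  case_sensitive = case_sensitive,
                  lowercase_fallback = lowercase_fallback)
}

#' Write a word-vector file
#'
#' @param model A `semcoh_embedding`.
#' @param path Output path.
#' @param dialect `"word2vec_text"` (with header) or `"glove_text"`.
#' @param digits Significant digits for components.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(model, path,
                             dialect = c("word2vec_text", "glove_text"),
                             digits = 8) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(model, "semcoh_embedding"))
  body <- paste(rownames(model$vectors),
                apply(model$vectors, 1L, function(v) {
                  paste(formatC(v, digits = digits, format = "g"),
                        collapse = " ")
                }))
  if (dialect == "word2vec_text") {
    body <- c(paste(nrow(model$vectors), model$dimension), body)
  }
  readr::write_lines(body, path)
  invisible(path)
}

lookup_rows <- function(tokens, model) {
  if (!model$case_sensitive) {
    idx <- match(stringi::stri_trans_tolower(tokens),
                 stringi::stri_trans_tolower(rownames(model$vectors)))
  } else {
    idx <- match(tokens, rownames(model$vectors))
    if (model$lowercase_fallback && anyNA(idx)) {
      miss <- is.na(idx)
      idx[miss] <- match(stringi::stri_trans_tolower(tokens[miss]),
                         rownames(model$vectors))
    }
  }
  idx
}

#' Sentence vector by mean pooling
#'
#' The embedding vectors of a sentence's in-vocabulary tokens are averaged
#' into one sentence vector. Out-of-vocabulary tokens are simply left out of
#' the average; a sentence with no in-vocabulary token has no vector and is
#' reported as missing (`NULL`), a value the coherence layer excludes and
#' counts — never an error and never a zero vector.
#'
#' @param tokens Character vector of (preprocessed) tokens.
#' @param model A `semcoh_embedding`.
#' @return Numeric vector of length `model$dimension`, or `NULL` if every
#'   token is OOV.
#' @export
sentence_vector <- function(tokens, model) {
  stopifnot(inherits(model, "semcoh_embedding"))
  idx <- lookup_rows(tokens, model)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NULL)
  colMeans(model$vectors[idx, , drop = FALSE])
}

#' Build the sentence-vector sequence of a preprocessed section
#'
#' @param sentences List of token vectors (one per sentence, in order).
#' @param model A `semcoh_embedding`.
#' @return A list with `vectors` (N x dim matrix of the sentences that have
#'   a vector, original order), `n` (= N), and `skipped` (count of all-OOV
#'   sentences excluded).
#' @export
section_vectors <- function(sentences, model) {
  vecs <- lapply(sentences, sentence_vector, model = model)
  keep <- !vapply(vecs, is.null, logical(1))
  mat <- if (any(keep)) do.call(rbind, vecs[keep])
         else matrix(numeric(0), nrow = 0, ncol = model$dimension)
  list(vectors = mat, n = nrow(mat), skipped = sum(!keep))
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`: symmetric, invariant to positive rescaling of
#' either argument, and bounded in `[-1, 1]`. Zero-norm inputs have no
#' defined direction and raise an error; upstream sentence construction
#' guarantees they do not occur.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))  # sqrt(2)/2
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v), length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for zero-norm vector", call. = FALSE)
  }
  # clamp guards against |value| exceeding 1 by floating-point rounding
  min(1, max(-1, sum(u * v) / (nu * nv)))
}
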