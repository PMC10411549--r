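#' Derive a named sub-stream seed from a root seed
#'
#' Every stochastic generator in the package draws its own seed from the run's
#' root seed plus a stream name, so adding a new generator to a workflow never
#' perturbs the random numbers of existing ones.
#'
#' @param root_seed Integer root seed for the run.
#' @param name Character stream name, e.g. `"transcripts"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "transcripts")
stream_seed <- function(root_seed, name) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.character(name))
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 1000003
  # all arithmetic stays below 2^53, result below 2^31
  as.integer(((abs(root_seed) %% 1e9) * 1009 + h * 97) %% 2147483629)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# shared emotion order: fixed across the whole package
NET_EMOTIONS <- c("sadness", "fear", "anger", "happiness")

#' The fixed emotion order of the interview
#'
#' The speech-elicitation interview asks three questions about each of four
#' basic emotions, always in the same order.
#'
#' @return Character vector of the four emotion labels in canonical order.
#' @export
net_emotions <- function() NET_EMOTIONS

is_missing_score <- function(x) is.null(x) || (length(x) == 1L && is.na(x))
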