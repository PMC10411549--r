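# Shared in-code fixtures: a tiny hand-auditable 2-D embedding and toy
# transcripts. Tests never rely on the shipped German lexicons; they pass
# explicit toy lexicons so expected values stay hand-computable.

toy_model_2d <- function(name = "toy2d") {
  m <- rbind(
    sonne  = c(1, 0),
    licht  = c(1, 0),
    regen  = c(0, 1),
    wolke  = c(0, 1),
    mitte  = c(1, 1),
    gegen  = c(-1, 0)
  )
  embedding_model(m, name = name)
}

toy_lexicons <- function() {
  lexicons(fillers = c("ehm", "äh"), stopwords = c("der", "die", "das", "und"))
}

# four sections, marker-annotated boundaries, all tokens in toy_model_2d
toy_transcript <- function(id = "P01") {
  transcript(id, list(
    emotion_section("sadness", questions = "Q?",
                    answer = "sonne licht. regen wolke."),
    emotion_section("fear", answer = "sonne sonne. sonne licht. regen mitte."),
    emotion_section("anger", answer = "mitte mitte."),
    emotion_section("happiness", answer = "licht licht. licht sonne.")
  ))
}

# independent brute-force metric oracles: explicit loops, no package code
# beyond plain arithmetic
oracle_cos <- function(u, v) {
  du <- 0; dv <- 0; dd <- 0
  for (i in seq_along(u)) {
    dd <- dd + u[i] * v[i]
    du <- du + u[i]^2
    dv <- dv + v[i]^2
  }
  dd / (sqrt(du) * sqrt(dv))
}

oracle_local <- function(m, denom = c("pairs", "verbatim_n")) {
  denom <- match.arg(denom)
  n <- nrow(m)
  if (n < 2) return(NA_real_)
  s <- 0
  for (i in 1:(n - 1)) s <- s + oracle_cos(m[i, ], m[i + 1, ])
  s / if (denom == "pairs") n - 1 else n
}

oracle_global <- function(m, denom = c("terms", "verbatim_n")) {
  denom <- match.arg(denom)
  n <- nrow(m)
  if (n < 1) return(NA_real_)
  centroid <- numeric(ncol(m))
  for (i in 1:n) centroid <- centroid + m[i, ]
  centroid <- centroid / n
  if (sum(centroid^2) == 0) return(NA_real_)
  k <- if (denom == "terms") n else n - 1
  if (k < 1) return(NA_real_)
  s <- 0
  for (i in 1:k) s <- s + oracle_cos(m[i, ], centroid)
  s / n
}

random_vector_sequence <- function(n, dim) {
  m <- matrix(stats::rnorm(n * dim), n, dim)
  # ensure nonzero norms (probability-1 anyway)
  m[rowSums(m^2) == 0, 1] <- 1
  m
}
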