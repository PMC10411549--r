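# independent partial-correlation oracle: inverse of the correlation matrix
oracle_partial_inverse <- function(x, y, controls) {
  d <- cbind(x = x, y = y, as.matrix(as.data.frame(controls)))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  p <- solve(stats::cor(d))
  -p[1, 2] / sqrt(p[1, 1] * p[2, 2])
}

# second independent oracle: explicit two-pass residualization via lm()
oracle_partial_resid <- function(x, y, controls) {
  df <- data.frame(x = x, y = y, as.data.frame(controls))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  ctrl <- paste(names(df)[-(1:2)], collapse = " + ")
  rx <- stats::resid(stats::lm(stats::as.formula(paste("x ~", ctrl)), df))
  ry <- stats::resid(stats::lm(stats::as.formula(paste("y ~", ctrl)), df))
  stats::cor(rx, ry)
}

test_that("pearson matches hand-computed fixtures and flags degenerate input", {
  res <- cor_pearson(1:5, 2 * (1:5) + 1)
  expect_equal(res$r, 1.0, tolerance = 1e-12)
  # r for (1,2,3) vs (1,2,4): cov = 1.5, sd_x = 1, sd_y = sqrt(7/3)
  res2 <- cor_pearson(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res2$r, 1.5 / sqrt(7 / 3), tolerance = 1e-9)
  expect_equal(res2$n, 3L)
  expect_error(cor_pearson(c(1, 2, 3), c(2, 2, 2), yname = "flat"), "flat")
  # pairwise deletion
  res3 <- cor_pearson(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_equal(res3$n, 3L)
  expect_equal(res3$r, 1.0)
  # too few pairs: missing result, not an error
  expect_true(is.na(cor_pearson(c(1, NA, NA), c(1, 2, 3))$r))
})

test_that("pearson is symmetric and invariant under positive affine maps", {
  set.seed(11)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(cor_pearson(x, y)$r, cor_pearson(y, x)$r, tolerance = 1e-12)
  expect_equal(cor_pearson(3 * x + 7, y)$r, cor_pearson(x, y)$r,
               tolerance = 1e-12)
})

test_that("partial correlation reduces to pearson with no controls", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(cor_partial(x, y, list())$r, cor_pearson(x, y)$r)
  expect_equal(cor_partial(x, y, list())$p, cor_pearson(x, y)$p)
})

test_that("partial correlation removes a shared confounder", {
  set.seed(13)
  n <- 200
  c1 <- rnorm(n)
  x <- 0.9 * c1 + 0.4 * rnorm(n)   # x and y share c1, nothing else
  y <- 0.9 * c1 + 0.4 * rnorm(n)
  raw <- cor_pearson(x, y)$r
  part <- cor_partial(x, y, list(c1 = c1))$r
  expect_gt(raw, 0.5)              # inflated by the confounder
  expect_lt(abs(part), 0.15)       # near zero once controlled
})

test_that("partial correlation agrees with both independent oracles", {
  set.seed(14)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    k <- sample(1:3, 1)
    ctrl <- as.data.frame(matrix(rnorm(n * k), n))
    x <- rnorm(n) + rowSums(ctrl) * runif(1, -1, 1)
    y <- rnorm(n) + rowSums(ctrl) * runif(1, -1, 1)
    got <- cor_partial(x, y, ctrl)$r
    expect_equal(got, oracle_partial_inverse(x, y, ctrl), tolerance = 1e-9)
    expect_equal(got, oracle_partial_resid(x, y, ctrl), tolerance = 1e-9)
  }
})

test_that("partial correlation errors name collinear controls", {
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20); c1 <- rnorm(20)
  expect_error(cor_partial(x, y, list(a = c1, b = 2 * c1)), "collinear")
  expect_error(cor_partial(x[1:4], y[1:4], list(a = c1[1:4], b = rnorm(4))),
               "n > k \\+ 2")
})

test_that("t-test matches the textbook pooled formula and handles edge cases", {
  a <- c(4.1, 5.2, 6.3, 5.8, 4.9)
  b <- c(3.2, 4.0, 3.6, 4.4)
  res <- coherence_t_test(a, b, var_equal = TRUE)
  # hand computation of the pooled two-sample t
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$t, t_hand, tolerance = 1e-9)
  expect_equal(res$df, length(a) + length(b) - 2)
  # identical groups: t = 0, p = 1
  same <- coherence_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(coherence_t_test(rep(0, 4), rep(1, 4)), "zero variance")
  expect_error(coherence_t_test(1, c(1, 2)), "at least two")
  # Welch is the default and differs from pooled under unequal variances
  set.seed(16)
  g1 <- rnorm(10, sd = 4); g2 <- rnorm(40, sd = 0.5)
  expect_false(isTRUE(all.equal(coherence_t_test(g1, g2)$df,
                                coherence_t_test(g1, g2, var_equal = TRUE)$df)))
})

test_that("validation_report emits the full table set with sane cells", {
  set.seed(17)
  n <- 60
  ids <- sprintf("S%03d", 1:n)
  lat <- rnorm(n)
  scores <- tibble::tibble(
    participant_id = ids,
    toyA_local = 0.6 + 0.05 * lat + rnorm(n, sd = 0.02),
    toyA_global = 0.7 + 0.04 * lat + rnorm(n, sd = 0.02),
    words = round(runif(n, 100, 400))
  )
  clinical <- tibble::tibble(
    participant_id = ids,
    panss_negative = 16 - 3 * lat + rnorm(n, sd = 3),
    panss_negative_t2 = 16 - 2 * lat + rnorm(n, sd = 3),
    empty_outcome = NA_real_,
    age = round(runif(n, 20, 60)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    medication = runif(n) < 0.8
  )
  rep <- validation_report(scores, clinical)
  # self-correlation cells are exactly 1
  self <- rep$score_score[rep$score_score$variable_x ==
                            rep$score_score$variable_y, ]
  expect_true(all(abs(self$r - 1) < 1e-12))
  # the built-in negative-symptom link is recovered with the right sign
  neg <- rep$score_outcome[rep$score_outcome$variable_y == "panss_negative", ]
  expect_true(all(neg$r < 0))
  # all-missing outcome: cells present, flagged missing with n = 0
  emp <- rep$score_outcome[rep$score_outcome$variable_y == "empty_outcome", ]
  expect_equal(nrow(emp), 2L)
  expect_true(all(is.na(emp$r)))
  expect_true(all(emp$n == 0))
  # partial block controls for the T1 outcome
  expect_true(all(rep$partial$controls == "panss_negative"))
  expect_true(all(rep$partial$variable_y == "panss_negative_t2"))
  # t-tests cover both categorical groupings for both scores
  expect_equal(nrow(rep$t_tests), 4L)
  expect_equal(nrow(rep$join_mismatches), 0L)
  # control screen includes transcript length
  expect_true("words" %in% rep$control_screen$variable_y)
  # rendered table carries significance markers and the descriptive banner
  txt <- format_cor_table(rep$score_score)
  expect_match(txt[1], "descriptive")
})

test_that("join mismatches are reported, not silently dropped", {
  scores <- tibble::tibble(participant_id = c("A", "B"),
                           m_local = c(0.5, 0.6), m_global = c(0.7, 0.8))
  clinical <- tibble::tibble(participant_id = c("B", "C"),
                             out = c(1, 2))
  rep <- validation_report(scores, clinical)
  expect_setequal(rep$join_mismatches$participant_id, c("A", "C"))
})
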