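#' Pearson correlation with descriptive p-value
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' usual two-sided p from the t transform on n - 2 degrees of freedom. In
#' exploratory validation work these p-values are descriptive only — no
#' multiple-testing correction is applied anywhere in this package, and the
#' report renderer says so.
#'
#' @param x,y Numeric vectors of equal length (NAs allowed; pairwise
#'   deletion).
#' @param xname,yname Variable names carried into the result.
#' @return A one-row tibble: `variable_x`, `variable_y`, `r`, `n`, `p`,
#'   `controls` (empty string for a plain Pearson correlation).
#' @export
cor_pearson <- function(x, y, xname = "x", yname = "y") {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(tibble::tibble(variable_x = xname, variable_y = yname,
                          r = NA_real_, n = n, p = NA_real_, controls = ""))
  }
  if (stats::var(x) == 0) stop("'", xname, "' has zero variance", call. = FALSE)
  if (stats::var(y) == 0) stop("'", yname, "' has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(variable_x = xname, variable_y = yname,
                 r = unname(ct$estimate), n = n,
                 p = ct$p.value, controls = "")
}

#' Partial correlation by residualization
#'
#' Correlation between `x` and `y` after removing the linear contribution of
#' the control variables from both: each is regressed (least squares, with
#' intercept) on the controls, and the Pearson correlation of the two
#' residual series is taken, with the p-value on n - 2 - k degrees of
#' freedom for k controls. Observations are deleted listwise across x, y and
#' all controls. With no controls this reduces exactly to [cor_pearson()].
#'
#' @inheritParams cor_pearson
#' @param controls A data frame / named list of numeric control variables
#'   (may be empty).
#' @return A one-row tibble as in [cor_pearson()], `controls` holding the
#'   comma-separated control names.
#' @export
cor_partial <- function(x, y, controls = list(), xname = "x", yname = "y") {
  controls <- as.data.frame(controls)
  if (!ncol(controls)) return(cor_pearson(x, y, xname, yname))
  stopifnot(length(x) == length(y), nrow(controls) == length(x))
  k <- ncol(controls)
  ok <- stats::complete.cases(x, y, controls)
  x <- x[ok]; y <- y[ok]
  cm <- as.matrix(controls[ok, , drop = FALSE])
  n <- length(x)
  if (n <= k + 2L) {
    stop("partial correlation needs n > k + 2 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, cm)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dep <- setdiff(colnames(design), colnames(design)[qrd$pivot[seq_len(qrd$rank)]])
    stop("collinear control variable(s): ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  rx <- stats::lm.fit(design, x)$residuals
  ry <- stats::lm.fit(design, y)$residuals
  if (stats::var(rx) == 0) stop("'", xname, "' has zero residual variance",
                                call. = FALSE)
  if (stats::var(ry) == 0) stop("'", yname, "' has zero residual variance",
                                call. = FALSE)
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(variable_x = xname, variable_y = yname, r = r, n = n,
                 p = 2 * stats::pt(-abs(tstat), df),
                 controls = paste(colnames(cm), collapse = ","))
}

#' Independent-samples t-test on coherence scores
#'
#' Two-sample t-test for mean differences between groups (e.g. by sex or
#' medication status). The variance assumption is configurable: Welch
#' (unequal variances) is the default because it is robust and costs almost
#' nothing when variances happen to be equal; the classical pooled-variance
#' test is available by flag.
#'
#' @param group_a,group_b Numeric vectors, each with at least two
#'   non-missing values.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
coherence_t_test <- function(group_a, group_b, var_equal = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two observations", call. = FALSE)
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    stop("both groups have zero variance; t statistic undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = var_equal)
  tibble::tibble(t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b))
}

#' Correlation matrix between two column sets
#'
#' @param data A data frame.
#' @param xvars,yvars Column names to correlate (every x against every y).
#' @param controls Optional character vector of control column names; when
#'   given, partial correlations are computed.
#' @return A long tibble of correlation rows; cells with fewer than three
#'   complete pairs carry `r = NA` and their `n`.
#' @export
cor_table <- function(data, xvars, yvars, controls = character()) {
  rows <- list()
  for (xv in xvars) {
    for (yv in yvars) {
      rows[[length(rows) + 1L]] <- if (length(controls)) {
        cor_partial(data[[xv]], data[[yv]], controls = data[controls],
                    xname = xv, yname = yv)
      } else {
        cor_pearson(data[[xv]], data[[yv]], xname = xv, yname = yv)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Render a correlation table with significance markers
#'
#' Formats a long correlation table as a text matrix (x variables as rows)
#' with the conventional markers `*` (p < .05) and `**` (p < .01). The
#' rendering carries a banner noting that p-values are descriptive and
#' uncorrected for the many parameters examined.
#'
#' @param tbl A tibble from [cor_table()].
#' @param digits Decimal places for r.
#' @param cutoffs Two-element numeric vector, the `*` and `**` thresholds.
#' @return A character vector of rendered lines.
#' @export
format_cor_table <- function(tbl, digits = 3, cutoffs = c(0.05, 0.01)) {
  mark <- function(p) {
    dplyr::case_when(is.na(p) ~ "", p < cutoffs[2] ~ "**",
                     p < cutoffs[1] ~ "*", TRUE ~ "")
  }
  cells <- tbl |>
    dplyr::mutate(cell = ifelse(
      is.na(.data$r), "NA",
      paste0(formatC(.data$r, digits = digits, format = "f"),
             mark(.data$p)))) |>
    tidyr::pivot_wider(id_cols = "variable_x", names_from = "variable_y",
                       values_from = "cell")
  wide <- as.data.frame(cells)
  header <- paste(formatC(colnames(wide), width = 14), collapse = " ")
  body <- apply(wide, 1L, function(r) paste(formatC(r, width = 14),
                                            collapse = " "))
  c("Correlations are exploratory; p-values are descriptive and uncorrected",
    paste0("(* p < ", cutoffs[1], ", ** p < ", cutoffs[2], ")"), "",
    header, body)
}

#' Full validation report for a scored cohort
#'
#' Joins the participant score table to a clinical outcome table and emits
#' the standard validation layer:
#' \describe{
#'   \item{score_score}{correlations among the coherence scores themselves}
#'   \item{score_outcome}{scores against clinical outcomes (cross-sectional)}
#'   \item{partial}{scores against follow-up (T2) outcomes, controlling for
#'     the same outcome at T1 — only for outcomes with both columns present}
#'   \item{t_tests}{mean score differences across each categorical grouping}
#'   \item{control_screen}{scores against nuisance variables (age, education,
#'     verbal IQ, transcript length)}
#' }
#'
#' @param scores Wide score table from [score_transcripts()] (needs
#'   `participant_id` and the score columns).
#' @param clinical Clinical table with `participant_id` and outcome columns.
#' @param outcomes Character vector of outcome column names; defaults to the
#'   numeric clinical columns that are not controls or T2 columns.
#' @param t2_suffix Suffix marking follow-up columns; an outcome `o` with a
#'   companion `o<t2_suffix>` enters the partial-correlation block.
#' @param group_vars Categorical columns for t-tests (two-level).
#' @param control_vars Nuisance columns for the control screen.
#' @param var_equal Passed to [coherence_t_test()].
#' @return A named list of tibbles (see above) plus `joined`, the merged
#'   analysis table. Participants present in only one input are reported in
#'   `join_mismatches`, not silently dropped.
#' @export
validation_report <- function(scores, clinical,
                              outcomes = NULL,
                              t2_suffix = "_t2",
                              group_vars = intersect(c("sex", "medication"),
                                                     names(clinical)),
                              control_vars = intersect(
                                c("age", "education_years", "verbal_iq",
                                  "words"),
                                c(names(clinical), names(scores))),
                              var_equal = FALSE) {
  stopifnot("participant_id" %in% names(scores),
            "participant_id" %in% names(clinical))
  score_cols <- grep("_(local|global)$", names(scores), value = TRUE)
  if (!length(score_cols)) stop("no *_local / *_global score columns found",
                                call. = FALSE)
  only_scores <- setdiff(scores$participant_id, clinical$participant_id)
  only_clin <- setdiff(clinical$participant_id, scores$participant_id)
  joined <- dplyr::inner_join(scores, clinical, by = "participant_id")
  if (is.null(outcomes)) {
    num <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
    outcomes <- setdiff(num, c("participant_id", control_vars, group_vars,
                               grep(paste0(t2_suffix, "$"), names(clinical),
                                    value = TRUE)))
  }
  t2_pairs <- outcomes[paste0(outcomes, t2_suffix) %in% names(clinical)]

  partial <- dplyr::bind_rows(lapply(t2_pairs, function(o) {
    tryCatch(
      cor_table(joined, score_cols, paste0(o, t2_suffix), controls = o),
      error = function(e) tibble::tibble(
        variable_x = score_cols, variable_y = paste0(o, t2_suffix),
        r = NA_real_, n = sum(stats::complete.cases(
          joined[[o]], joined[[paste0(o, t2_suffix)]])),
        p = NA_real_, controls = o))
  }))

  t_tests <- dplyr::bind_rows(lapply(group_vars, function(g) {
    lv <- sort(unique(stats::na.omit(joined[[g]])))
    if (length(lv) != 2L) return(NULL)
    dplyr::bind_rows(lapply(score_cols, function(sc) {
      id <- tibble::tibble(score = sc, group = g,
                           level_a = as.character(lv[1]),
                           level_b = as.character(lv[2]))
      res <- tryCatch(
        coherence_t_test(joined[[sc]][joined[[g]] %in% lv[1]],
                         joined[[sc]][joined[[g]] %in% lv[2]],
                         var_equal = var_equal),
        # undersized or degenerate group: report the cell as missing
        error = function(e) tibble::tibble(
          t = NA_real_, df = NA_real_, p = NA_real_,
          mean_a = NA_real_, mean_b = NA_real_,
          n_a = sum(joined[[g]] %in% lv[1] & !is.na(joined[[sc]])),
          n_b = sum(joined[[g]] %in% lv[2] & !is.na(joined[[sc]]))))
      dplyr::bind_cols(id, res)
    }))
  }))

  list(
    score_score = cor_table(joined, score_cols, score_cols),
    score_outcome = cor_table(joined, score_cols, outcomes),
    partial = partial,
    t_tests = t_tests,
    control_screen = cor_table(joined, score_cols,
                               intersect(control_vars, names(joined))),
    joined = joined,
    join_mismatches = tibble::tibble(
      participant_id = c(only_scores, only_clin),
      present_in = rep(c("scores", "clinical"),
                       c(length(only_scores), length(only_clin))))
  )
}
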