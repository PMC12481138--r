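# Session-level statistics: questionnaire scoring, half-comparison of
# exercise errors with false-discovery-rate control, and the
# repeated-measures ANOVA machinery for motivation scales.

#' Score the System Usability Scale
#'
#' Standard SUS scoring: odd (positively worded) items contribute
#' `response - 1`, even (negatively worded) items `5 - response`, and the
#' sum is scaled by 2.5 to a 0-100 range.
#'
#' @param items Exactly 10 responses, each in 1-5, in questionnaire order.
#' @return Score in 0-100.
#' @examples
#' sus_score(rep(c(5, 1), 5))  # ceiling: 100
#' @export
sus_score <- function(items) {
  if (length(items) != 10) {
    abort("SUS requires exactly 10 items", class = "pitchcoach_bad_items")
  }
  if (any(items < 1 | items > 5)) {
    abort("SUS responses must lie in 1..5", class = "pitchcoach_bad_items")
  }
  odd <- items[c(1, 3, 5, 7, 9)]
  even <- items[c(2, 4, 6, 8, 10)]
  (sum(odd - 1) + sum(5 - even)) * 2.5
}

#' Default IMI item-to-scale mapping
#'
#' Two consecutive items per scale, no reversals. The instrument's exact
#' item order is configurable because published short forms vary; reversed
#' items score as `8 - response`.
#'
#' @return A named list of integer item indices with a `reversed` attribute.
#' @export
imi_default_mapping <- function() {
  m <- list(interest_enjoyment = c(1L, 2L),
            effort_importance = c(3L, 4L),
            perceived_competence = c(5L, 6L),
            pressure_tension = c(7L, 8L))
  attr(m, "reversed") <- integer(0)
  m
}

#' Score the 8-item Intrinsic Motivation Inventory
#'
#' Four scales of two items each (interest/enjoyment, effort/importance,
#' perceived competence, pressure/tension); each scale is the sum of its
#' items after any configured reversal, so scores range 2-14.
#'
#' @param items Exactly 8 responses in 1-7.
#' @param mapping Item-to-scale mapping as from [imi_default_mapping()].
#' @return A named numeric vector of the 4 scale scores.
#' @export
imi_scores <- function(items, mapping = imi_default_mapping()) {
  if (length(items) != 8) {
    abort("this IMI form requires exactly 8 items",
          class = "pitchcoach_bad_items")
  }
  if (any(items < 1 | items > 7)) {
    abort("IMI responses must lie in 1..7", class = "pitchcoach_bad_items")
  }
  idx <- sort(unlist(mapping))
  if (!identical(as.integer(idx), 1:8)) {
    abort("mapping must assign each of the 8 items to exactly one scale",
          class = "pitchcoach_bad_items")
  }
  rev_idx <- attr(mapping, "reversed") %||% integer(0)
  scored <- items
  scored[rev_idx] <- 8 - scored[rev_idx]
  vapply(mapping, function(i) sum(scored[i]), numeric(1))
}

# test-result container --------------------------------------------------

stat_result <- function(method, statistic, df, p, n,
                        estimate = NA_real_, alpha = 0.05) {
  new_tibble(
    list(method = method, statistic = statistic, df = df,
         p.value = p, estimate = estimate, n = n,
         significant = !is.na(p) & p < alpha),
    nrow = 1L)
}

#' Compare first-half and second-half exercise errors
#'
#' Each participant's mean error over repetitions 1-5 is paired with their
#' mean over repetitions 6-10. If the paired differences pass a
#' Shapiro-Wilk normality check (alpha = .05) a two-tailed paired t test is
#' used, otherwise a Wilcoxon signed-rank test. Differences that are all
#' zero return statistic 0 and p = 1 by convention; nonzero differences
#' with zero variance fall through to the signed-rank branch (the t
#' statistic is undefined there).
#'
#' @param errors A tibble with columns `participant`, `repetition` (1-10)
#'   and `exercise_error`, or an `n x 10` matrix (rows = participants).
#' @param alpha Significance level (default .05, also the normality-gate
#'   level).
#' @return A one-row tibble: `method`, `statistic`, `df`, `p.value`,
#'   `estimate` (mean first-half minus second-half difference), `n`,
#'   `significant`.
#' @export
compare_halves <- function(errors, alpha = 0.05) {
  if (is.matrix(errors)) {
    stopifnot(ncol(errors) == 10)
    first <- rowMeans(errors[, 1:5, drop = FALSE])
    second <- rowMeans(errors[, 6:10, drop = FALSE])
  } else {
    errors <- as_tibble(errors)
    halves <- errors |>
      dplyr::filter(!is.na(.data$exercise_error)) |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(
        first = mean(.data$exercise_error[.data$repetition <= 5]),
        second = mean(.data$exercise_error[.data$repetition > 5]),
        .groups = "drop")
    first <- halves$first
    second <- halves$second
  }
  ok <- is.finite(first) & is.finite(second)
  first <- first[ok]; second <- second[ok]
  n <- length(first)
  if (n < 3) {
    abort("need at least 3 participants with complete halves",
          class = "pitchcoach_too_few")
  }
  d <- first - second
  if (all(d == 0)) {
    return(stat_result("paired-t", 0, n - 1, 1, n, estimate = 0,
                       alpha = alpha))
  }
  normal <- sd(d) > 0 && shapiro.test(d)$p.value >= 0.05
  if (normal) {
    tt <- t.test(first, second, paired = TRUE)
    stat_result("paired-t", unname(tt$statistic), unname(tt$parameter),
                tt$p.value, n, estimate = mean(d), alpha = alpha)
  } else {
    wt <- suppressWarnings(wilcox.test(first, second, paired = TRUE))
    stat_result("signed-rank", unname(wt$statistic), NA_real_, wt$p.value,
                n, estimate = mean(d), alpha = alpha)
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up procedure: adjusted p values via
#' [stats::p.adjust]`(method = "BH")`, rejections where the adjusted value
#' is at most `alpha`.
#'
#' @param pvals P values in `[0, 1]`.
#' @param alpha Base FDR level (default .05).
#' @return A tibble with `p.value`, `p.adjusted`, `rejected`, in input
#'   order.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    abort("p values must lie in [0, 1]", class = "pitchcoach_bad_p")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  tibble(p.value = pvals, p.adjusted = adj, rejected = adj <= alpha)
}

#' One-sample t test against a benchmark
#'
#' Two-tailed, `t = (mean - mu) / (sd / sqrt(n))` on `n - 1` degrees of
#' freedom — used to compare SUS scores against the acceptability benchmark
#' of 70.
#'
#' @param values Sample values (n >= 2, nonzero variance).
#' @param mu Benchmark value.
#' @param alpha Significance level.
#' @return A one-row result tibble as in [compare_halves()].
#' @export
one_sample_test <- function(values, mu, alpha = 0.05) {
  if (length(values) < 2) {
    abort("need at least 2 values", class = "pitchcoach_too_few")
  }
  if (sd(values) == 0) {
    abort("zero variance: one-sample t is undefined",
          class = "pitchcoach_degenerate")
  }
  tt <- t.test(values, mu = mu)
  stat_result("one-sample-t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, length(values), estimate = mean(values) - mu,
              alpha = alpha)
}

#' One-way repeated-measures ANOVA
#'
#' Within-subjects F test comparing `k` conditions measured on the same
#' `n` participants: the subject effect is removed from the error term and
#' `F = MS_condition / MS_error` on `(k - 1, (n - 1)(k - 1))` degrees of
#' freedom. No sphericity correction is applied.
#'
#' @param table An `n x k` numeric matrix (rows = participants, columns =
#'   conditions) or a tibble with columns `participant`, `condition`,
#'   `value`.
#' @param alpha Significance level.
#' @return A one-row result tibble; `df` holds the numerator df and a
#'   `df2` column the denominator df.
#' @export
rm_anova <- function(table, alpha = 0.05) {
  if (!is.matrix(table)) {
    table <- as_tibble(table) |>
      tidyr::pivot_wider(id_cols = "participant", names_from = "condition",
                         values_from = "value") |>
      dplyr::select(-"participant") |>
      as.matrix()
  }
  if (anyNA(table)) {
    abort("repeated-measures ANOVA requires a complete table",
          class = "pitchcoach_bad_dataset")
  }
  n <- nrow(table); k <- ncol(table)
  if (n < 3 || k < 2) {
    abort("need >= 3 participants and >= 2 conditions",
          class = "pitchcoach_too_few")
  }
  grand <- mean(table)
  ss_subj <- k * sum((rowMeans(table) - grand)^2)
  ss_cond <- n * sum((colMeans(table) - grand)^2)
  ss_tot <- sum((table - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_err <- ss_err / df2
  f <- if (ms_err <= 0) {
    if (ss_cond <= 1e-12) 0 else Inf
  } else {
    (ss_cond / df1) / ms_err
  }
  p <- if (f == 0) 1 else pf(f, df1, df2, lower.tail = FALSE)
  out <- stat_result("rm-anova", f, df1, p, n, alpha = alpha)
  out$df2 <- df2
  out
}

#' Holm-Sidak step-down adjustment
#'
#' For ascending-sorted p values `p(1) <= ... <= p(m)`,
#' `adjusted(i) = max over j <= i of 1 - (1 - p(j))^(m - j + 1)`, capped at
#' 1, returned in the input order.
#'
#' @param pvals P values in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
holm_sidak <- function(pvals) {
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    abort("p values must lie in [0, 1]", class = "pitchcoach_bad_p")
  }
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  sorted <- pvals[o]
  adj <- pmin(cummax(1 - (1 - sorted)^(m - seq_len(m) + 1)), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# session summary --------------------------------------------------------

#' Summarize a session dataset
#'
#' The machine twin of the evaluation's results tables: per exercise, the
#' mean (SD) across participants of the first-half and second-half mean
#' errors, the half-comparison test, and Benjamini-Hochberg flags across
#' the exercises; plus SUS (with the benchmark test against 70) and IMI
#' scale summaries when questionnaire items are present.
#'
#' @param data A [session_dataset()].
#' @param alpha Base significance / FDR level (default .05).
#' @param sus_benchmark Benchmark SUS score (default 70).
#' @return A `session_summary` object: list with tibbles `errors`, and
#'   optionally `sus`, `sus_test`, `imi`.
#' @export
summarize_session <- function(data, alpha = 0.05, sus_benchmark = 70) {
  stopifnot(inherits(data, "session_dataset"))
  if (nrow(data$errors) == 0) {
    abort("empty session dataset", class = "pitchcoach_bad_dataset")
  }
  err <- data$errors |> dplyr::filter(!.data$excluded)
  halves <- err |>
    dplyr::group_by(.data$exercise, .data$participant) |>
    dplyr::summarise(
      first = mean(.data$exercise_error[.data$repetition <= 5]),
      second = mean(.data$exercise_error[.data$repetition > 5]),
      .groups = "drop")
  per_ex <- halves |>
    dplyr::group_by(.data$exercise) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_first = mean(.data$first), sd_first = sd(.data$first),
      mean_second = mean(.data$second), sd_second = sd(.data$second),
      .groups = "drop")
  tests <- err |>
    dplyr::group_by(.data$exercise) |>
    dplyr::group_modify(~ compare_halves(.x, alpha = alpha)) |>
    dplyr::ungroup()
  bh <- bh_adjust(tests$p.value, alpha = alpha)
  errors_tbl <- per_ex |>
    dplyr::left_join(
      tests |> dplyr::select("exercise", "method", "statistic", "p.value"),
      by = "exercise") |>
    dplyr::mutate(p.adjusted = bh$p.adjusted, significant = bh$rejected) |>
    # preserve battery order rather than alphabetical
    dplyr::arrange(match(.data$exercise, unique(err$exercise)))

  out <- list(errors = errors_tbl, alpha = alpha)
  if (!is.null(data$sus)) {
    scores <- data$sus |>
      dplyr::arrange(.data$participant, .data$item) |>
      dplyr::group_by(.data$participant) |>
      dplyr::summarise(score = sus_score(.data$response), .groups = "drop")
    out$sus <- tibble(mean = mean(scores$score), sd = sd(scores$score),
                      n = nrow(scores))
    out$sus_test <- one_sample_test(scores$score, sus_benchmark,
                                    alpha = alpha)
  }
  if (!is.null(data$imi)) {
    out$imi <- data$imi |>
      dplyr::arrange(.data$participant, .data$exercise_type, .data$item) |>
      dplyr::group_by(.data$participant, .data$exercise_type) |>
      dplyr::group_modify(~ {
        s <- imi_scores(.x$response)
        tibble(scale = names(s), score = unname(s))
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$scale, .data$exercise_type) |>
      dplyr::summarise(mean = mean(.data$score), sd = sd(.data$score),
                       n = dplyr::n(), .groups = "drop")
  }
  structure(out, class = "session_summary")
}

#' @export
print.session_summary <- function(x, digits = 3, ...) {
  cat("Exercise errors, first vs second 5 repetitions (Hz)\n")
  tab <- x$errors |>
    dplyr::mutate(
      `first 5` = sprintf("%.1f (%.1f)", .data$mean_first, .data$sd_first),
      `second 5` = sprintf("%.1f (%.1f)", .data$mean_second, .data$sd_second),
      p = signif(.data$p.value, 2),
      sig = ifelse(.data$significant, "*", "")) |>
    dplyr::select("exercise", "first 5", "second 5", "method", "p", "sig")
  print(as.data.frame(tab), row.names = FALSE)
  if (!is.null(x$sus)) {
    cat(sprintf("\nSUS: mean %.1f (SD %.1f), n = %d; vs benchmark: t = %.2f, p = %.3g\n",
                x$sus$mean, x$sus$sd, x$sus$n,
                x$sus_test$statistic, x$sus_test$p.value))
  }
  if (!is.null(x$imi)) {
    cat("\nIMI scale means (2-14) by exercise type\n")
    wide <- x$imi |>
      dplyr::mutate(cell = sprintf("%.1f (%.1f)", .data$mean, .data$sd)) |>
      tidyr::pivot_wider(id_cols = "scale", names_from = "exercise_type",
                         values_from = "cell")
    print(as.data.frame(wide), row.names = FALSE)
  }
  invisible(x)
}
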