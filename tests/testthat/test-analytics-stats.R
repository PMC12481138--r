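test_that("SUS scoring matches the standard formula", {
  expect_equal(sus_score(rep(c(5, 1), 5)), 100)
  expect_equal(sus_score(rep(3, 10)), 50)
  expect_equal(sus_score(c(4, 2, 4, 2, 4, 2, 4, 2, 4, 2)), 75)
  expect_equal(sus_score(rep(c(1, 5), 5)), 0)
  expect_error(sus_score(rep(3, 9)), class = "pitchcoach_bad_items")
  expect_error(sus_score(c(rep(3, 9), 6)), class = "pitchcoach_bad_items")
})

test_that("IMI scales sum item pairs with optional reversal", {
  expect_equal(unname(imi_scores(rep(7, 8))), rep(14, 4))
  expect_equal(unname(imi_scores(rep(1, 8))), rep(2, 4))
  m <- imi_default_mapping()
  attr(m, "reversed") <- 2L
  s <- imi_scores(rep(7, 8), m)
  expect_equal(unname(s["interest_enjoyment"]), 7 + (8 - 7))
  expect_equal(unname(s["effort_importance"]), 14)
  expect_error(imi_scores(rep(7, 7)), class = "pitchcoach_bad_items")
  bad <- imi_default_mapping()
  bad$interest_enjoyment <- c(1L, 1L)
  expect_error(imi_scores(rep(4, 8), bad), class = "pitchcoach_bad_items")
})

test_that("questionnaire scores are affine in each item", {
  base <- rep(3, 10)
  s0 <- sus_score(base)
  for (i in 1:10) {
    x <- base
    x[i] <- 4
    d <- sus_score(x) - s0
    expect_equal(abs(d), 2.5)                  # +2.5 odd, -2.5 even
    expect_equal(d, if (i %% 2 == 1) 2.5 else -2.5)
  }
  b <- rep(4, 8)
  i0 <- imi_scores(b)
  for (i in 1:8) {
    x <- b
    x[i] <- 5
    expect_equal(sum(imi_scores(x) - i0), 1)
  }
})

test_that("half comparison gates on normality and handles degeneracy", {
  # identical halves: p = 1 convention
  errs <- matrix(rep(1:21, each = 10), ncol = 10, byrow = TRUE)
  res <- compare_halves(errs)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # constant nonzero difference: zero variance falls to the signed-rank branch
  m <- cbind(matrix(c(10, 12, 14), 3, 5), matrix(c(8, 10, 12), 3, 5))
  res <- compare_halves(m)
  expect_equal(res$method, "signed-rank")
  expect_true(is.finite(res$p.value))
  # normally distributed differences reproduce the closed-form t statistic
  withr::with_seed(4, {
    first <- rnorm(21, 10, 2)
    second <- first - rnorm(21, 1, 0.8)
  })
  res <- compare_halves(cbind(matrix(first, 21, 5), matrix(second, 21, 5)))
  d <- first - second
  expect_equal(res$method, "paired-t")
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(21)), tolerance = 1e-9)
  expect_equal(res$df, 20)
  # long-format input agrees with the matrix input
  tbl <- tibble::tibble(
    participant = rep(1:21, each = 10),
    repetition = rep(1:10, 21),
    exercise_error = as.vector(t(cbind(matrix(first, 21, 5),
                                       matrix(second, 21, 5)))))
  expect_equal(compare_halves(tbl)$statistic, res$statistic)
  expect_error(compare_halves(matrix(1:20, 2, 10)),
               class = "pitchcoach_too_few")
})

test_that("BH adjustment equals a brute-force step-up scan", {
  brute_bh <- function(p, alpha = 0.05) {
    m <- length(p)
    s <- sort(p)
    k <- max(c(0, which(s <= (1:m) / m * alpha)))
    p <= if (k == 0) -1 else s[k]
  }
  withr::with_seed(7, {
    for (i in 1:1000) {
      p <- runif(sample(1:12, 1))^sample(1:3, 1)
      expect_identical(bh_adjust(p)$rejected, brute_bh(p))
    }
  })
  expect_equal(sum(bh_adjust(rep(1, 5))$rejected), 0)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "pitchcoach_bad_p")
})

test_that("multiplicity procedures are correctly ordered in strictness", {
  withr::with_seed(8, {
    for (i in 1:200) {
      p <- runif(7)^2
      bh <- bh_adjust(p)$rejected
      bonf <- p <= 0.05 / 7
      raw <- p <= 0.05
      expect_true(all(bh[bonf]))               # BH superset of Bonferroni
      expect_true(all(raw[bh]))                # BH subset of unadjusted
      expect_true(all(diff(sort(bh_adjust(p)$p.adjusted)) >= -1e-12))
      expect_true(all(diff(sort(holm_sidak(p))) >= -1e-12))
    }
  })
})

test_that("one-sample t test matches its closed form and distribution", {
  res <- one_sample_test(c(69, 70, 71), 70)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  res <- one_sample_test(c(1, 2, 3), 0)
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$df, 2)
  withr::with_seed(3, x <- rnorm(21, 75, 10))
  res <- one_sample_test(x, 70)
  t_manual <- (mean(x) - 70) / (sd(x) / sqrt(21))
  expect_equal(res$statistic, t_manual, tolerance = 1e-9)
  expect_equal(res$p.value, 2 * pt(abs(t_manual), 20, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_error(one_sample_test(rep(5, 4), 3),
               class = "pitchcoach_degenerate")
})

test_that("repeated-measures ANOVA partitions sums of squares correctly", {
  # identical conditions per subject: F = 0, p = 1
  tab <- matrix(rep(c(3, 5, 9, 7), 4), 4, 4)
  res <- rm_anova(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # two conditions: F equals the squared paired-t statistic
  withr::with_seed(5, {
    a <- rnorm(12, 10, 3)
    b <- a + rnorm(12, 1, 1)
  })
  f <- rm_anova(cbind(a, b))
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(f$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(f$p.value, tt$p.value, tolerance = 1e-9)
  # 4 x 5 table: cross-check against aov with an Error(subject) stratum
  withr::with_seed(6, tab <- matrix(rnorm(20, 8, 2), 5, 4))
  res <- rm_anova(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(1:5, 4)),
                   cond = factor(rep(1:4, each = 5)))
  av <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  f_aov <- av[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(res$statistic, f_aov, tolerance = 1e-9)
  expect_equal(c(res$df, res$df2), c(3, 12))
  expect_error(rm_anova(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)),
               class = "pitchcoach_bad_dataset")
})

test_that("Holm-Sidak follows the step-down closed formula", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0, 0, 0)), c(0, 0, 0))
  p <- c(0.01, 0.03, 0.04)
  manual <- cummax(1 - (1 - p)^(3:1))
  expect_equal(holm_sidak(p), manual, tolerance = 1e-12)
  # order-independence: adjustment commutes with permutation
  withr::with_seed(9, {
    for (i in 1:50) {
      p <- runif(6)
      perm <- sample(6)
      expect_equal(holm_sidak(p)[perm], holm_sidak(p[perm]),
                   tolerance = 1e-12)
    }
  })
  expect_error(holm_sidak(c(-0.1, 0.5)), class = "pitchcoach_bad_p")
})

test_that("session summaries are deterministic and zero under zero noise", {
  ds <- generate_session(
    n_participants = 5,
    population = function(seed) noiseless_user(seed = seed),
    seed = 77)
  s <- summarize_session(ds)
  expect_true(all(s$errors$mean_first == 0))
  expect_true(all(s$errors$sd_second == 0))
  expect_true(all(s$errors$p.value == 1))
  expect_equal(sum(s$errors$significant), 0)
  # pure function of the dataset / seed
  ds2 <- generate_session(
    n_participants = 5,
    population = function(seed) noiseless_user(seed = seed),
    seed = 77)
  expect_identical(ds$errors, ds2$errors)
  expect_identical(ds$sus, ds2$sus)
  expect_equal(tidy(summarize_session(ds2)), tidy(s))
  expect_error(
    summarize_session(session_dataset(ds$errors[0, ])),
    class = "pitchcoach_bad_dataset")
})

test_that("tidiers expose the summary tables", {
  ds <- generate_session(n_participants = 6, seed = 12)
  s <- summarize_session(ds)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$exercise, unique(ds$errors$exercise))
  gl <- glance(s)
  expect_equal(gl$n_exercises, 7)
  expect_equal(gl$n_participants, 6)
  expect_true(gl$sus_mean > 0 && gl$sus_mean <= 100)
  p <- autoplot(s)
  expect_s3_class(p, "ggplot")
  trk <- simulate_user_track(stair_target(), simulated_user(seed = 2))
  expect_s3_class(autoplot(trk, target = stair_target()), "ggplot")
})
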