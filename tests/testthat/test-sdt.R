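test_that("count tallies cross responses with labels and foil subsets", {
  d <- fx_d2n()
  tr <- d$trials
  # perfect responder: yes iff the trial is labelled correct
  test <- test_trials(d)
  log <- data.frame(participant_id = "p", group = d$group, policy = "oracle",
                    position = seq_len(nrow(test)), trial_index = test$index,
                    answer = ifelse(test$label == "correct", "yes", "no"))
  expect_equal(unname(tally_counts(log, d)), c(120L, 0L, 0L, 120L))
  expect_equal(unname(tally_counts(log, d, restrict = "S2")),
               c(120L, 0L, 0L, 40L))
  # a first-pair strategist: all S2 foils become false alarms
  st <- simulate_strategist(d, "first")
  expect_equal(unname(tally_counts(st, d, restrict = "S2")),
               c(120L, 0L, 40L, 0L))
  expect_equal(unname(tally_counts(st, d, restrict = "S1")),
               c(120L, 0L, 0L, 40L))
  # misaligned logs error
  bad <- log
  bad$trial_index[1] <- 1e6L
  expect_error(tally_counts(bad, d), "not aligned")
})

test_that("corrected d-prime matches the normal-quantile oracle", {
  # equal corrected rates give exactly zero for any symmetric counts
  for (k in c(0, 3, 50)) {
    expect_equal(dprime(c(k, k, k, k))$d_prime, 0)
  }
  expect_equal(dprime(c(90, 30, 30, 90))$d_prime,
               qnorm(90.5 / 121) - qnorm(30.5 / 121), tolerance = 1e-12)
  expect_equal(dprime(c(120, 0, 0, 120))$d_prime,
               2 * qnorm(120.5 / 121), tolerance = 1e-12)
  expect_equal(dprime(c(120, 0, 0, 120))$d_prime, 5.279, tolerance = 1e-3)
  # criterion definition
  est <- dprime(c(90, 30, 10, 110))
  expect_equal(est$criterion,
               -(qnorm(90.5 / 121) + qnorm(10.5 / 121)) / 2,
               tolerance = 1e-12)
  expect_error(dprime(c(0, 0, 0, 0), cell_correction = 0), "undefined")
})

test_that("d-prime is antisymmetric under swapping response classes", {
  withr::with_seed(5, {
    for (i in 1:20) {
      cts <- sample(0:60, 4, replace = TRUE)
      a <- dprime(cts)$d_prime
      b <- dprime(cts[c(2, 1, 4, 3)])$d_prime
      expect_equal(a, -b, tolerance = 1e-12)
    }
  })
})

test_that("block and length partitions conserve the full tallies", {
  d1 <- fx_d1n(); d2 <- fx_d2n()
  expect_equal(block_sizes(d1), c(120L, 120L, 120L))
  expect_equal(block_sizes(d2), c(80L, 80L, 80L))
  log <- simulate_sdt_learner(d1, sensitivity = 1, seed = 9)
  total <- tally_counts(log, d1)
  blocks <- sdt_by_block(log, d1)
  expect_equal(Reduce(`+`, lapply(blocks, as.integer)),
               as.integer(total))
  expect_true(all(vapply(blocks, sum, numeric(1)) == 120))
  lens <- sdt_by_length(log, d1)
  expect_named(lens, c("short", "medium", "long"))
  expect_equal(Reduce(`+`, lapply(lens, as.integer)), as.integer(total))
  expect_true(all(vapply(lens, sum, numeric(1)) == 120))
})

test_that("one-sample t reports the textbook statistic and Cohen's d", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$cohens_d, 2)
  sym <- one_sample_t(c(-2, -1, 1, 2))
  expect_equal(sym$t, 0)
  expect_equal(sym$cohens_d, 0)
  expect_equal(one_sample_t(rnorm(15))$df, 14)
  expect_error(one_sample_t(rep(1, 5)), "zero variance")
})

test_that("independent t uses pooled variance and n1+n2-2 dfs", {
  a <- c(1, 2, 3, 4)
  r <- independent_t(a, a)
  expect_equal(r$t, 0)
  expect_equal(r$df, 6)
  withr::with_seed(2, {
    expect_equal(independent_t(rnorm(15), rnorm(15))$df, 28)
    expect_equal(independent_t(rnorm(20), rnorm(20))$df, 38)
  })
  expect_error(independent_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("mixed ANOVA agrees with the aov/car oracle to 1e-8", {
  for (seed in c(11, 22, 33)) {
    withr::with_seed(seed, {
      n <- 15; k <- 3
      y <- matrix(rnorm(2 * n * k), ncol = k)
      y[, 2] <- y[, 2] + rnorm(1)
      y[, 3] <- y[, 3] + rnorm(1)
      grp <- rep(c("g1", "g2"), each = n)
    })
    mine <- mixed_anova_gg(y, grp)
    # oracle 1: split-plot sums of squares via stats::aov
    df <- data.frame(y = as.vector(y),
                     subj = factor(rep(seq_len(2 * n), k)),
                     w = factor(rep(seq_len(k), each = 2 * n)),
                     g = factor(rep(grp, k)))
    fit <- summary(stats::aov(y ~ g * w + Error(subj / w), data = df))
    between_tab <- fit[["Error: subj"]][[1]]
    within_tab <- fit[["Error: subj:w"]][[1]]
    expect_equal(mine$SS[mine$effect == "between"], between_tab["g", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "between"], between_tab["g", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$SS[mine$effect == "within"], within_tab["w", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "within"], within_tab["w", "F value"],
                 tolerance = 1e-8)
    expect_equal(mine$SS[mine$effect == "interaction"],
                 within_tab["g:w", "Sum Sq"], tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "interaction"],
                 within_tab["g:w", "F value"], tolerance = 1e-8)
    # partial eta squared from the oracle's sums of squares
    expect_equal(mine$pes[mine$effect == "within"],
                 within_tab["w", "Sum Sq"] /
                   (within_tab["w", "Sum Sq"] +
                    within_tab["Residuals", "Sum Sq"]), tolerance = 1e-8)
    # oracle 2: Greenhouse-Geisser epsilon and corrected p via car
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    mlm <- stats::lm(y ~ grp)
    aa <- car::Anova(mlm, idata = data.frame(w = factor(seq_len(k))),
                     idesign = ~w, type = 3)
    s <- suppressWarnings(summary(aa, multivariate = FALSE))
    adj <- s$pval.adjustments
    expect_equal(unname(mine$eps[mine$effect == "within"]),
                 unname(adj["w", "GG eps"]), tolerance = 1e-8)
    expect_equal(unname(mine$p_gg[mine$effect == "within"]),
                 unname(adj["w", "Pr(>F[GG])"]), tolerance = 1e-8)
    expect_equal(unname(mine$p_gg[mine$effect == "interaction"]),
                 unname(adj["grp:w", "Pr(>F[GG])"]), tolerance = 1e-8)
  }
})

test_that("two within levels force epsilon 1; degenerate inputs give F 0", {
  withr::with_seed(4, {
    y <- matrix(rnorm(40), ncol = 2)
    grp <- rep(c("a", "b"), each = 10)
  })
  tab <- mixed_anova_gg(y, grp)
  expect_equal(tab$eps[tab$effect == "within"], 1)
  expect_equal(tab$df_gg[tab$effect == "within"], 1)
  flat <- matrix(1, nrow = 10, ncol = 3)
  tab0 <- mixed_anova_gg(flat, rep(c("a", "b"), each = 5))
  expect_equal(tab0$F, c(0, 0, 0))
  expect_equal(tab0$pes, c(0, 0, 0))
  expect_error(mixed_anova_gg(y, rep(c("a", "b"), c(12, 8))), "balanced")
})

test_that("binomial strategy diagnostics flag strategists, not abstainers", {
  d <- fx_d2n()
  st <- binomial_strategy_tests(simulate_strategist(d, "first"), d)
  expect_equal(unname(st$yes["S2"]), 40)
  expect_equal(unname(st$p["S2"]), 0.5^40, tolerance = 1e-6)
  expect_true(st$first_pair)
  expect_false(st$last_pair)
  last <- binomial_strategy_tests(simulate_strategist(d, "last"), d)
  expect_true(last$last_pair)
  expect_false(last$first_pair)
  # all-no responder: nothing significant, no flags
  test <- test_trials(d)
  none <- data.frame(participant_id = "p", group = d$group, policy = "mute",
                     position = seq_len(nrow(test)),
                     trial_index = test$index, answer = "no")
  res <- binomial_strategy_tests(none, d)
  expect_false(res$first_pair || res$last_pair)
  expect_true(all(res$p > 0.99))
  expect_error(binomial_strategy_tests(none, fx_d1n()), "experiment-2")
})
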