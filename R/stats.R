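#' One-sample t-test against a reference value, with Cohen's d
#'
#' Thin wrapper around [stats::t.test()] that also reports the
#' standardized effect size Cohen's d = mean(x - mu0) / sd(x), the
#' convention used when testing per-participant sensitivities against
#' chance (d' = 0).
#'
#' @param values Numeric vector (n >= 2, nonzero variance).
#' @param mu0 Null value (default 0).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  s <- stats::sd(values)
  if (s == 0) stop("zero variance", call. = FALSE)
  tt <- stats::t.test(values, mu = mu0)
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = (mean(values) - mu0) / s,
    mean = mean(values),
    sd = s,
    n = length(values)
  )
}

#' Independent-samples t-test (pooled variance)
#'
#' Classical two-sample t with pooled variance and df = n1 + n2 - 2 (so two
#' groups of 15 give df = 28, two of 20 give df = 38). Also reports Cohen's
#' d on the pooled standard deviation.
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @return List with `t`, `df`, `p`, `cohens_d`, `mean_a`, `mean_b`.
#' @export
independent_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  v <- stats::var(group_a) * (length(group_a) - 1) +
    stats::var(group_b) * (length(group_b) - 1)
  if (v == 0) stop("zero pooled variance", call. = FALSE)
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  sp <- sqrt(v / (length(group_a) + length(group_b) - 2))
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    cohens_d = (mean(group_a) - mean(group_b)) / sp,
    mean_a = mean(group_a),
    mean_b = mean(group_b)
  )
}

#' Mixed (split-plot) ANOVA with Greenhouse-Geisser correction
#'
#' Two-way mixed ANOVA for a design with one between-subjects factor (the
#' trained grammar) and one within-subjects factor with k levels (test
#' block or sequence length). Computes the classical split-plot sums of
#' squares, F ratios, partial eta squared
#' (SS_effect / (SS_effect + SS_error)), and — for k >= 3 — the
#' Greenhouse-Geisser epsilon from the pooled within-group covariance of
#' the repeated measures. Corrected degrees of freedom are epsilon * df
#' (this is how fractional dfs such as F(1.30, 36.46) arise); the
#' uncorrected dfs and p are reported alongside. With k = 2 sphericity is
#' vacuous and epsilon = 1 exactly.
#'
#' Degenerate effects with SS ~ 0 (e.g. all cells equal) are reported as
#' F = 0, p = 1, partial eta squared = 0.
#'
#' @param d_matrix Numeric matrix, participants x within-factor levels.
#' @param between Factor (or vector) of group labels, one per participant;
#'   groups must be balanced.
#' @return Data frame with one row per effect (`between`, `within`,
#'   `interaction`) and columns `SS`, `df`, `df_error`, `F`, `p`,
#'   `pes` (partial eta squared), `eps` (GG epsilon), `df_gg`,
#'   `df_error_gg`, `p_gg`.
#' @export
mixed_anova_gg <- function(d_matrix, between) {
  d_matrix <- as.matrix(d_matrix)
  between <- factor(between)
  if (nrow(d_matrix) != length(between)) {
    stop("`between` must have one label per row of `d_matrix`",
         call. = FALSE)
  }
  if (length(table(between)) < 2L || length(unique(table(between))) != 1L) {
    stop("between-subjects groups must be balanced (>= 2 groups, equal n)",
         call. = FALSE)
  }
  a <- nlevels(between)
  n <- unname(table(between)[1])
  k <- ncol(d_matrix)
  if (k < 2L) stop("need >= 2 within-factor levels", call. = FALSE)
  big_n <- a * n

  grand <- mean(d_matrix)
  subj_means <- rowMeans(d_matrix)
  col_means <- colMeans(d_matrix)
  grp_means <- tapply(subj_means, between, mean)
  cell_means <- apply(d_matrix, 2, function(col) tapply(col, between, mean))
  cell_means <- matrix(cell_means, nrow = a)  # a x k

  ss_total <- sum((d_matrix - grand)^2)
  ss_between <- k * n * sum((grp_means - grand)^2)
  ss_subj <- k * sum((subj_means - grp_means[between])^2)
  ss_within <- big_n * sum((col_means - grand)^2)
  ss_cells <- n * sum((cell_means - grand)^2)
  ss_inter <- ss_cells - ss_between - ss_within
  ss_err <- ss_total - ss_between - ss_subj - ss_within - ss_inter

  df_between <- a - 1
  df_subj <- a * (n - 1)
  df_within <- k - 1
  df_inter <- (a - 1) * (k - 1)
  df_err <- df_subj * (k - 1)

  ## GG epsilon from the pooled within-group covariance of the k measures
  eps <- 1
  if (k >= 3L) {
    s_pool <- matrix(0, k, k)
    for (g in levels(between)) {
      rows <- d_matrix[between == g, , drop = FALSE]
      s_pool <- s_pool + (nrow(rows) - 1) * stats::cov(rows)
    }
    s_pool <- s_pool / (big_n - a)
    cm <- stats::contr.helmert(k)
    cm <- sweep(cm, 2, sqrt(colSums(cm^2)), "/")  # orthonormal columns
    e <- t(cm) %*% s_pool %*% cm
    denom <- (k - 1) * sum(e^2)
    eps <- if (denom > 0) sum(diag(e))^2 / denom else 1
    eps <- min(1, max(1 / (k - 1), eps))
  }

  f_row <- function(effect, ss_eff, df_eff, ss_error, df_error,
                    gg = FALSE) {
    tiny <- 1e-12
    if (ss_eff < tiny) {
      fv <- 0
      p <- 1
      pes <- 0
      p_gg <- 1
    } else {
      fv <- (ss_eff / df_eff) / (ss_error / df_error)
      p <- stats::pf(fv, df_eff, df_error, lower.tail = FALSE)
      pes <- ss_eff / (ss_eff + ss_error)
      p_gg <- if (gg) {
        stats::pf(fv, eps * df_eff, eps * df_error, lower.tail = FALSE)
      } else {
        p
      }
    }
    data.frame(
      effect = effect, SS = ss_eff, df = df_eff, df_error = df_error,
      F = fv, p = p, pes = pes,
      eps = if (gg) eps else NA_real_,
      df_gg = if (gg) eps * df_eff else NA_real_,
      df_error_gg = if (gg) eps * df_error else NA_real_,
      p_gg = if (gg) p_gg else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    f_row("between", ss_between, df_between, ss_subj, df_subj),
    f_row("within", ss_within, df_within, ss_err, df_err, gg = TRUE),
    f_row("interaction", ss_inter, df_inter, ss_err, df_err, gg = TRUE)
  )
  rownames(out) <- NULL
  out
}

#' Per-participant exact binomial strategy diagnostics
#'
#' For each Experiment-2 foil subset, tests whether the participant said
#' yes more often than chance (exact binomial, one-sided toward excess
#' yes, null probability 0.5). S1 (other-grammar foils) indexes a general
#' yes bias; S2 (first-pair-preserving foils) indexes the
#' first-element-pair strategy; S3 the last-element-pair strategy. A
#' participant is flagged for a strategy iff the corresponding subset test
#' is significant while the S1 yes-bias test is not — a significant S1
#' result means excess yes responses cannot be attributed to a pair
#' strategy.
#'
#' @param log Single-participant response log on an Experiment-2 design.
#' @param design The `agl_design` (experiment 2).
#' @param alpha Significance level (default 0.05).
#' @return List with per-subset `yes`, `n`, `p` vectors and logical flags
#'   `first_pair` and `last_pair`.
#' @export
binomial_strategy_tests <- function(log, design, alpha = 0.05) {
  stopifnot(inherits(design, "agl_design"))
  if (design$experiment != 2) {
    stop("strategy diagnostics require an experiment-2 design",
         call. = FALSE)
  }
  tr <- design$trials
  m <- match(log$trial_index, tr$index)
  subset <- tr$foil_subset[m]
  yes <- log$answer == "yes"
  res <- lapply(c(S1 = "S1", S2 = "S2", S3 = "S3"), function(s) {
    rows <- which(subset == s)
    if (length(rows) == 0L) {
      stop("no responses for foil subset ", s, call. = FALSE)
    }
    k <- sum(yes[rows])
    list(yes = k, n = length(rows),
         p = stats::binom.test(k, length(rows), 0.5,
                               alternative = "greater")$p.value)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  list(
    yes = vapply(res, `[[`, numeric(1), "yes"),
    n = vapply(res, `[[`, numeric(1), "n"),
    p = p,
    alpha = alpha,
    first_pair = unname(p["S2"] < alpha && p["S1"] >= alpha),
    last_pair = unname(p["S3"] < alpha && p["S1"] >= alpha)
  )
}
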