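#' @keywords internal
.new_response_log <- function(participant_id, group, policy, positions,
                              trial_index, answer) {
  data.frame(
    participant_id = participant_id,
    group = group,
    policy = policy,
    position = positions,
    trial_index = trial_index,
    answer = ifelse(answer, "yes", "no"),
    stringsAsFactors = FALSE
  )
}

# Resolve the presentation order of the test phase for one participant:
# either the design's stored order or an explicit permutation of test
# trial indices.
.presentation <- function(design, order = NULL) {
  test <- test_trials(design)
  if (!is.null(order)) {
    if (!setequal(order, test$index) || anyDuplicated(order)) {
      stop("`order` must be a permutation of the design's test trial indices",
           call. = FALSE)
    }
    test <- test[match(order, test$index), , drop = FALSE]
  }
  test
}

#' Simulate an equal-variance Gaussian signal-detection responder
#'
#' The generative model matches the d-prime estimator used by the analysis:
#' on a correct trial the observer says yes with probability
#' `pnorm(sensitivity / 2 - criterion)`, on an incorrect trial with
#' probability `pnorm(-sensitivity / 2 - criterion)`, independently across
#' trials. `sensitivity` is the process d-prime; `criterion` > 0 biases
#' toward no, < 0 toward yes. A nonzero `learning_slope` raises sensitivity
#' by that amount per test block (thirds of the presentation order),
#' emulating continued learning across the test phase.
#'
#' @param design An `agl_design`.
#' @param sensitivity Generating d-prime (>= 0).
#' @param criterion Response criterion.
#' @param learning_slope Additive sensitivity increment per block
#'   (default 0: flat).
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the log.
#' @param order Optional permutation of test trial indices (presentation
#'   order); defaults to the design's stored order.
#' @return A response-log data frame with columns `participant_id`, `group`,
#'   `policy`, `position`, `trial_index`, `answer`.
#' @export
simulate_sdt_learner <- function(design, sensitivity = 1, criterion = 0,
                                 learning_slope = 0, seed = 1L,
                                 participant_id = "sdt_1", order = NULL) {
  stopifnot(inherits(design, "agl_design"))
  if (sensitivity < 0) stop("`sensitivity` must be >= 0", call. = FALSE)
  test <- .presentation(design, order)
  n <- nrow(test)
  block <- ceiling(seq_len(n) / (n / 3))
  d_b <- sensitivity + learning_slope * (block - 1)
  signed <- ifelse(test$label == "correct", d_b / 2, -d_b / 2)
  p_yes <- stats::pnorm(signed - criterion)
  yes <- withr::with_seed(seed, stats::runif(n) < p_yes)
  .new_response_log(participant_id, design$group, "sdt_learner",
                    seq_len(n), test$index, yes)
}

#' Simulate a deterministic single-pair strategist
#'
#' Responds yes iff the inspected dependency pair of the trained grammar is
#' intact in the trial's sequence, ignoring everything else. `"first"`
#' inspects the trained grammar's first dependency link (outermost for
#' nested, leftmost for cross-serial); `"last"` its last link. On the
#' Experiment-1 design this shortcut achieves perfect accuracy — the leak
#' the Experiment-2 foil subsets were built to close.
#'
#' @param design An `agl_design`.
#' @param which `"first"` or `"last"`.
#' @param participant_id Identifier stored in the log.
#' @param order Optional presentation order (permutation of test indices).
#' @param lexicon Lexicon table.
#' @return A response-log data frame.
#' @export
simulate_strategist <- function(design, which = c("first", "last"),
                                participant_id = "strategist_1",
                                order = NULL, lexicon = agl_lexicon()) {
  stopifnot(inherits(design, "agl_design"))
  which <- match.arg(which)
  test <- .presentation(design, order)
  seq_lists <- strsplit(test$sequence, " ", fixed = TRUE)
  yes <- vapply(seq_lists, function(s) {
    n <- length(s) %/% 2L
    ds <- dependency_structure(n, design$group)
    link <- if (which == "first") ds[1, ] else ds[n, ]
    .link_intact(s, link, lexicon)
  }, logical(1))
  policy <- paste0(which, "_pair_strategist")
  .new_response_log(participant_id, design$group, policy,
                    seq_len(nrow(test)), test$index, yes)
}

#' Simulate a (possibly yes-biased) guesser
#'
#' Answers yes with fixed probability `yes_rate` on every trial,
#' independent of content. With `yes_rate = 0.5` this is the chance-level
#' null model: its expected corrected d-prime is 0; biased rates shift the
#' criterion but not the expected d-prime.
#'
#' @param design An `agl_design`.
#' @param yes_rate Probability of a yes response, in \[0, 1\].
#' @param seed Integer seed.
#' @param participant_id Identifier stored in the log.
#' @param order Optional presentation order.
#' @return A response-log data frame.
#' @export
simulate_guesser <- function(design, yes_rate = 0.5, seed = 1L,
                             participant_id = "guesser_1", order = NULL) {
  stopifnot(inherits(design, "agl_design"))
  if (yes_rate < 0 || yes_rate > 1) {
    stop("`yes_rate` must be in [0, 1]", call. = FALSE)
  }
  test <- .presentation(design, order)
  n <- nrow(test)
  yes <- withr::with_seed(seed, stats::runif(n) < yes_rate)
  .new_response_log(participant_id, design$group, "guesser",
                    seq_len(n), test$index, yes)
}

#' Simulate a cohort of participants over one or both groups
#'
#' Generates a stacked response log for `n_per_group` participants in each
#' supplied design (typically one design per trained grammar). Every
#' participant gets a child seed derived from `master_seed`, so the whole
#' cohort is reproducible. For Experiment-2 designs each participant also
#' receives a fresh random presentation order (the Experiment-2 procedure);
#' Experiment-1 participants share the design's stored order.
#'
#' `policy` is recycled across the participants of each group, so a vector
#' like `c("sdt_learner", "first_pair_strategist")` embeds strategists in a
#' learner cohort. Policy names: `"sdt_learner"`, `"first_pair_strategist"`,
#' `"last_pair_strategist"`, `"guesser"`.
#'
#' @param designs An `agl_design` or a list of them (one per group).
#' @param n_per_group Participants per design.
#' @param policy Character vector of policy names, recycled to
#'   `n_per_group`.
#' @param sensitivity,criterion,learning_slope Parameters for
#'   `sdt_learner` participants.
#' @param yes_rate Parameter for `guesser` participants.
#' @param master_seed Integer master seed.
#' @return A stacked response-log data frame; the cohort manifest (policy,
#'   parameters, child seeds per participant) is attached as attribute
#'   `"manifest"`.
#' @examples
#' d <- agl_design(2, "nested", seed = 3)
#' logs <- simulate_cohort(d, n_per_group = 4, policy = "guesser",
#'                         master_seed = 9)
#' length(unique(logs$participant_id))  # 4
#' @export
simulate_cohort <- function(designs, n_per_group = 15L,
                            policy = "sdt_learner",
                            sensitivity = 1, criterion = 0,
                            learning_slope = 0, yes_rate = 0.5,
                            master_seed = 1L) {
  if (inherits(designs, "agl_design")) designs <- list(designs)
  policies <- rep_len(policy, n_per_group)
  known <- c("sdt_learner", "first_pair_strategist", "last_pair_strategist",
             "guesser")
  if (!all(policies %in% known)) {
    stop("unknown policy; use one of: ", paste(known, collapse = ", "),
         call. = FALSE)
  }
  n_total <- length(designs) * n_per_group
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max, 2L * n_total))
  child_seed <- seeds[seq_len(n_total)]
  order_seed <- seeds[n_total + seq_len(n_total)]

  logs <- list()
  manifest <- list()
  k <- 0L
  for (design in designs) {
    stopifnot(inherits(design, "agl_design"))
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      pid <- sprintf("%s_%02d", gsub("-", "_", design$group), i)
      ord <- NULL
      if (design$experiment == 2) {
        idx <- test_trials(design)$index
        ord <- withr::with_seed(order_seed[k], sample(idx))
      }
      log <- switch(policies[i],
        sdt_learner = simulate_sdt_learner(
          design, sensitivity = sensitivity, criterion = criterion,
          learning_slope = learning_slope, seed = child_seed[k],
          participant_id = pid, order = ord),
        first_pair_strategist = simulate_strategist(
          design, "first", participant_id = pid, order = ord),
        last_pair_strategist = simulate_strategist(
          design, "last", participant_id = pid, order = ord),
        guesser = simulate_guesser(
          design, yes_rate = yes_rate, seed = child_seed[k],
          participant_id = pid, order = ord)
      )
      logs[[k]] <- log
      manifest[[k]] <- list(participant_id = pid, group = design$group,
                            policy = policies[i], seed = child_seed[k],
                            order_seed = if (design$experiment == 2)
                              order_seed[k] else NA_integer_)
    }
  }
  out <- do.call(rbind, logs)
  rownames(out) <- NULL
  attr(out, "manifest") <- manifest
  out
}
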