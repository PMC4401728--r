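#' Tally signal-detection counts from a response log
#'
#' Crosses one participant's yes/no judgments with the design's trial
#' labels: hits and misses come from correct trials (always all of them);
#' false alarms and correct rejections come from incorrect trials,
#' optionally restricted to one Experiment-2 foil subset. The restricted
#' tallies are what the strategy-specific sensitivities d'_first (S2) and
#' d'_last (S3) are built from: the hit rate is shared, only the error rate
#' is subset-specific.
#'
#' @param log Response log for a single participant (see
#'   [simulate_sdt_learner()] for the format).
#' @param design The `agl_design` the responses belong to.
#' @param restrict `"all"`, `"S1"`, `"S2"` or `"S3"` — which incorrect
#'   trials to score.
#' @param rows Optional integer vector of log rows to score (used by the
#'   block/length splits); defaults to all.
#' @return An object of class `sdt_counts`: named integer vector with
#'   elements `hits`, `misses`, `false_alarms`, `correct_rejections`.
#' @export
tally_counts <- function(log, design, restrict = c("all", "S1", "S2", "S3"),
                         rows = NULL) {
  restrict <- match.arg(restrict)
  stopifnot(inherits(design, "agl_design"))
  if (length(unique(log$participant_id)) > 1L) {
    stop("`log` must contain a single participant; see full_report() for ",
         "cohorts", call. = FALSE)
  }
  tr <- design$trials
  m <- match(log$trial_index, tr$index)
  if (anyNA(m) || any(tr$phase[m] != "test")) {
    stop("response log is not aligned to the design's test trials",
         call. = FALSE)
  }
  if (is.null(rows)) rows <- seq_len(nrow(log))
  label <- tr$label[m][rows]
  subset <- tr$foil_subset[m][rows]
  yes <- log$answer[rows] == "yes"
  score_fa <- label == "incorrect" &
    (restrict == "all" | subset == restrict)
  counts <- c(
    hits = sum(label == "correct" & yes),
    misses = sum(label == "correct" & !yes),
    false_alarms = sum(score_fa & yes),
    correct_rejections = sum(score_fa & !yes)
  )
  structure(as.integer(counts), names = names(counts), class = "sdt_counts")
}

#' Corrected d-prime and criterion from signal-detection counts
#'
#' Equal-variance Gaussian sensitivity with an unconditional log-linear
#' style cell correction: `cell_correction` (default 0.5) is added to all
#' four cells for every scoring, not only when a cell is empty, so that no
#' rate is ever 0 or 1. With corrected rates H and F,
#' `d' = qnorm(H) - qnorm(F)` and `criterion = -(qnorm(H) + qnorm(F)) / 2`.
#' A d-prime of 0 corresponds to chance (50% accuracy at a neutral
#' criterion).
#'
#' @param counts An `sdt_counts` vector (or any numeric vector of hits,
#'   misses, false alarms, correct rejections in that order).
#' @param cell_correction Constant added to each cell (>= 0).
#' @return List with `d_prime`, `criterion`, `hit_rate`, `fa_rate` (the
#'   corrected rates), and the corrected `counts`.
#' @examples
#' dprime(c(90, 30, 30, 90))$d_prime  # ~1.336
#' @export
dprime <- function(counts, cell_correction = 0.5) {
  if (length(counts) != 4L || any(counts < 0)) {
    stop("`counts` must be 4 nonnegative values", call. = FALSE)
  }
  if (cell_correction < 0) {
    stop("`cell_correction` must be >= 0", call. = FALSE)
  }
  k <- as.numeric(counts) + cell_correction
  if (k[1] + k[2] <= 0 || k[3] + k[4] <= 0) {
    stop("undefined rates: zero scored trials and no cell correction",
         call. = FALSE)
  }
  h <- k[1] / (k[1] + k[2])
  f <- k[3] / (k[3] + k[4])
  if (h %in% c(0, 1) || f %in% c(0, 1)) {
    stop("degenerate rate of 0 or 1; use a positive cell correction",
         call. = FALSE)
  }
  list(
    d_prime = stats::qnorm(h) - stats::qnorm(f),
    criterion = -(stats::qnorm(h) + stats::qnorm(f)) / 2,
    hit_rate = h,
    fa_rate = f,
    counts = k
  )
}

#' Split a participant's test responses into consecutive blocks
#'
#' Partitions the test phase into `n_blocks` equal consecutive blocks by
#' presentation position (thirds by default: 120 trials per block for the
#' Experiment-1 test phase, 80 for Experiment 2) and tallies
#' signal-detection counts per block.
#'
#' @inheritParams tally_counts
#' @param n_blocks Number of equal consecutive blocks (default 3).
#' @return Named list of `sdt_counts`, one per block.
#' @export
sdt_by_block <- function(log, design, n_blocks = 3L) {
  n <- nrow(log)
  if (n %% n_blocks != 0L) {
    stop("test-phase trial count ", n, " is not divisible into ",
         n_blocks, " equal blocks", call. = FALSE)
  }
  size <- n %/% n_blocks
  ord <- order(log$position)
  out <- lapply(seq_len(n_blocks), function(b) {
    rows <- ord[((b - 1L) * size + 1L):(b * size)]
    tally_counts(log, design, rows = rows)
  })
  names(out) <- paste0("block", seq_len(n_blocks))
  out
}

#' Split a participant's test responses by sequence length
#'
#' Tallies signal-detection counts separately for the short, medium and
#' long sequence classes (4/6/8 syllables) of an Experiment-1-style design.
#'
#' @inheritParams tally_counts
#' @return Named list of `sdt_counts`, one per length class present.
#' @export
sdt_by_length <- function(log, design) {
  tr <- design$trials
  m <- match(log$trial_index, tr$index)
  lc <- tr$length_class[m]
  classes <- intersect(names(design$config$lengths), unique(lc))
  out <- lapply(classes, function(x) {
    tally_counts(log, design, rows = which(lc == x))
  })
  names(out) <- classes
  out
}

#' Block sizes of a design's test phase
#'
#' @param design An `agl_design`.
#' @param n_blocks Number of blocks.
#' @return Integer vector of block sizes (all equal).
#' @export
block_sizes <- function(design, n_blocks = 3L) {
  n <- nrow(test_trials(design))
  if (n %% n_blocks != 0L) {
    stop("test-phase trial count ", n, " is not divisible into ",
         n_blocks, " equal blocks", call. = FALSE)
  }
  rep(n %/% n_blocks, n_blocks)
}
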