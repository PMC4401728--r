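#' Run the full analysis battery on a simulated or imported cohort
#'
#' Reproduces the complete analysis sequence of the grammar-learning
#' paradigm on a cohort of response logs: per-participant corrected
#' d-prime (overall, per test block, and — for Experiment-1 designs — per
#' sequence length; for Experiment-2 designs the strategy-restricted
#' d'_first and d'_last), group-level one-sample t-tests of d' against
#' chance with Cohen's d, a between-groups independent-samples t-test,
#' 2 x 3 mixed ANOVAs over blocks (and sequence lengths for Experiment 1)
#' with Greenhouse-Geisser correction and partial eta squared, follow-up
#' 2 x 2 ANOVAs on level pairs, and — for Experiment 2 — per-participant
#' exact binomial strategy diagnostics plus a sensitivity rerun of the
#' group tests excluding flagged participants.
#'
#' @param logs Stacked response-log data frame (see [simulate_cohort()]).
#' @param designs An `agl_design`, or a named list of designs keyed by
#'   group (`"nested"`, `"cross-serial"`).
#' @param alpha Significance level for the strategy diagnostics.
#' @param cell_correction Cell correction for [dprime()].
#' @param bonferroni If `TRUE`, Bonferroni-adjust the follow-up 2 x 2
#'   ANOVA p-values within each family; default `FALSE` (no adjustment).
#' @return An object of class `agl_report`.
#' @export
full_report <- function(logs, designs, alpha = 0.05, cell_correction = 0.5,
                        bonferroni = FALSE) {
  if (inherits(designs, "agl_design")) {
    designs <- stats::setNames(list(designs), designs$group)
  }
  experiment <- unique(vapply(designs, `[[`, integer(1), "experiment"))
  if (length(experiment) != 1L) {
    stop("all designs must belong to the same experiment", call. = FALSE)
  }
  pids <- unique(logs$participant_id)
  if (length(pids) < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }

  per <- lapply(pids, function(pid) {
    log <- logs[logs$participant_id == pid, , drop = FALSE]
    grp <- log$group[1]
    design <- designs[[grp]]
    if (is.null(design)) {
      stop("no design supplied for group '", grp, "'", call. = FALSE)
    }
    row <- list(participant_id = pid, group = grp)
    row$d_prime <- dprime(tally_counts(log, design),
                          cell_correction)$d_prime
    row$criterion <- dprime(tally_counts(log, design),
                            cell_correction)$criterion
    blocks <- sdt_by_block(log, design)
    for (b in names(blocks)) {
      row[[paste0("d_", b)]] <- dprime(blocks[[b]], cell_correction)$d_prime
    }
    if (experiment == 1) {
      lens <- sdt_by_length(log, design)
      for (l in names(lens)) {
        row[[paste0("d_", l)]] <- dprime(lens[[l]], cell_correction)$d_prime
      }
    } else {
      row$d_first <- dprime(tally_counts(log, design, restrict = "S2"),
                            cell_correction)$d_prime
      row$d_last <- dprime(tally_counts(log, design, restrict = "S3"),
                           cell_correction)$d_prime
      st <- binomial_strategy_tests(log, design, alpha)
      row$p_S1 <- unname(st$p["S1"])
      row$p_S2 <- unname(st$p["S2"])
      row$p_S3 <- unname(st$p["S3"])
      row$flag_first <- st$first_pair
      row$flag_last <- st$last_pair
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  participants <- do.call(rbind, per)
  rownames(participants) <- NULL

  groups <- unique(participants$group)
  group_stats <- function(df) {
    out <- lapply(groups, function(g) {
      one_sample_t(df$d_prime[df$group == g], 0)
    })
    names(out) <- groups
    between <- NULL
    if (length(groups) == 2L) {
      between <- independent_t(df$d_prime[df$group == groups[1]],
                               df$d_prime[df$group == groups[2]])
    }
    list(vs_zero = out, between = between)
  }
  main <- group_stats(participants)

  anovas <- list()
  followups <- list()
  if (length(groups) == 2L) {
    block_cols <- grep("^d_block", names(participants), value = TRUE)
    bm <- as.matrix(participants[block_cols])
    anovas$block <- mixed_anova_gg(bm, participants$group)
    if (experiment == 1) {
      len_cols <- paste0("d_", names(designs[[1]]$config$lengths))
      lm_ <- as.matrix(participants[len_cols])
      anovas$length <- mixed_anova_gg(lm_, participants$group)
      pairs2 <- function(mat, labels) {
        cmb <- utils::combn(ncol(mat), 2)
        out <- lapply(seq_len(ncol(cmb)), function(i) {
          mixed_anova_gg(mat[, cmb[, i]], participants$group)
        })
        names(out) <- apply(cmb, 2, function(ix) {
          paste(labels[ix], collapse = "_vs_")
        })
        out
      }
      followups$block <- pairs2(bm, sub("^d_", "", block_cols))
      followups$length <- pairs2(lm_, sub("^d_", "", len_cols))
      if (bonferroni) {
        adjust <- function(fam) {
          k <- length(fam)
          lapply(fam, function(tab) {
            tab$p <- pmin(1, tab$p * k)
            tab$p_gg <- pmin(1, tab$p_gg * k)
            tab
          })
        }
        followups <- lapply(followups, adjust)
      }
    }
  }

  strategy <- NULL
  rerun <- NULL
  if (experiment == 2) {
    strat_t <- list()
    for (g in groups) {
      strat_t[[g]] <- list(
        d_first = one_sample_t(participants$d_first[participants$group == g]),
        d_last = one_sample_t(participants$d_last[participants$group == g])
      )
    }
    flagged <- participants$participant_id[
      participants$flag_first | participants$flag_last]
    strategy <- list(tests = strat_t, flagged = flagged)
    if (length(flagged)) {
      keep <- !(participants$participant_id %in% flagged)
      enough <- all(table(participants$group[keep]) >= 2)
      if (enough) rerun <- group_stats(participants[keep, , drop = FALSE])
    }
  }

  structure(
    list(experiment = experiment, participants = participants,
         group_tests = main, anovas = anovas, followups = followups,
         strategy = strategy, rerun_excluding_flagged = rerun,
         alpha = alpha, cell_correction = cell_correction),
    class = "agl_report"
  )
}

.fmt_t <- function(x) {
  sprintf("t(%g) = %.2f, p = %.4g, d = %.2f",
          x$df, x$t, x$p, x$cohens_d)
}

#' @export
print.agl_report <- function(x, ...) {
  cat("AGL analysis report (experiment", x$experiment, ")\n")
  cat(" participants:", nrow(x$participants), "in groups:",
      paste(unique(x$participants$group), collapse = ", "), "\n\n")
  cat(" d' vs chance (0):\n")
  for (g in names(x$group_tests$vs_zero)) {
    cat("  ", g, ": ", .fmt_t(x$group_tests$vs_zero[[g]]), "\n", sep = "")
  }
  if (!is.null(x$group_tests$between)) {
    b <- x$group_tests$between
    cat("  between groups: t(", b$df, ") = ", sprintf("%.2f", b$t),
        ", p = ", sprintf("%.4g", b$p), "\n", sep = "")
  }
  for (nm in names(x$anovas)) {
    tab <- x$anovas[[nm]]
    w <- tab[tab$effect == "within", ]
    cat("\n 2x", sum(!is.na(w$eps)) + 2, " mixed ANOVA (", nm, "): within ",
        sprintf("F(%.2f, %.2f) = %.2f, p = %.4g, pes = %.2f",
                w$df_gg, w$df_error_gg, w$F, w$p_gg, w$pes), "\n", sep = "")
  }
  if (!is.null(x$strategy)) {
    cat("\n strategy-flagged participants:",
        if (length(x$strategy$flagged)) {
          paste(x$strategy$flagged, collapse = ", ")
        } else "none", "\n")
  }
  invisible(x)
}

#' @export
summary.agl_report <- function(object, ...) {
  print(object)
  cat("\nPer-participant measures:\n")
  print(utils::head(object$participants, 10))
  invisible(object)
}
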