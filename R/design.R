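#' Design configuration defaults
#'
#' Returns the count parameters of the two experimental designs. Defaults:
#' the learning phase (both experiments) has 80 sequences per length class
#' (short/medium/long = 4/6/8 syllables, i.e. 2/3/4 dependency pairs), 240
#' in total, with 25% repeat probes. The Experiment-1 test phase has 360
#' trials: 180 members of the trained grammar (correct) and 180 members of
#' the untrained grammar (incorrect), 60 per length class per label. The
#' Experiment-2 test phase has 240 medium-length trials: 120 correct and 120
#' foils split into three subsets of 40 (S1 other-grammar, S2 first-pair
#' preserving, S3 last-pair preserving).
#'
#' @param experiment 1 or 2.
#' @param learning_per_length Learning sequences per length class.
#' @param test_per_length_per_label Experiment-1 test sequences per
#'   (length class, label) cell.
#' @param test_correct Experiment-2 correct test trials.
#' @param foils_per_subset Experiment-2 foils per subset.
#' @param repeat_probe_rate Fraction of learning trials flagged as repeat
#'   probes (alertness checks); the count is floored to an integer.
#' @param lengths Named integer vector mapping length-class labels to the
#'   number of dependency pairs.
#' @return A list of class `agl_config`.
#' @export
agl_config <- function(experiment = 1,
                       learning_per_length = 80L,
                       test_per_length_per_label = 60L,
                       test_correct = 120L,
                       foils_per_subset = 40L,
                       repeat_probe_rate = 0.25,
                       lengths = c(short = 2L, medium = 3L, long = 4L)) {
  if (!experiment %in% c(1L, 2L)) {
    stop("`experiment` must be 1 or 2", call. = FALSE)
  }
  n_syll <- 20L
  if (learning_per_length %% n_syll != 0L) {
    stop("`learning_per_length` must be divisible by ", n_syll,
         " for exact counterbalancing", call. = FALSE)
  }
  if (experiment == 1L && test_per_length_per_label %% n_syll != 0L) {
    stop("`test_per_length_per_label` must be divisible by ", n_syll,
         call. = FALSE)
  }
  if (experiment == 2L) {
    if (test_correct %% n_syll != 0L) {
      stop("`test_correct` must be divisible by ", n_syll, call. = FALSE)
    }
    if (foils_per_subset %% 2L != 0L ||
        (3L * foils_per_subset) %% n_syll != 0L) {
      stop("`foils_per_subset` must be even and 3x it divisible by ",
           n_syll, call. = FALSE)
    }
  }
  structure(list(
    experiment = as.integer(experiment),
    learning_per_length = as.integer(learning_per_length),
    test_per_length_per_label = as.integer(test_per_length_per_label),
    test_correct = as.integer(test_correct),
    foils_per_subset = as.integer(foils_per_subset),
    repeat_probe_rate = repeat_probe_rate,
    lengths = lengths
  ), class = "agl_config")
}

# Counterbalanced A-part generation with local repair.
#
# Each of the n_pos columns is a seeded shuffle of a multiset holding every
# category-A syllable exactly n_rows/20 times, so per-position occupancy is
# exactly uniform by construction. Rows violating a constraint (duplicate
# pair within the sequence, or a realized sequence string colliding with a
# previously used one or another row) are repaired by swapping single column
# entries between rows -- swaps preserve the column multisets, hence the
# counterbalance. `realize` maps (row index, A syllables) to the full
# realized sequence (character vector).
.balanced_a_parts <- function(n_rows, n_pos, realize, used, lexicon,
                              max_attempts = 50000L) {
  syll <- lexicon$class_a
  per <- n_rows %/% length(syll)
  mat <- vapply(seq_len(n_pos), function(j) sample(rep(syll, per)),
                character(n_rows))
  mat <- matrix(mat, nrow = n_rows)
  pair_of <- function(s) lexicon$pair_id[match(s, lexicon$class_a)]
  seq_str <- character(n_rows)
  recompute <- function(r) {
    if (anyDuplicated(pair_of(mat[r, ])) == 0L) {
      seq_str[r] <<- paste(realize(r, mat[r, ]), collapse = " ")
    } else {
      seq_str[r] <<- NA_character_
    }
  }
  for (r in seq_len(n_rows)) recompute(r)
  # Badness of a row: number of surplus duplicate pairs (+1 while any exist,
  # since the sequence cannot even be realized), or 1 for a realized string
  # that collides with a used or sibling sequence. Zero means valid. Swaps
  # are accepted only when they strictly reduce the summed badness of the
  # two rows involved, so multi-duplicate rows are repaired incrementally
  # and the loop cannot cycle.
  row_score <- function(r) {
    p <- pair_of(mat[r, ])
    dups <- sum(duplicated(p))
    if (dups > 0L) return(dups + 1L)
    s <- seq_str[r]
    if (s %in% used || sum(seq_str == s, na.rm = TRUE) > 1L) 1L else 0L
  }
  attempts <- 0L
  repeat {
    scores <- vapply(seq_len(n_rows), row_score, integer(1))
    bad <- which(scores > 0L)
    if (isTRUE(getOption("aglsdt.debug"))) {
      cat("repair sweep:", length(bad), "rows pending,", attempts,
          "attempts\n")
    }
    if (length(bad) == 0L) break
    for (r in bad) {
      for (k in seq_len(200L)) {
        attempts <- attempts + 1L
        if (attempts > max_attempts) {
          stop("sequence generation exhausted: could not satisfy ",
               "uniqueness/distinct-pair constraints", call. = FALSE)
        }
        # prefer a column involved in a duplicated pair, if any
        p <- pair_of(mat[r, ])
        dup_pos <- which(p %in% p[duplicated(p)])
        j <- if (length(dup_pos)) {
          dup_pos[sample.int(length(dup_pos), 1L)]
        } else {
          sample.int(n_pos, 1L)
        }
        r2 <- sample.int(n_rows, 1L)
        if (r2 == r || mat[r, j] == mat[r2, j]) next
        before <- row_score(r) + row_score(r2)
        keep_r <- mat[r, ]
        keep_r2 <- mat[r2, ]
        tmp <- mat[r, j]
        mat[r, j] <- mat[r2, j]
        mat[r2, j] <- tmp
        recompute(r)
        recompute(r2)
        if (row_score(r) + row_score(r2) < before) {
          break
        }
        mat[r, ] <- keep_r
        mat[r2, ] <- keep_r2
        recompute(r)
        recompute(r2)
      }
    }
  }
  list(mat = mat, sequences = seq_str)
}

.trial_rows <- function(sequences, phase, length_class, n_pairs, label,
                        foil_subset, grammar) {
  data.frame(
    phase = phase,
    length_class = length_class,
    n_pairs = n_pairs,
    sequence = sequences,
    label = label,
    foil_subset = foil_subset,
    repeat_probe = FALSE,
    grammar_of_sequence = grammar,
    stringsAsFactors = FALSE
  )
}

# Learning phase: counterbalanced members of the trained grammar, all three
# length classes, shuffled into one presentation order. Assumes the RNG has
# been seeded by the caller; `used` is an environment with a character
# vector `seqs` tracking every realized sequence in the design.
.build_learning <- function(group, config, used, lexicon) {
  out <- lapply(names(config$lengths), function(lc) {
    n <- config$lengths[[lc]]
    res <- .balanced_a_parts(
      config$learning_per_length, n,
      realize = function(r, a) arrange_b_part(a, group, lexicon),
      used = used$seqs, lexicon = lexicon
    )
    used$seqs <- c(used$seqs, res$sequences)
    .trial_rows(res$sequences, "learning", lc, n, "n/a", "none", group)
  })
  trials <- do.call(rbind, out)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  n_probe <- floor(config$repeat_probe_rate * nrow(trials))
  trials$repeat_probe[sample.int(nrow(trials), n_probe)] <- TRUE
  rownames(trials) <- NULL
  trials
}

# Experiment-1 test phase: per length class, `test_per_length_per_label`
# members of the trained grammar (correct) and of the untrained grammar
# (incorrect); one shared shuffled presentation order.
.build_test_exp1 <- function(group, config, used, lexicon) {
  foil_grammar <- other_dependency(group)
  out <- list()
  for (lc in names(config$lengths)) {
    n <- config$lengths[[lc]]
    for (lab in c("correct", "incorrect")) {
      gram <- if (lab == "correct") group else foil_grammar
      res <- .balanced_a_parts(
        config$test_per_length_per_label, n,
        realize = function(r, a) arrange_b_part(a, gram, lexicon),
        used = used$seqs, lexicon = lexicon
      )
      used$seqs <- c(used$seqs, res$sequences)
      out[[paste(lc, lab)]] <-
        .trial_rows(res$sequences, "test", lc, n, lab, "none", gram)
    }
  }
  trials <- do.call(rbind, out)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  rownames(trials) <- NULL
  trials
}

# The six incorrect-sequence templates per trained grammar: A-index order
# and B-index order applied to a base triple of pair identities. Two
# variants per subset. S1 sequences are members of the untrained grammar;
# S2 preserves the trained grammar's first dependency pair, S3 its last.
.foil_templates <- function(group) {
  switch(group,
    "nested" = list(
      S1 = list(list(a = c(1, 2, 3), b = c(1, 2, 3)),
                list(a = c(3, 2, 1), b = c(3, 2, 1))),
      S2 = list(list(a = c(1, 2, 3), b = c(2, 3, 1)),
                list(a = c(1, 3, 2), b = c(3, 2, 1))),
      S3 = list(list(a = c(1, 2, 3), b = c(3, 1, 2)),
                list(a = c(2, 1, 3), b = c(3, 2, 1)))
    ),
    "cross-serial" = list(
      S1 = list(list(a = c(1, 2, 3), b = c(3, 2, 1)),
                list(a = c(3, 2, 1), b = c(1, 2, 3))),
      S2 = list(list(a = c(1, 2, 3), b = c(1, 3, 2)),
                list(a = c(1, 3, 2), b = c(1, 2, 3))),
      S3 = list(list(a = c(1, 2, 3), b = c(2, 1, 3)),
                list(a = c(2, 1, 3), b = c(1, 2, 3)))
    )
  )
}

#' Realize a strategy-control foil template
#'
#' Builds one Experiment-2 incorrect sequence from a base triple of pair
#' identities and one of the six printed templates for the trained grammar.
#' Subset S1 foils are members of the untrained grammar (as in Experiment
#' 1); S2 foils violate the trained rule while keeping its first dependency
#' pair intact (so a first-element-pair strategist accepts them); S3 foils
#' keep the last dependency pair intact. Each subset has two template
#' variants.
#'
#' @param pair_ids Integer vector of 3 distinct pair identities
#'   (the base triple p1, p2, p3).
#' @param subset `"S1"`, `"S2"` or `"S3"`.
#' @param variant 1 or 2.
#' @param group Trained grammar (`"nested"` or `"cross-serial"`).
#' @param lexicon Lexicon table.
#' @return Character vector of 6 syllables.
#' @examples
#' # nested group, S2 variant 1, pairs 1..3: A1 A2 A3 B2 B3 B1
#' apply_foil_template(1:3, "S2", 1, "nested")
#' @export
apply_foil_template <- function(pair_ids, subset, variant = 1,
                                group, lexicon = agl_lexicon()) {
  group <- match_dependency(group)
  subset <- match.arg(subset, c("S1", "S2", "S3"))
  if (!variant %in% c(1L, 2L)) {
    stop("`variant` must be 1 or 2", call. = FALSE)
  }
  if (length(pair_ids) != 3L || anyDuplicated(pair_ids) ||
      !all(pair_ids %in% lexicon$pair_id)) {
    stop("`pair_ids` must be 3 distinct lexicon pair identities",
         call. = FALSE)
  }
  tpl <- .foil_templates(group)[[subset]][[variant]]
  c(lexicon$class_a[match(pair_ids[tpl$a], lexicon$pair_id)],
    lexicon$class_b[match(pair_ids[tpl$b], lexicon$pair_id)])
}

# Experiment-2 test phase: 120 medium-length correct trials plus 120 foils
# (40 per subset, the two template variants used 20 times each). Foil base
# triples go through the same counterbalance machinery as correct trials.
.build_test_exp2 <- function(group, config, used, lexicon) {
  n <- config$lengths[["medium"]]
  res_c <- .balanced_a_parts(
    config$test_correct, n,
    realize = function(r, a) arrange_b_part(a, group, lexicon),
    used = used$seqs, lexicon = lexicon
  )
  used$seqs <- c(used$seqs, res_c$sequences)
  correct <- .trial_rows(res_c$sequences, "test", "medium", n, "correct",
                         "none", group)

  n_foil <- 3L * config$foils_per_subset
  subset_vec <- rep(c("S1", "S2", "S3"), each = config$foils_per_subset)
  variant_vec <- rep(rep(1:2, each = config$foils_per_subset %/% 2L), 3L)
  res_f <- .balanced_a_parts(
    n_foil, n,
    realize = function(r, a) {
      apply_foil_template(syllable_pairs(a, lexicon), subset_vec[r],
                          variant_vec[r], group, lexicon)
    },
    used = used$seqs, lexicon = lexicon
  )
  used$seqs <- c(used$seqs, res_f$sequences)
  foil_grammar <- ifelse(subset_vec == "S1", other_dependency(group), "none")
  foils <- .trial_rows(res_f$sequences, "test", "medium", n, "incorrect",
                       subset_vec, foil_grammar)

  trials <- rbind(correct, foils)
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  rownames(trials) <- NULL
  trials
}

#' Build a learning-phase trial list
#'
#' Standalone access to the learning-set constructor: counterbalanced
#' members of the trained grammar across the three length classes, with
#' repeat probes flagged. [agl_design()] is the usual entry point; use this
#' when only the learning phase is needed.
#'
#' @param group Trained grammar.
#' @param seed Integer seed.
#' @param config An [agl_config()].
#' @param lexicon Lexicon table.
#' @return A trial data frame (no test phase).
#' @export
build_learning_set <- function(group, seed = 1L, config = agl_config(1),
                               lexicon = agl_lexicon()) {
  group <- match_dependency(group)
  withr::with_seed(seed, {
    used <- new.env(parent = emptyenv())
    used$seqs <- character()
    .build_learning(group, config, used, lexicon)
  })
}

#' Build an Experiment-1 or Experiment-2 test trial list
#'
#' Standalone access to the test-set constructors. `used_sequences` carries
#' the learning-phase sequences so that no sequence recurs anywhere in the
#' design.
#'
#' @inheritParams build_learning_set
#' @param used_sequences Character vector of already-used sequence strings.
#' @return A trial data frame (test phase only).
#' @export
build_test_set_exp1 <- function(group, seed = 1L, config = agl_config(1),
                                used_sequences = character(),
                                lexicon = agl_lexicon()) {
  group <- match_dependency(group)
  withr::with_seed(seed, {
    used <- new.env(parent = emptyenv())
    used$seqs <- used_sequences
    .build_test_exp1(group, config, used, lexicon)
  })
}

#' @rdname build_test_set_exp1
#' @export
build_test_set_exp2 <- function(group, seed = 1L, config = agl_config(2),
                                used_sequences = character(),
                                lexicon = agl_lexicon()) {
  group <- match_dependency(group)
  withr::with_seed(seed, {
    used <- new.env(parent = emptyenv())
    used$seqs <- used_sequences
    .build_test_exp2(group, config, used, lexicon)
  })
}

#' Construct a complete experimental design
#'
#' Builds the full ordered trial list (learning then test) for one group of
#' one experiment: counterbalanced A-parts, grammar-derived B-parts,
#' global sequence uniqueness, repeat probes, and — for Experiment 2 — the
#' three strategy-control foil subsets. All randomness derives from `seed`;
#' identical inputs give byte-identical designs. The stored test order is
#' the shared presentation order for Experiment 1; Experiment-2 cohorts
#' draw a fresh per-participant order at simulation time (see
#' [simulate_cohort()]).
#'
#' @param experiment 1 or 2.
#' @param group Trained grammar (`"nested"`, `"cross-serial"`, or the alias
#'   `"cross"`).
#' @param seed Integer seed.
#' @param config An [agl_config()]; defaults to the standard counts for
#'   `experiment`.
#' @param lexicon Lexicon table.
#' @return An object of class `agl_design`: a list with elements
#'   `experiment`, `group`, `seed`, `config` and `trials` (a data frame with
#'   columns `index`, `phase`, `length_class`, `n_pairs`, `sequence`,
#'   `label`, `foil_subset`, `repeat_probe`, `grammar_of_sequence`,
#'   `test_position`).
#' @examples
#' d <- agl_design(2, "nested", seed = 42)
#' table(d$trials$foil_subset[d$trials$phase == "test"])
#' @export
agl_design <- function(experiment = 1, group = "nested", seed = 1L,
                       config = NULL, lexicon = agl_lexicon()) {
  group <- match_dependency(group)
  if (is.null(config)) config <- agl_config(experiment)
  if (config$experiment != experiment) {
    stop("`config` was built for experiment ", config$experiment,
         call. = FALSE)
  }
  validate_lexicon(lexicon)
  trials <- withr::with_seed(seed, {
    used <- new.env(parent = emptyenv())
    used$seqs <- character()
    learning <- .build_learning(group, config, used, lexicon)
    test <- if (experiment == 1) {
      .build_test_exp1(group, config, used, lexicon)
    } else {
      .build_test_exp2(group, config, used, lexicon)
    }
    rbind(learning, test)
  })
  trials$index <- seq_len(nrow(trials))
  trials$test_position <- NA_integer_
  is_test <- trials$phase == "test"
  trials$test_position[is_test] <- seq_len(sum(is_test))
  trials <- trials[c("index", "phase", "length_class", "n_pairs", "sequence",
                     "label", "foil_subset", "repeat_probe",
                     "grammar_of_sequence", "test_position")]
  structure(
    list(experiment = as.integer(experiment), group = group,
         seed = as.integer(seed), config = config, trials = trials),
    class = "agl_design"
  )
}

#' @export
print.agl_design <- function(x, ...) {
  tr <- x$trials
  cat("AGL design: experiment", x$experiment, "| trained grammar:", x$group,
      "| seed:", x$seed, "\n")
  cat(" learning:", sum(tr$phase == "learning"), "trials (",
      sum(tr$repeat_probe), "repeat probes )\n")
  test <- tr[tr$phase == "test", ]
  cat(" test:    ", nrow(test), "trials;",
      sum(test$label == "correct"), "correct /",
      sum(test$label == "incorrect"), "incorrect\n")
  if (x$experiment == 2) {
    cat(" foils:   ", paste(names(table(test$foil_subset[test$foil_subset !=
      "none"])), table(test$foil_subset[test$foil_subset != "none"]),
      sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Test-phase trials of a design in presentation order
#' @param design An `agl_design`.
#' @return Data frame of test trials ordered by `test_position`.
#' @export
test_trials <- function(design) {
  stopifnot(inherits(design, "agl_design"))
  tr <- design$trials[design$trials$phase == "test", , drop = FALSE]
  tr[order(tr$test_position), , drop = FALSE]
}

# Is a given dependency link (one row of dependency_structure()) intact in
# a sequence: category-A at a_pos, category-B at b_pos, same pair identity.
.link_intact <- function(syllables, link_row, lexicon) {
  info <- .lookup_syllables(syllables, lexicon)
  a <- info[link_row$a_pos, ]
  b <- info[link_row$b_pos, ]
  a$category == "A" && b$category == "B" && a$pair_id == b$pair_id
}

#' Validate a design against its declared structure
#'
#' Recomputes every structural property the generators promise and reports
#' violations rather than throwing: cell counts, global sequence uniqueness,
#' label soundness (a test trial is labelled correct iff its sequence is a
#' member of the trained grammar), Experiment-1 foil identity (incorrect
#' sequences are members of the untrained grammar), Experiment-2 foil
#' subset properties (sizes; S2 preserves the trained grammar's first
#' dependency pair, S3 its last; no foil is a member of the trained
#' grammar), exact A-position counterbalance where the design defines it,
#' and repeat-probe count/placement.
#'
#' @param design An `agl_design`.
#' @param lexicon Lexicon table.
#' @return An object of class `agl_verification`: list with `violations`
#'   (character vector, empty iff valid), `valid` (logical) and `tallies`.
#' @export
verify_design <- function(design, lexicon = agl_lexicon()) {
  stopifnot(inherits(design, "agl_design"))
  cfg <- design$config
  tr <- design$trials
  group <- design$group
  v <- character()
  note <- function(msg) v <<- c(v, msg)

  learning <- tr[tr$phase == "learning", ]
  test <- tr[tr$phase == "test", ]

  ## cell counts
  lc_counts <- table(learning$length_class)
  for (lc in names(cfg$lengths)) {
    got <- if (lc %in% names(lc_counts)) lc_counts[[lc]] else 0L
    if (got != cfg$learning_per_length) {
      note(sprintf("learning count for %s is %d, expected %d",
                   lc, got, cfg$learning_per_length))
    }
  }
  if (design$experiment == 1) {
    for (lc in names(cfg$lengths)) {
      for (lab in c("correct", "incorrect")) {
        got <- sum(test$length_class == lc & test$label == lab)
        if (got != cfg$test_per_length_per_label) {
          note(sprintf("test count for (%s, %s) is %d, expected %d",
                       lc, lab, got, cfg$test_per_length_per_label))
        }
      }
    }
  } else {
    if (any(test$length_class != "medium")) {
      note("experiment-2 test trials must all be medium length")
    }
    if (sum(test$label == "correct") != cfg$test_correct) {
      note(sprintf("experiment-2 correct count is %d, expected %d",
                   sum(test$label == "correct"), cfg$test_correct))
    }
    for (s in c("S1", "S2", "S3")) {
      got <- sum(test$foil_subset == s)
      if (got != cfg$foils_per_subset) {
        note(sprintf("foil subset %s has %d trials, expected %d",
                     s, got, cfg$foils_per_subset))
      }
    }
  }

  ## uniqueness across the whole design
  dup <- duplicated(tr$sequence)
  if (any(dup)) {
    note(sprintf("%d duplicated sequence(s) in the design", sum(dup)))
  }

  ## membership / label soundness
  seq_lists <- strsplit(tr$sequence, " ", fixed = TRUE)
  member_trained <- vapply(seq_lists, is_member, logical(1),
                           dependency = group, lexicon = lexicon)
  if (!all(member_trained[tr$phase == "learning"])) {
    note("learning-phase sequence not a member of the trained grammar")
  }
  is_test_row <- tr$phase == "test"
  mism <- is_test_row &
    (member_trained != (tr$label == "correct"))
  if (any(mism)) {
    note(sprintf("%d test trial(s) with unsound label", sum(mism)))
  }

  ## foil identity / subset properties
  foil_gram <- other_dependency(group)
  if (design$experiment == 1) {
    inc <- which(is_test_row & tr$label == "incorrect")
    ok <- vapply(seq_lists[inc], is_member, logical(1),
                 dependency = foil_gram, lexicon = lexicon)
    if (!all(ok)) {
      note(sprintf("%d experiment-1 foil(s) not members of the %s grammar",
                   sum(!ok), foil_gram))
    }
  } else {
    n_med <- cfg$lengths[["medium"]]
    ds <- dependency_structure(n_med, group)
    first_link <- ds[1, ]
    last_link <- ds[n_med, ]
    s1 <- which(tr$foil_subset == "S1")
    ok1 <- vapply(seq_lists[s1], is_member, logical(1),
                  dependency = foil_gram, lexicon = lexicon)
    if (!all(ok1)) {
      note(sprintf("%d S1 foil(s) not members of the %s grammar",
                   sum(!ok1), foil_gram))
    }
    s2 <- which(tr$foil_subset == "S2")
    ok2 <- vapply(seq_lists[s2], .link_intact, logical(1),
                  link_row = first_link, lexicon = lexicon)
    if (!all(ok2)) {
      note(sprintf("%d S2 foil(s) do not preserve the first dependency pair",
                   sum(!ok2)))
    }
    s3 <- which(tr$foil_subset == "S3")
    ok3 <- vapply(seq_lists[s3], .link_intact, logical(1),
                  link_row = last_link, lexicon = lexicon)
    if (!all(ok3)) {
      note(sprintf("%d S3 foil(s) do not preserve the last dependency pair",
                   sum(!ok3)))
    }
  }

  ## exact counterbalance of A-position occupancy where defined
  tally_cells <- list()
  check_balance <- function(rows, expected, what) {
    if (length(rows) == 0L) return(invisible())
    n <- tr$n_pairs[rows[1]]
    a_mat <- t(vapply(seq_lists[rows], function(s) s[seq_len(n)],
                      character(n)))
    tab <- apply(a_mat, 2, function(col) table(factor(col,
      levels = lexicon$class_a)))
    tally_cells[[what]] <<- tab
    if (!all(tab == expected)) {
      note(sprintf("A-position counterbalance violated in %s", what))
    }
  }
  for (lc in names(cfg$lengths)) {
    check_balance(which(tr$phase == "learning" & tr$length_class == lc),
                  cfg$learning_per_length / 20L,
                  paste0("learning/", lc))
  }
  if (design$experiment == 1) {
    for (lc in names(cfg$lengths)) {
      for (lab in c("correct", "incorrect")) {
        check_balance(
          which(is_test_row & tr$length_class == lc & tr$label == lab),
          cfg$test_per_length_per_label / 20L,
          paste0("test/", lc, "/", lab))
      }
    }
  } else {
    check_balance(which(is_test_row & tr$label == "correct"),
                  cfg$test_correct / 20L, "test/correct")
  }

  ## repeat probes
  expected_probes <- floor(cfg$repeat_probe_rate * nrow(learning))
  if (sum(learning$repeat_probe) != expected_probes) {
    note(sprintf("repeat-probe count is %d, expected %d",
                 sum(learning$repeat_probe), expected_probes))
  }
  if (any(test$repeat_probe)) {
    note("repeat probes must only occur in the learning phase")
  }

  structure(
    list(violations = v, valid = length(v) == 0L, tallies = tally_cells),
    class = "agl_verification"
  )
}

#' @export
print.agl_verification <- function(x, ...) {
  if (x$valid) {
    cat("Design valid: no violations.\n")
  } else {
    cat("Design INVALID:", length(x$violations), "violation(s)\n")
    for (m in x$violations) cat(" -", m, "\n")
  }
  invisible(x)
}
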