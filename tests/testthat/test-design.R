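test_that("default Experiment-1 design reproduces the printed cell counts", {
  d <- fx_d1n()
  tr <- d$trials
  learning <- tr[tr$phase == "learning", ]
  test <- tr[tr$phase == "test", ]
  expect_equal(nrow(learning), 240L)
  expect_equal(unname(table(learning$length_class)[c("short", "medium",
                                                     "long")]),
               c(80L, 80L, 80L), ignore_attr = TRUE)
  expect_equal(sum(learning$repeat_probe), 60L)
  expect_equal(nrow(test), 360L)
  expect_equal(sum(test$label == "correct"), 180L)
  expect_equal(sum(test$label == "incorrect"), 180L)
  cell <- table(test$length_class, test$label)
  expect_true(all(cell == 60L))
  # length classes are 4/6/8 syllables
  lens <- vapply(strsplit(tr$sequence, " "), length, integer(1))
  expect_equal(sort(unique(lens[tr$length_class == "short"])), 4L)
  expect_equal(sort(unique(lens[tr$length_class == "medium"])), 6L)
  expect_equal(sort(unique(lens[tr$length_class == "long"])), 8L)
})

test_that("structural verification passes for all four default designs", {
  for (d in list(fx_d1n(), fx_d1c(), fx_d2n(), fx_d2c())) {
    v <- verify_design(d)
    expect_true(v$valid)
    expect_length(v$violations, 0L)
  }
})

test_that("A-syllable occupancy is exactly uniform per position and length", {
  d <- fx_d1n()
  tr <- d$trials
  for (lc in c("short", "medium", "long")) {
    rows <- tr$phase == "learning" & tr$length_class == lc
    n <- tr$n_pairs[rows][1]
    a_parts <- lapply(strsplit(tr$sequence[rows], " "),
                      function(s) s[seq_len(n)])
    for (pos in seq_len(n)) {
      tab <- table(vapply(a_parts, `[`, character(1), pos))
      expect_length(tab, 20L)
      expect_true(all(tab == 4L))  # 80 / 20
    }
  }
})

test_that("no sequence recurs anywhere within a design", {
  for (d in list(fx_d1n(), fx_d2n())) {
    expect_equal(anyDuplicated(d$trials$sequence), 0L)
  }
})

test_that("test labels are sound and Experiment-1 foils follow the other grammar", {
  d <- fx_d1c()
  test <- d$trials[d$trials$phase == "test", ]
  seqs <- strsplit(test$sequence, " ")
  member <- vapply(seqs, is_member, logical(1), dependency = d$group)
  expect_equal(member, test$label == "correct")
  foil <- vapply(seqs[test$label == "incorrect"], is_member, logical(1),
                 dependency = "nested")
  expect_true(all(foil))
})

test_that("designs are byte-identical under identical seeds and differ otherwise", {
  cfg <- agl_config(1, learning_per_length = 20L,
                    test_per_length_per_label = 20L)
  a <- agl_design(1, "nested", seed = 7, config = cfg)
  b <- agl_design(1, "nested", seed = 7, config = cfg)
  c_ <- agl_design(1, "nested", seed = 8, config = cfg)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials$sequence, c_$trials$sequence))
})

test_that("infeasible counterbalance counts are rejected up front", {
  expect_error(agl_config(1, learning_per_length = 75), "divisible")
  expect_error(agl_config(1, test_per_length_per_label = 50), "divisible")
  expect_error(agl_config(2, test_correct = 110), "divisible")
  expect_error(agl_config(2, foils_per_subset = 30), "divisible")
})

test_that("foil templates realize the printed index permutations", {
  lex <- agl_lexicon()
  syl <- function(cls, i) lex[[cls]][i]
  # nested group, S2 variant 1, pairs (1,2,3): A1 A2 A3 B2 B3 B1
  expect_equal(apply_foil_template(1:3, "S2", 1, "nested"),
               c(syl("class_a", 1:3), syl("class_b", c(2, 3, 1))))
  # nested group, S3 variant 1: A1 A2 A3 B3 B1 B2
  expect_equal(apply_foil_template(1:3, "S3", 1, "nested"),
               c(syl("class_a", 1:3), syl("class_b", c(3, 1, 2))))
  # cross-serial group, S2 variant 2: A1 A3 A2 B1 B2 B3
  expect_equal(apply_foil_template(1:3, "S2", 2, "cross-serial"),
               c(syl("class_a", c(1, 3, 2)), syl("class_b", 1:3)))
  expect_error(apply_foil_template(c(1, 1, 2), "S1", 1, "nested"),
               "distinct")
  expect_error(apply_foil_template(1:3, "S2", 3, "nested"), "variant")
})

test_that("every foil template output violates the trained grammar", {
  for (group in dependency_types()) {
    other <- setdiff(dependency_types(), group)
    for (subset in c("S1", "S2", "S3")) {
      for (variant in 1:2) {
        s <- apply_foil_template(c(4, 9, 17), subset, variant, group)
        expect_false(is_member(s, group))
        if (subset == "S1") expect_true(is_member(s, other))
      }
    }
  }
})

test_that("Experiment-2 foil subsets preserve exactly the advertised pair", {
  d <- fx_d2n()
  tr <- d$trials
  ds <- dependency_structure(3, d$group)
  intact <- function(s, link) {
    p <- syllable_pairs(s[c(link$a_pos, link$b_pos)])
    cls <- classify_syllable(s[c(link$a_pos, link$b_pos)])
    cls[1] == "A" && cls[2] == "B" && p[1] == p[2]
  }
  for (i in which(tr$foil_subset == "S2")) {
    s <- strsplit(tr$sequence[i], " ")[[1]]
    expect_true(intact(s, ds[1, ]))
    expect_false(intact(s, ds[3, ]))
  }
  for (i in which(tr$foil_subset == "S3")) {
    s <- strsplit(tr$sequence[i], " ")[[1]]
    expect_true(intact(s, ds[3, ]))
    expect_false(intact(s, ds[1, ]))
  }
  for (i in which(tr$foil_subset == "S1")) {
    s <- strsplit(tr$sequence[i], " ")[[1]]
    expect_false(intact(s, ds[1, ]))
    expect_false(intact(s, ds[3, ]))
  }
})

test_that("verification detects planted defects", {
  d <- fx_d2n()
  # duplicated sequence
  d_dup <- d
  test_rows <- which(d_dup$trials$phase == "test")
  d_dup$trials$sequence[test_rows[1]] <- d_dup$trials$sequence[test_rows[2]]
  v <- verify_design(d_dup)
  expect_false(v$valid)
  expect_true(any(grepl("duplicated", v$violations)))
  # broken S2 foil (first pair no longer intact)
  d_bad <- d
  s2 <- which(d_bad$trials$foil_subset == "S2")[1]
  s <- strsplit(d_bad$trials$sequence[s2], " ")[[1]]
  s[6] <- agl_lexicon()$class_b[syllable_pairs(s[2])]  # last B now pairs A2
  d_bad$trials$sequence[s2] <- paste(s, collapse = " ")
  v2 <- verify_design(d_bad)
  expect_false(v2$valid)
  expect_true(any(grepl("S2", v2$violations)))
  # mislabelled trial
  d_lab <- d
  cor1 <- which(d_lab$trials$label == "correct")[1]
  d_lab$trials$label[cor1] <- "incorrect"
  v3 <- verify_design(d_lab)
  expect_true(any(grepl("unsound", v3$violations)))
})

test_that("standalone phase builders honour the uniqueness bookkeeping", {
  cfg <- agl_config(1, learning_per_length = 20L,
                    test_per_length_per_label = 20L)
  learn <- build_learning_set("nested", seed = 3, config = cfg)
  expect_equal(nrow(learn), 60L)
  test <- build_test_set_exp1("nested", seed = 4, config = cfg,
                              used_sequences = learn$sequence)
  expect_equal(nrow(test), 120L)
  expect_equal(anyDuplicated(c(learn$sequence, test$sequence)), 0L)
  cfg2 <- agl_config(2, learning_per_length = 20L, test_correct = 40L,
                     foils_per_subset = 20L)
  t2 <- build_test_set_exp2("cross", seed = 5, config = cfg2)
  expect_equal(nrow(t2), 100L)
  expect_equal(sum(t2$foil_subset == "S2"), 20L)
})
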