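#' The embedded syllable lexicon
#'
#' The stimulus vocabulary is a fixed table of 20 syllable pairs. Each pair
#' couples one category-A syllable (vowel 'e' or 'i') with one category-B
#' syllable (vowel 'o' or 'u'); the shared `pair_id` is the dependency
#' identity used by both grammars. Pair membership is resolved by table
#' lookup, never by comparing initial letters: the table contains
#' onset-ambiguous entries (e.g. "sek" and "sted" both start with "s"), so
#' prefix matching would be unsafe.
#'
#' @return A data frame with columns `pair_id` (integer 1..20), `class_a`
#'   and `class_b` (character syllables).
#' @examples
#' lex <- agl_lexicon()
#' nrow(lex)          # 20
#' lex$class_a[1]     # "del"
#' @export
agl_lexicon <- function() {
  data.frame(
    pair_id = 1:20,
    class_a = c("del", "sted", "bem", "jelz", "pfes", "schip", "riw", "fid",
                "hiz", "zib", "lef", "sek", "kem", "pegs", "wel", "tix",
                "miv", "nist", "xim", "gid"),
    class_b = c("dol", "stod", "bom", "jolz", "pfos", "schop", "row", "fod",
                "hoz", "zob", "luf", "suk", "kum", "pugs", "wul", "tux",
                "muv", "nust", "xum", "gud"),
    stringsAsFactors = FALSE
  )
}

#' The two dependency types
#'
#' `"nested"` arranges the B half in reverse pair order (mirror pattern,
#' A1 A2 A3 B3 B2 B1; characteristic of context-free languages);
#' `"cross-serial"` keeps the B half in the same pair order (copy pattern,
#' A1 A2 A3 B1 B2 B3; characteristic of mildly context-sensitive languages).
#'
#' @return Character vector of the two canonical names.
#' @export
dependency_types <- function() c("nested", "cross-serial")

#' Normalise a dependency-type name
#'
#' Accepts the canonical names plus the short alias `"cross"`.
#' @param dependency Character scalar.
#' @return `"nested"` or `"cross-serial"`.
#' @keywords internal
match_dependency <- function(dependency) {
  if (length(dependency) != 1L || !is.character(dependency)) {
    stop("`dependency` must be a single character string", call. = FALSE)
  }
  if (identical(dependency, "cross")) {
    return("cross-serial")
  }
  match.arg(dependency, dependency_types())
}

#' The dependency type an experimental group was NOT trained on
#' @keywords internal
other_dependency <- function(dependency) {
  setdiff(dependency_types(), match_dependency(dependency))
}

# Lookup helper: rows of the lexicon for a vector of syllables, with the
# category each syllable belongs to. Errors on unknown syllables.
.lookup_syllables <- function(syllables, lexicon = agl_lexicon()) {
  ia <- match(syllables, lexicon$class_a)
  ib <- match(syllables, lexicon$class_b)
  unknown <- is.na(ia) & is.na(ib)
  if (any(unknown)) {
    stop("unknown syllable(s): ", paste(unique(syllables[unknown]),
                                        collapse = ", "), call. = FALSE)
  }
  data.frame(
    syllable = syllables,
    category = ifelse(is.na(ia), "B", "A"),
    pair_id  = ifelse(is.na(ia), lexicon$pair_id[ib], lexicon$pair_id[ia]),
    stringsAsFactors = FALSE
  )
}

#' Classify a syllable as category A or B
#'
#' Category membership is signalled by the vowel (A: 'e'/'i', B: 'o'/'u') and
#' resolved by lexicon lookup.
#'
#' @param syllable Character vector of syllables.
#' @param lexicon Lexicon table, as from [agl_lexicon()].
#' @return Character vector of `"A"`/`"B"`.
#' @examples
#' classify_syllable(c("del", "dol"))  # "A" "B"
#' @export
classify_syllable <- function(syllable, lexicon = agl_lexicon()) {
  .lookup_syllables(syllable, lexicon)$category
}

#' Pair identity of syllables
#'
#' @inheritParams classify_syllable
#' @return Integer vector of `pair_id`s.
#' @export
syllable_pairs <- function(syllable, lexicon = agl_lexicon()) {
  .lookup_syllables(syllable, lexicon)$pair_id
}

#' Dependency structure of a sequence template
#'
#' For `n_pairs` dependencies over a 2n-syllable sequence, returns which
#' sequence positions each link connects and how many elements intervene.
#' Links are numbered 1..n, outermost-first for nested dependencies and
#' leftmost-first for cross-serial dependencies; sequence positions are
#' 1-based. Nested link i connects positions (i, 2n - i + 1) with
#' 2(n - i) intervening elements; cross-serial link i connects (i, n + i)
#' with n - 1 intervening elements for every link. With three pairs, the
#' first nested dependency spans four intervening elements while the first
#' cross-serial dependency spans two — the memory-cost asymmetry that
#' locality theories of sentence processing build on.
#'
#' @param n_pairs Number of dependency pairs (>= 1).
#' @param dependency `"nested"` or `"cross-serial"`.
#' @return Data frame with columns `link`, `a_pos`, `b_pos`, `distance`.
#' @examples
#' dependency_structure(3, "nested")$distance        # 4 2 0
#' dependency_structure(3, "cross-serial")$distance  # 2 2 2
#' @export
dependency_structure <- function(n_pairs, dependency) {
  dep <- match_dependency(dependency)
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || n_pairs < 1 ||
      n_pairs != round(n_pairs)) {
    stop("`n_pairs` must be a single integer >= 1", call. = FALSE)
  }
  n <- as.integer(n_pairs)
  i <- seq_len(n)
  if (dep == "nested") {
    b_pos <- 2L * n - i + 1L
    distance <- 2L * (n - i)
  } else {
    b_pos <- n + i
    distance <- rep(n - 1L, n)
  }
  data.frame(link = i, a_pos = i, b_pos = b_pos, distance = distance)
}

#' Complete an A-part into a full grammatical sequence
#'
#' Given the first half of a sequence (category-A syllables with pairwise
#' distinct pair identities), appends the paired category-B syllables in
#' reversed pair order (nested) or identical pair order (cross-serial).
#'
#' @param a_sequence Character vector of category-A syllables.
#' @param dependency `"nested"` or `"cross-serial"`.
#' @param lexicon Lexicon table.
#' @return Character vector of length `2 * length(a_sequence)`.
#' @examples
#' arrange_b_part(c("del", "sted"), "nested")       # del sted stod dol
#' arrange_b_part(c("del", "sted"), "cross-serial") # del sted dol stod
#' @export
arrange_b_part <- function(a_sequence, dependency, lexicon = agl_lexicon()) {
  dep <- match_dependency(dependency)
  info <- .lookup_syllables(a_sequence, lexicon)
  if (any(info$category != "A")) {
    stop("all elements of `a_sequence` must be category-A syllables",
         call. = FALSE)
  }
  if (anyDuplicated(info$pair_id)) {
    stop("duplicate pair identity in `a_sequence`", call. = FALSE)
  }
  b_order <- if (dep == "nested") rev(info$pair_id) else info$pair_id
  c(a_sequence, lexicon$class_b[match(b_order, lexicon$pair_id)])
}

#' Grammar membership of a syllable sequence
#'
#' A sequence belongs to a dependency grammar iff its first half is all
#' category A with pairwise distinct pair identities, its second half all
#' category B, and the B-half pair order matches the dependency pattern
#' (reversed for nested, identical for cross-serial). For `n_pairs = 1` the
#' two grammars coincide. Malformed input (odd length, syllables outside the
#' lexicon) is an error, not a `FALSE`. With a `dummy` syllable supplied, the
#' recognizer accepts the variant with that single filler inserted between
#' the two halves (see [insert_dummy()]).
#'
#' @param sequence Character vector of syllables.
#' @param dependency `"nested"` or `"cross-serial"`.
#' @param lexicon Lexicon table.
#' @param dummy Optional dummy syllable; when given, sequences must carry it
#'   (exactly once, mid-sequence) and it is stripped before the check.
#' @return `TRUE` or `FALSE`.
#' @examples
#' is_member(c("del", "sted", "stod", "dol"), "nested")        # TRUE
#' is_member(c("del", "sted", "stod", "dol"), "cross-serial")  # FALSE
#' @export
is_member <- function(sequence, dependency, lexicon = agl_lexicon(),
                      dummy = NULL) {
  dep <- match_dependency(dependency)
  if (!is.null(dummy)) {
    if (length(sequence) %% 2L != 1L || length(sequence) < 3L) {
      stop("dummy-mode sequences must have odd length >= 3", call. = FALSE)
    }
    mid <- (length(sequence) + 1L) %/% 2L
    if (!identical(sequence[mid], dummy)) {
      return(FALSE)
    }
    sequence <- sequence[-mid]
  }
  if (length(sequence) %% 2L != 0L || length(sequence) < 2L) {
    stop("sequence must have even length >= 2", call. = FALSE)
  }
  info <- .lookup_syllables(sequence, lexicon)
  n <- length(sequence) %/% 2L
  first <- info[seq_len(n), ]
  second <- info[n + seq_len(n), ]
  if (any(first$category != "A") || any(second$category != "B")) {
    return(FALSE)
  }
  if (anyDuplicated(first$pair_id)) {
    return(FALSE)
  }
  want <- if (dep == "nested") rev(first$pair_id) else first$pair_id
  all(second$pair_id == want)
}

#' Insert a dummy syllable at the innermost position
#'
#' Places a filler element between the A half and the B half of a
#' grammatical sequence (A1 A2 A3 D B3 B2 B1 for nested, A1 A2 A3 D B1 B2 B3
#' for cross-serial). This removes the zero-distance innermost dependency of
#' the nested pattern: every link spanning the insertion point gains one
#' intervening element.
#'
#' @param sequence A sequence that is a member of `dependency`.
#' @param dependency `"nested"` or `"cross-serial"`.
#' @param dummy Dummy syllable string.
#' @param lexicon Lexicon table.
#' @return Character vector of odd length `2n + 1`.
#' @export
insert_dummy <- function(sequence, dependency, dummy = "dax",
                         lexicon = agl_lexicon()) {
  dep <- match_dependency(dependency)
  if (!is_member(sequence, dep, lexicon)) {
    stop("`sequence` is not a member of the ", dep, " grammar", call. = FALSE)
  }
  n <- length(sequence) %/% 2L
  append(sequence, dummy, after = n)
}

#' Write / read a lexicon CSV
#'
#' Round-trippable CSV with columns `pair_id`, `class_a`, `class_b`. Writing
#' the embedded default reproduces the canonical table exactly.
#'
#' @param lexicon Lexicon table.
#' @param path File path.
#' @return `read_lexicon` returns the lexicon data frame; `write_lexicon`
#'   returns `path` invisibly.
#' @export
write_lexicon <- function(lexicon = agl_lexicon(), path) {
  utils::write.csv(lexicon, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "class_a", "class_b")
  if (!all(need %in% names(lex))) {
    stop("lexicon CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  lex <- lex[need]
  validate_lexicon(lex)
  lex
}

#' Validate a lexicon table
#'
#' Checks the structural invariants: 20 pairs, 40 distinct syllables, one A
#' and one B syllable per pair, and the vowel-category rule (A syllables
#' contain 'e' or 'i', B syllables 'o' or 'u').
#'
#' @param lexicon Lexicon table.
#' @return The lexicon, invisibly; errors on violation.
#' @export
validate_lexicon <- function(lexicon) {
  if (nrow(lexicon) != 20L) {
    stop("lexicon must contain exactly 20 pairs", call. = FALSE)
  }
  all_syll <- c(lexicon$class_a, lexicon$class_b)
  if (anyDuplicated(all_syll) || anyDuplicated(lexicon$pair_id)) {
    stop("lexicon syllables and pair_ids must be distinct", call. = FALSE)
  }
  bad_a <- !grepl("[ei]", lexicon$class_a) | grepl("[ou]", lexicon$class_a)
  bad_b <- !grepl("[ou]", lexicon$class_b) | grepl("[ei]", lexicon$class_b)
  if (any(bad_a) || any(bad_b)) {
    stop("vowel-category rule violated (A: e/i, B: o/u)", call. = FALSE)
  }
  invisible(lexicon)
}
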