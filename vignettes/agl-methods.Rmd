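---
title: "Methods: stimulus designs, simulated observers, and the signal-detection battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus designs, simulated observers, and the signal-detection battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aglsdt)
```

## The paradigm and its formal core

Two artificial grammars are defined over a lexicon of 20 syllable pairs.
Each pair couples a category-A syllable (vowel *e* or *i*) with a
category-B syllable (vowel *o* or *u*); the pair identity is the
dependency. A grammatical sequence consists of an A half followed by a B
half. The **nested** grammar mirrors the pair order
(A₁A₂A₃B₃B₂B₁), giving center-embedded dependencies of the context-free
kind; the **cross-serial** grammar copies it (A₁A₂A₃B₁B₂B₃), the pattern
that pushes a language beyond context-free into the mildly
context-sensitive class. For one pair (length 2) the grammars coincide;
for two or more distinct pairs their realizations of the same A half are
distinct strings, and each is a member of exactly its own grammar — the
package checks this exhaustively over a reduced lexicon in its tests.

`dependency_structure()` records which positions each dependency links and
how many elements intervene. With three pairs the first nested dependency
spans four intervening elements while every cross-serial dependency spans
two; summed over links both grammars carry n(n − 1) intervening elements.
These distances are what memory-based (locality) accounts of processing
difficulty operate on, and they are the package's worked structural
quantities. Positions are reported 1-based, the natural indexing in R;
link numbering is outermost-first for nested and leftmost-first for
cross-serial structures, matching the subscripts conventionally used for
these patterns.

Pair identity is resolved by explicit table lookup rather than by the
shared initial letter that motivates the lexicon's construction: the table
contains onset-ambiguous entries ("sek" vs "sted"), so prefix matching
could misclassify. The shared-onset property is treated as descriptive.

## Design generation

**Counterbalancing.** Each design cell (e.g. the 80 medium learning
trials) draws its A half from per-position multisets containing every
A syllable exactly `count / 20` times, shuffled under the design seed.
This makes per-position occupancy exactly uniform by construction. Rows
that violate a constraint — a pair repeated within one sequence, or a
realized sequence colliding with any other sequence in the design — are
repaired by swapping single entries between rows *within a column*, which
preserves the column multisets and hence the counterbalance. Swaps are
accepted only when they strictly reduce a badness score (number of surplus
duplicate pairs, plus one for a string collision), so rows needing several
repairs converge stepwise and the loop cannot cycle; an attempt cap turns
pathological configurations into an explicit generation error rather than
a hang. Because the B half is a deterministic function of the A half and
the grammar, B-side occupancy is whatever the grammar induces — uniform
for cross-serial, slightly uneven across positions for nested — which is a
consequence of the construction, not a target.

**Within-sequence pair repetition is forbidden.** The source materials
never show a repeated pair inside one sequence and the foil templates
index three distinct pairs, but the rule is nowhere stated explicitly; we
adopt the prohibition as an interpretation and apply it uniformly
(constructor, recognizer, generators). A sequence with a repeated pair is
treated as a non-member, not as malformed input.

**Uniqueness and phases.** Every sequence occurs at most once across the
entire design (learning plus test). Both phases are counterbalanced with
the same machinery; the general stimulus description arguably scopes the
counterbalance claim to all phases, and balancing the test phase only
removes a potential confound. Test A halves may coincide with learning A
halves only when realized under the other grammar, since uniqueness is
enforced at the full-sequence level.

**Defaults.** Learning: 240 sequences, 80 per length class (4/6/8
syllables = 2/3/4 pairs), 25% repeat probes (exactly 60; probes are
flagged but never analysed, matching the source procedure where they only
monitor alertness). Experiment-1 test: 360 sequences, 180 per label, 60
per length × label cell; every incorrect sequence is a member of the
untrained grammar. Experiment-2 test: 240 medium sequences, 120 correct,
and 40 foils in each of three subsets built from the printed templates —
S1 (untrained-grammar members), S2 (trained rule violated, first
dependency pair intact), S3 (last pair intact). The two printed template
variants per subset are used exactly 20 times each. At the string level
the two variants of a subset can realize the same residual pattern (for
the nested S2 templates, both amount to a rotation of the B half relative
to the realized A half), so variant balance is a construction-level
property rather than one recoverable from the output sequences.

**Trial order.** Experiment-1 designs carry one seeded presentation order
shared by all simulated participants; Experiment-2 cohorts draw a fresh
seeded order per participant. Both choices mirror the respective
procedures, and order is exposed as an argument for non-default use.

`verify_design()` recomputes all of these properties from the finished
trial list and reports violations as data rather than errors, so a design
read back from CSV can be audited identically.

## Simulated observers

The package deliberately contains no trial-by-trial learning model; the
simulants exist to give the analysis chain inputs with known ground truth.

- **`sdt_learner`** is the matched generative model for the analysis: an
  equal-variance Gaussian observer saying yes with probability
  Φ(d′/2 − c) on members and Φ(−d′/2 − c) on foils, independently across
  trials. `sensitivity` is the process d′ (dimensionless; 0 = chance);
  `criterion` c biases toward no (> 0) or yes (< 0). An optional
  `learning_slope` adds that amount of sensitivity per test block
  (default 0), enough to exercise the block analysis without committing
  to a learning mechanism.
- **Strategists** answer yes iff one inspected dependency pair of the
  trained grammar is intact — the first link (outermost/leftmost) or the
  last. They are deterministic and order-independent. On the Experiment-1
  design the first-pair strategist scores 100%, which is precisely the
  leak that motivates the Experiment-2 foils; there it accepts all 40 S2
  foils and rejects S1/S3, for 200/240 accuracy.
- **Guessers** say yes with fixed probability `yes_rate`, independent of
  content; expected d′ is 0 at any rate, with the criterion absorbing the
  bias.

Cohorts derive per-participant child seeds from one master seed, so all
simulation is exactly reproducible. What the simulants do **not** emulate:
reaction times, fatigue, sequence-similarity gradients, memorization of
individual items, or any interaction between the learning phase content
and test behaviour. Passing tests therefore validate the *pipeline* —
design correctness, estimator calibration, diagnostic power — not any
claim about human learners.

## The analysis battery

**Sensitivity.** d′ = Φ⁻¹(H) − Φ⁻¹(F), criterion = −(Φ⁻¹(H) + Φ⁻¹(F))/2,
with 0.5 added *unconditionally* to hits, misses, false alarms and
correct rejections before forming rates. The unconditional correction
(rather than only-when-zero) keeps the estimator identical across
participants at the cost of a small shrinkage toward 0; with 120 + 120
scored trials the bias is well under the sampling noise, and the tests
verify recovery of the generating sensitivity within three standard
errors at cohort and large-n scales.

**Strategy-restricted sensitivity.** d′\_first (and d′\_last) use the hit
rate from *all* correct trials and the false-alarm rate from only the S2
(resp. S3) foils. The restricted quantity is described in the source only
as an "error rate"; since correct trials have no subset structure, holding
the hit side fixed is the only reading that yields a well-defined d′, and
it is the one implemented.

**Group tests.** One-sample t against 0 with Cohen's d = mean/sd per
group; pooled-variance independent t between groups (the df conventions
28 = 15 + 15 − 2 and 38 = 20 + 20 − 2 imply pooling, which we adopt).

**Mixed ANOVA.** The 2 (grammar) × 3 (block or length) split-plot sums of
squares are computed directly; partial η² = SS_effect/(SS_effect +
SS_error) uses each effect's own error term. Greenhouse–Geisser ε is
computed from the pooled within-group covariance of the repeated measures
via orthonormal contrasts, clamped to [1/(k − 1), 1], and applied whenever
the within factor has ≥ 3 levels; corrected dfs are ε·df and uncorrected
values are reported alongside. With k = 2 sphericity is vacuous and
ε = 1 exactly. If an effect's SS is numerically zero the F ratio is 0/0;
we report F = 0, p = 1, η² = 0 — the natural reading of "no effect" for
degenerate inputs such as all-equal cells. Follow-up 2 × 2 ANOVAs on all
level pairs are run without multiplicity adjustment by default (matching
the source analyses); `bonferroni = TRUE` multiplies follow-up p-values by
the family size. The implementation is cross-checked in the test suite
against `stats::aov` (sums of squares, F) and `car::Anova` (ε, corrected
p) to 1e-8 on seeded fixtures.

**Strategy diagnostics.** For each foil subset, an exact binomial test of
the yes count against 0.5, one-sided toward excess yes — the question is
whether a participant said yes *more* often than chance on
strategy-consistent foils, so the upper tail is the only relevant one
(the sidedness is not stated in the source; we document the choice).
A participant is flagged for the first-pair (last-pair) strategy iff the
S2 (S3) test is significant while the S1 yes-bias control is not. A pure
strategist yields 40/40 yes on its subset (p = 2⁻⁴⁰) and is flagged with
certainty; an unbiased guesser is flagged at below the nominal α
(≈ 0.039 per strategy at n = 40, α = .05, by the discreteness of the
exact test). `full_report()` reruns the group tests excluding flagged
participants, mirroring the source's sensitivity analysis.

## Numerical and interface choices

- All randomness flows through explicit integer seeds
  (`withr::with_seed`), so designs, cohorts and reports are byte-stable;
  the global RNG state is never disturbed.
- Sequences serialize as space-separated syllables in CSV; designs pair a
  trial CSV with a config JSON so a design can be audited and re-analysed
  without the generating session.
- Malformed inputs fail loudly and early: unknown syllables, odd-length
  sequences, misaligned response logs, non-divisible counterbalance
  counts, unbalanced ANOVA inputs and schema violations are errors (with
  row/field diagnostics for files), while design audits return violation
  reports instead of throwing.

## Problem sizes in the test suite

The suite exercises full-size default designs (600 and 480 trials),
cohorts of 15–40 participants, large-n estimator checks at 10⁵ trials,
and 10⁴-replicate Monte-Carlo calibration of the strategy diagnostics;
exhaustive grammar enumeration uses a 5-pair reduced lexicon up to 4
dependencies. These sizes were chosen to make binomial sampling error
small relative to the tolerances tested (three standard errors
throughout) while keeping the suite comfortably fast.

## Known limitations

- No generative model of human learning: simulants are measurement-model
  observers, so the package can calibrate and power the analysis chain
  but cannot predict empirical effect sizes.
- The repair-based counterbalancer guarantees exact A-side uniformity but
  only grammar-induced regularity on the B side (exact for cross-serial).
- Audio, timing and presentation-software concerns are out of scope;
  syllable durations would be metadata only.
- The binomial strategy flags inherit the discreteness of exact tests at
  n = 40: their realized false-positive rate sits below the nominal α.
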