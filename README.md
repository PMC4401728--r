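# aglsdt

Artificial grammar learning (AGL) experiments ask whether people can induce
a syntactic rule from exposure to meaningless symbol sequences. A central
contrast is between **nested dependencies** (mirror order,
A₁A₂A₃B₃B₂B₁ — the signature of context-free languages) and **cross-serial
dependencies** (copy order, A₁A₂A₃B₁B₂B₃ — the signature of mildly
context-sensitive languages). If the Chomsky Hierarchy tracked cognitive
difficulty, cross-serial patterns should be harder to learn; locality-based
memory accounts predict the opposite, because the first nested dependency
at n = 3 spans four intervening elements while every cross-serial
dependency spans only two.

`aglsdt` is a complete, tested pipeline for this paradigm, aimed at
researchers designing or power-analysing such studies:

- **Stimulus designs.** A fixed lexicon of 20 syllable pairs (category A
  marked by vowels e/i, category B by o/u, pairing by shared identity);
  counterbalanced learning sets (240 sequences, 80 per length 4/6/8, every
  A syllable exactly 4× per position, 25% repeat probes); a test phase of
  360 trials (180 trained-grammar members, 180 other-grammar members) for
  Experiment 1, or 240 medium-length trials for Experiment 2 whose 120
  foils split into three subsets: S1 (other grammar), S2 (violations that
  preserve the *first* dependency pair) and S3 (preserving the *last*
  pair). S2/S3 exist because a responder tracking a single pair — a
  regular-language shortcut — scores 100% on the Experiment-1 test; the
  subsets make that strategy detectable.
- **Simulated observers.** Equal-variance Gaussian signal-detection
  learners with sensitivity d′ and criterion c
  (P(yes | member) = Φ(d′/2 − c), P(yes | foil) = Φ(−d′/2 − c)),
  deterministic first-/last-pair strategists, and yes-biased guessers;
  reproducible cohorts with per-participant seeds and (for Experiment 2)
  per-participant presentation orders.
- **Analysis battery.** Sensitivity d′ = Φ⁻¹(H) − Φ⁻¹(F) with an
  unconditional +0.5 added to hits, misses, false alarms and correct
  rejections; d′ per test block and per sequence length; strategy-restricted
  d′_first / d′_last; one-sample and pooled-variance independent t-tests
  with Cohen's d; 2×3 mixed ANOVAs with Greenhouse–Geisser ε, corrected
  fractional dfs and partial η²; and per-participant exact one-sided
  binomial tests on each foil subset (a participant is strategy-flagged iff
  S2 or S3 is significant while the S1 yes-bias control is not), with a
  sensitivity rerun excluding flagged participants.

## Worked example

```r
library(aglsdt)

design_nested <- agl_design(experiment = 2, group = "nested",       seed = 42)
design_cross  <- agl_design(experiment = 2, group = "cross-serial", seed = 43)
print(design_nested)
#> AGL design: experiment 2 | trained grammar: nested | seed: 42
#>  learning: 240 trials ( 60 repeat probes )
#>  test:     240 trials; 120 correct / 120 incorrect
#>  foils:    S1=40 S2=40 S3=40

logs <- simulate_cohort(list(design_nested, design_cross), n_per_group = 20,
                        policy = c("first_pair_strategist",
                                   rep("sdt_learner", 19)),
                        sensitivity = 1.2, master_seed = 7)
report <- full_report(logs, list("nested" = design_nested,
                                 "cross-serial" = design_cross))
print(report)
#> AGL analysis report (experiment 2 )
#>  participants: 40 in groups: nested, cross-serial
#>
#>  d' vs chance (0):
#>   nested: t(19) = 12.77, p = 8.947e-11, d = 2.86
#>   cross-serial: t(19) = 13.16, p = 5.37e-11, d = 2.94
#>   between groups: t(38) = -0.02, p = 0.9819
#>
#>  2x3 mixed ANOVA (block): within F(1.71, 64.87) = 0.07, p = 0.9044, pes = 0.00
#>
#>  strategy-flagged participants: nested_01, cross_serial_01
```

Both simulated groups sit far above chance (d′ = 0 is chance; the t-tests
use df = n − 1 = 19), the groups do not differ (the learners share one
generating sensitivity, 1.2), there is no block trend (flat sensitivity),
and the one embedded first-pair strategist per group is exactly the
participant flagged by the binomial diagnostics. `verify_design()`
recomputes every structural promise of a design (counts, uniqueness,
label soundness, counterbalance, foil-pair preservation) and reports
violations instead of throwing.

A thin command-line front end covering design / verify / simulate /
analyze lives at `inst/cli/agl.R`:

```sh
Rscript inst/cli/agl.R design --experiment 2 --group nested --seed 7 \
        --out trials.csv --config config.json
```

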