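---
title: "Two-locus scale-pattern genetics: model, inference and the rheostat simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-locus scale-pattern genetics: model, inference and the rheostat simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carpscales)
```

## The genetic model

Scale cover in common carp is controlled by two unlinked loci. The S locus
(a fibroblast growth factor receptor paralog) carries a dominant wild-type
allele S and a partial loss-of-function allele s; the second locus carries a
recessive wild-type n and a dominant-acting mutant N whose molecular
identity is unknown. The phenotype map of the **standard model** is:

| genotype | phenotype |
|----------|-----------|
| S_ nn    | scaled    |
| S_ Nn    | linear    |
| ss nn    | scattered (mirror / irregular) |
| ss Nn    | nude      |
| any NN   | lethal before hatching |

Because the loci sit on different chromosomes, gametes assort independently
and every cross probability is an exact fraction with denominator dividing
16. `carpscales` therefore carries all transmission arithmetic as integer
numerators over a common denominator (`phenotype_dist`), reducing by gcd and
converting to floating point only when printing. This is not pedantry: the
survivor-conditioned nude fraction of a nude × nude cross is exactly 2/3,
and tests of downstream code should compare against that, not 0.6667.

Survivor conditioning (`condition_on_survival()`) removes the lethal mass
and renormalises, again exactly; it is idempotent, and it is the bridge
between zygote-level expectations (how published tables present them) and
what is countable in a tank of hatched fry.

The model predicts only the aggregate *scattered* class. The mirror vs
irregular presentation is applied afterwards at the observation layer —
either as a Bernoulli split with probability `scattered_split` (default 0.5,
a free parameter: the genetics provides no rule for it), or mechanically by
the rheostat simulator (below). The two mechanisms are never mixed in one
run.

## Variant allele hypotheses

Two single-change variants of the phenotype map capture the mechanisms
proposed for crosses that deviate from the classical ratios:

* **weak-N** (`weak_n_model()`): NN is viable with a nude phenotype and
  *nothing else changes*. No cross has a lethal class; a nude × nude cross
  yields nude 3/4, scattered 1/4 among all offspring.
* **strong-s** (`strong_s_model()`): a third S-locus allele s\* causes
  complete loss of function, so `ss*` and `s*s*` fish are nude-like
  regardless of the N locus; NN lethality is unchanged.

These parameterizations are deliberately minimal. The verbal versions of
both hypotheses in the literature are looser — e.g. a weak-N heterozygote
might plausibly look scattered rather than nude — but minimal
parameterizations keep each hypothesis identifiable as a single change to
the standard map, and the ranking machinery accepts any `allele_model` a
user cares to define.

## Inference

Observed crosses are count vectors over the five observable categories
(scaled, linear, irregular, mirror, nude); the lethal class is invisible.
Published tables print percentages and a total, so `reconstruct_counts()`
inverts that: nearest integer per category, residual absorbed by the
largest category, total preserved exactly.

`rank_parent_hypotheses()` enumerates, for each registered allele model,
every genotype pair compatible with the recorded parental phenotypes,
groups pairs with identical offspring distributions into equivalence
classes (SSnn × SSnn and SSnn × Ssnn are indistinguishable from offspring
phenotypes — the class lists both), and scores each class by the multinomial
log-likelihood of the observed counts under the survivor-conditioned
expectation. The multinomial coefficient is included so values are
comparable across reports; rankings are unaffected by it. Ties keep
registration order, which is reported.

By default, irregular and mirror counts are pooled against the model's
aggregate scattered probability (`merge_scattered = TRUE`) because the
genetic model predicts only the aggregate; the unmerged path (splitting the
model's scattered mass by `scattered_split`) exists for when that split is
itself under study.

Goodness of fit uses the Pearson chi-square with df = categories − 1,
dropping categories that are impossible under the hypothesis *and*
unobserved; an observed count in an impossible category yields an infinite
statistic (p = 0) rather than an error, and a single-category comparison is
a degenerate perfect fit (df 0, p NA). An exact multinomial test
(enumeration of all outcome tables, summing the probability of every table
no more probable than the observed one) is available for ≤ 4 categories and
n ≤ 500; enumeration beyond ~2 × 10^6 tables is refused. The survival
comparison is a pooled-variance Student's t-test — matching how such
comparisons are conventionally reported — with Welch behind
`var_equal = FALSE`.

## Phenotype scoring

Fin defects are scored per fish on a cumulative scale over seven fins
(dorsal, caudal, anal, paired pectorals, paired pelvics — the inventory that
per-fin-type breakdowns of such data use): absent 1, stunted 0.75, reduced
0.5, slightly reduced 0.25, normal 0 points, so scores are multiples of
0.25 in [0, 7] and monotone in any single fin's state. Pharyngeal teeth are
counted 0–10 (ten is the full complement counted in fully scaled fish).
Group summaries report mean/SD/n (plus the toothless fraction for teeth,
since the most severe nudes lack teeth entirely) and all pairwise Student's
t-tests, unadjusted as such comparisons are conventionally presented, with
a Holm-adjusted column alongside.

## The rheostat simulator

The simulator realises the dose/threshold reading of the phenotype series:
a scale-inducing signal varies over the body surface, genotypes attenuate
it, and a scale forms wherever the attenuated signal clears a fixed
threshold. Of the two equivalent parameterizations — falling signal with
fixed threshold, or fixed signal with rising threshold — the falling-signal
form is implemented; they produce identical maps.

**Signal profile.** A 100 × 30 grid (dorso-ventral positions × head-to-tail
columns). Three rows are privileged: the dorsal-fin line (row 12, baseline
4.5), the lateral line (row 50, baseline 2.28) and the belly line (row 88,
baseline 4.2); the dorsal and ventral lines are the global maxima, matching
where scales persist in severely descaled fish. Flank positions get
baseline values from a piecewise-linear quantile function fed by a
golden-ratio low-discrepancy sequence — deterministic, no RNG — with knots
at cumulative fractions (0, 0.45, 0.68, 0.78, 0.92, 1) mapping to baselines
(1.28, 1.82, 2.70, 2.857, 3.00, 3.30). None of these constants is measured
anywhere; they are free parameters chosen once so that the default
attenuations reproduce the four classical phenotype classes (next
paragraph), and all are configurable.

**Attenuation and classification.** Default attenuations: scaled classes
1.0, linear 0.55, scattered (ssnn) 0.35, nude 0.12, with a per-fish
lognormal signal multiplier (sdlog 0.06) and per-position Gaussian noise
(sd 0.08). The flank quantile knots place the ssnn class exactly at the
classification boundary between irregular (coverage > 25%) and mirror
(dorsal + ventral lines only, coverage ≤ 25%), so the per-fish multiplier —
not a coin flip — decides the presentation, with a median fish sitting on
the boundary (≈ 50/50 split). Classification itself is rule-based, mirroring
photographic scoring: coverage ≥ 95% → scaled; dorsal line ≥ 80% complete
with a populated lateral line (≥ 60%) over non-dense flanks → linear;
dorsal + ventral lines with an empty lateral line at ≤ 25% coverage →
mirror; ≤ 5% coverage → nude; anything else → irregular. Nude sub-typing is
phenomenological (the genetics of the sub-types is unknown): residual
scales → nude1, otherwise total fin loss separates nude3 from nude2.

**Dose-coupled side phenotypes.** Teeth are Binomial(10, p) with logit(p)
interpolated in the effective attenuation through knots (0.12, 0.35, 1.0) →
(−3.32, 0.847, 2.586). The knots are calibration constants targeting the
published Singapore gradient (scaled ≈ 9.3, scattered ≈ 7, nude < 1 with
~70% toothless); interpolation is used rather than a single logit slope
because that three-point gradient is not logit-linear in attenuation, and a
quadratic fit would break monotonicity near full signal. Per-fin severity
is Binomial(4, q)/4 over the five fin states with logit(q) knots (0.12,
0.33, 0.37, 1.0) → (0.588, −1.578, −2.05, −4.6), targeting mean fin scores
≈ 4.5 (nude), ≈ 1.2 (mirror), < 1 (irregular), ≈ 0 (scaled). Both knot sets
live in `rheostat_params()`, not in code.

**What the generator does and does not emulate.** It reproduces the
transmission ratios exactly (gamete sampling), the direction and rough
magnitude of the fin/teeth gradients, pre-hatching loss of NN zygotes
(counted separately, never observed), and an irregular/mirror split driven
by signal dose. It does not model scale placode development, growth,
cannibalism-driven loss of weak nude fry after hatching (a documented
source of nude deficits in real tanks, noted as a caveat rather than
modelled), parental effects, or linkage — so passing tests demonstrate
internal consistency of the model chain, not fidelity to any particular
real cohort.

## Numerical and design choices

* Exact integer arithmetic for all transmission probabilities; floats only
  at reporting boundaries and in the observation layer.
* Genotype strings are canonicalised (S before s before s\*, N before n), so
  `"nNsS"` and `"SsNn"` are the same genotype; pair labels sort with C
  collation for locale independence.
* Equivalence classes of parent pairs are reported with all members listed,
  never collapsed to a representative.
* `simulate_cross()` takes an explicit seed and is reproducible byte for
  byte; the split observation layer exists because category-level studies
  (e.g. recovery simulations) do not need 3,000-cell scale maps per fish.
* Simulation study sizes used by the packaged tests and analysis scripts —
  n = 4,000 for transmission consistency, 5 cross types × 100 replicates at
  n = 300 for genotype recovery, 2,000 replicates at n = 200 for the
  chi-square calibration check — were chosen to keep Monte-Carlo error well
  below the effect sizes under test while running in seconds.

## Known limitations

* The two variant models are single-change parameterizations; richer
  variants (dose-dependent weak-N heterozygotes, s\* over the N locus
  interactions) are expressible only as new phenotype maps.
* Genotype inference is maximum-likelihood over discrete classes; no
  posterior uncertainty is attached (a deliberate non-goal).
* Survivor counts alone barely discriminate standard from weak-N for a
  nude × nude cross (2/3 vs 3/4 nude); egg-survival data carries the
  decisive signal, which is why `compare_survival()` exists alongside the
  ranking.
* The published per-fish fin/teeth records behind the group means are not
  deposited, so scoring functions are exercised on simulated cohorts; the
  packaged 19-cross table carries only what the publication printed.
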