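# carpscales

Transmission genetics of scale-pattern inheritance in common carp
(*Cyprinus carpio*), for geneticists and aquaculture researchers who work
with crossing data from scale-cover variants.

## The model

Scale cover in carp follows a classical two-locus, four-allele system. The
dominant **S** allele maintains scale formation; **ss** homozygotes lose most
body cover (the *scattered* class, comprising the *mirror* and *irregular*
presentations). One dose of the mutant **N** allele strips the remainder —
**ssNn** fish are *nude* (leather) carp, with reduced pharyngeal teeth and
frequent fin defects — while **NN** homozygotes die before hatching. With
unlinked loci, a double-heterozygote cross SsNn × SsNn therefore yields

> scaled 3/16 : linear 6/16 : scattered 1/16 : nude 2/16 : lethal 4/16,

and a nude × nude cross (ssNn × ssNn) yields 25% scattered : 50% nude : 25%
lethal at the zygote level, i.e. 33% : 67% among survivors.

The package provides:

* **Exact transmission genetics** — gamete and cross distributions as exact
  fractions, Punnett squares, survivor conditioning, and enumeration of the
  parental genotype classes compatible with any pair of observed phenotypes
  (`cross_distribution()`, `punnett_table()`, `condition_on_survival()`,
  `expected_for_cross_type()`).
* **Variant allele hypotheses** — a "weak-N" model (NN viable and nude, no
  lethal class) and a "strong-s" model (a third S-locus allele `s*` whose
  carriers `ss*`/`s*s*` are nude-like), motivated by crosses that deviate
  from the classical ratios (`weak_n_model()`, `strong_s_model()`).
* **Inference** — count reconstruction from printed percentages, Pearson and
  exact multinomial goodness of fit, multinomial-likelihood ranking of
  genotype/model hypotheses, and a pooled-variance survival comparison
  (`goodness_of_fit()`, `rank_parent_hypotheses()`, `compare_survival()`).
* **Phenotype scoring** — the cumulative per-fish fin-defect scale (absent
  1, stunted 0.75, reduced 0.5, slightly reduced 0.25 points per fin over
  seven fins) and pharyngeal teeth-count summaries with pairwise contrasts
  (`fin_defect_score()`, `group_score_summary()`, `teeth_summary()`).
* **A rheostat simulator** — a signal × threshold model of scale placement:
  a graded signal over the body surface, peaking along the dorsal-fin and
  belly lines, is attenuated by genotype; scales form where the attenuated
  signal clears a threshold. Simulated fish get scale maps, categories,
  dose-coupled teeth counts and fin states (`signal_profile()`,
  `simulate_scale_map()`, `classify_scale_map()`, `simulate_cross()`).
* **A packaged 19-cross table** (`table2_crosses()`) with observed category
  percentages and verbatim published expectation strings.

## Worked example

```r
library(carpscales)

# Expected offspring of a nude x nude cross, and the survivor view
d <- cross_distribution("ssNn", "ssNn")
d
#>   category numerator denominator probability percent
#>  scattered         1           4        0.25     25%
#>       nude         2           4        0.50     50%
#>     lethal         1           4        0.25     25%
condition_on_survival(d)
#>   category numerator denominator probability percent
#>  scattered         1           3   0.3333333  33.33%
#>       nude         2           3   0.6666667  66.67%

# A Hungarian nude x nude cross: 13% mirror / 87% nude among 208 offspring
oc <- observed_cross("26nu.nu", c("nude", "nude"),
                     reconstruct_counts(208, c(mirror = 13.0, nude = 87.0)))
goodness_of_fit(oc, condition_on_survival(d))
#> <gof_result> chi-square
#>   X-squared = 38.77, df = 1, p = 4.764e-10
```

The cross is overwhelmingly incompatible with the 33%/67% survivor
expectation — too many nudes and no early loss, the signature that motivates
the weak-N hypothesis. Ranking all three allele models:

```r
rank_parent_hypotheses(oc, list(standard_model(), weak_n_model()))[1:2, ]
#>   rank    model class_id  hypothesis    loglik
#> 1    1   weak-N        4 ssNn x ssNn -11.70852
#> 2    2 standard        1 ssNn x ssNn -25.25984
```

The weak-N parameterization (nude 3/4 among all offspring, nothing lost)
fits the 87% nude observation far better than the standard survivor
expectation of 2/3.

## Analysis workflow

The `analysis/` scripts re-run the package's studies end to end, writing
tables under `results/`:

1. `01_expectations.R` — exact expectations for every cross type, including
   the two published linear × mirror expectation cells that Punnett
   arithmetic cannot produce.
2. `02_table2_gof.R` — goodness of fit and hypothesis ranking for the 19
   packaged crosses.
3. `03_survival.R` — simulated carrier-vs-control egg-survival comparison
   under the standard and weak-N models.
4. `04_rheostat_cohort.R` — a simulated cohort's fin-defect and teeth
   gradients, plus representative scale maps.
5. `05_parameter_recovery.R` — genotype-class recovery from offspring counts
   and the standard-vs-weak-N discrimination limit.

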