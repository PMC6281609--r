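---
title: "Validating a quantitative trait gene: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a quantitative trait gene: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtgtest)
```

This vignette is the package's own account of the statistics it implements:
the generative model behind the simulators, the three analysis stages
(mixed-model adjustment, the quantitative complementation test, the causal
inference test), the tunable parameters with their defaults and the reasons
for them, the numerical conventions, and the places where the design was
genuinely open and a choice had to be made.

## The scientific setting

A QTL for a body-composition trait has been fine-mapped to a region
containing a candidate gene, and two engineered strains exist on a common
background: a knockout (KO) strain for the candidate and a subcongenic
strain (SR) carrying the QTL allele. Three designs then bear on whether the
candidate is the quantitative trait gene:

1. **Four-way cross** (KO × its background) × (SR × its background): every
   animal carries one allele at the KO locus and one at the QTL locus, so
   the four genotype classes segregate 1:1:1:1 on a uniform background. If
   the knocked-out locus *is* the QTL, the effect of the QTL allele depends
   on whether the other chromosome carries a functional copy — a KO×QTL
   interaction. Failure to complement (significant interaction) is the
   genetic evidence of identity.
2. **F2 intercross** (KO × background): genotypes segregate 1:2:1 in copies
   of the functional allele; one-way ANOVA, Tukey HSD and trait-group MANOVA
   describe the phenotypic consequences of losing copies.
3. **CIT on a two-genotype subset**: liver transcript abundance of the
   candidate, quantified by qPCR, is tested as the mediator between
   genotype and trait.

## The generative model

`mediation_model()` holds one focal trait \(T\), one transcript \(E\) and
the genotype \(G\) (functional-allele copies), under four topologies:

* causal: \(E = \mu_E + \beta_{GE} G + u_E + \varepsilon_E\),
  \(T = \mu_T + \beta_{ET} E + c(x) + u_T + \varepsilon_T\);
* independent: \(E\) as above, \(T = \mu_T + \beta_{GT} G + c(x) + u_T +
  \varepsilon_T\);
* reactive: \(T\) as in independent, \(E = \mu_E + \beta_{TE}(T - \mu_T) +
  u_E + \varepsilon_E\);
* null: no genotype effect anywhere.

\(u\) are litter random intercepts, \(\varepsilon\) Gaussian residuals, and
\(c(x)\) collects covariate effects (sex, parity, litter size, dissection
body weight). Non-focal traits carry only covariate, litter and residual
structure, so they are non-mediated by construction and serve as negative
controls in every downstream test.

### Default calibration

The defaults were fixed once, from the published group summaries of the
validated obesity-resistance locus, and are not revisited:

| parameter | default | unit | reason |
|---|---|---|---|
| `beta_GE` | 1.13 | fold/copy | one-copy mean 1.00, two-copy mean 2.13 |
| `mu_E` | −0.13 | fold | anchors the one-copy group at 1.00 |
| `sigma_E` | 0.31 | fold | back-derived from the printed SEM 0.09 at n = 12 |
| `beta_ET` | −0.31 | g/fold | gives the ~0.35 g fat contrast and, with the SDs below, a population \(R^2 \approx 0.28\) for \(T\) on \(E\) in the 12-vs-12 subset |
| `sigma_T` | 0.31 | g | back-derived from the printed trait SEM 0.093 at n = 12 |
| `sigma_litter`, `sigma_litter_E` | 0.10 | g, fold | intra-litter correlation ≈ 9%; the studies publish no litter variance, so this is a realism choice |
| `beta_sex` | 0.2 | g | males carry more fat; no genotype-by-sex effect is simulated |
| `beta_bw` | 0.05 | g/g | fat scales with dissection body weight |

Cohort sizes default to the study conditions: 352 four-way animals
(`four_way_design()`), 108 F2 animals with a male excess (`f2_design()`),
and 12 males per genotype in the expression subset.

Because expression is Gaussian on the fold scale, a one-copy animal can in
rare replicates draw a non-positive "true" level. Such a sample is below the
detection limit of the Ct transform (`Ct = baseline − log2(E)`) and is
excluded from the expression subset, exactly as an undetectable qPCR sample
would be; `simulate_ct_panel()` refuses non-positive inputs rather than
silently clamping them.

### What the simulator does and does not emulate

It reproduces Mendelian segregation (1:1:1:1 and 1:2:1, with independent
loci — the two alleles enter from different parents, so no linkage is
modelled), litter structure (round-robin assignment, sizes uniform on the
design's range, parity uniform per litter), correlated longitudinal body
weights, sex effects, and the mediation topologies. It does not emulate
dominance or epistasis beyond the two-locus factorial, genotyping error,
diet phases, maternal genetic effects distinct from the litter intercept,
or skewed trait distributions. Passing tests therefore certify the
statistical machinery under a well-specified Gaussian world, not robustness
to real-data pathologies.

## Trait adjustment

The adjustment stage reproduces the two-stage residualization these studies
use: fit `trait ~ fixed effects (+ body weight) + (1 | litter)` by REML,
subtract the fixed-effect predictions and the predicted (BLUP) litter
effects, and re-center the residuals to overall mean zero. Downstream tests
then run on residuals. This is statistically less efficient than one joint
model per test (uncertainty in the adjustment is ignored), but it is the
procedure the study design prescribes, and it keeps every downstream test
identical across traits.

Fixed effects are screened by backward elimination at the nominal 5% level:
interactions are eligible for removal first, a main effect only once no
retained interaction contains it, each step refitting and using Type III F
tests with Satterthwaite degrees of freedom (`lmerTest`). The published
methods state the 5% rule but no algorithm; interactions-first elimination
is the standard hierarchical choice.

Numerical conventions: REML rather than ML (variance components feed the
fit report, and REML's small-sample bias is smaller); a litter variance
estimated at the zero boundary (detected via `lme4::isSingular`) triggers a
fall-back to the fixed-effects-only least-squares fit, with a warning — at
the boundary the BLUPs are zero anyway, and the fall-back makes that exact.
Parity is treated as categorical and litter size as continuous; the source
methods do not say, and both choices are visible in `model_spec` and
changeable. Whether sex should also be residualized before sex-combined
analysis is likewise unstated; the package leaves sex in the data (default
off) and handles it explicitly in the group tests, because removing a sex
main effect before testing genotype-by-sex structure would be circular.

## Group tests

One-way ANOVA reports the classical decomposition with least-squares means
from the fitted model (not raw group means), so unbalanced groups and an
optional additive sex covariate are handled consistently. Tukey HSD uses
the pooled within-group variance and the Tukey–Kramer standard error under
unequal n; letters come from the insert-and-absorb algorithm, so two groups
share a letter exactly when their pairwise P ≥ α.

MANOVA per trait group fits the multivariate linear model with sum-to-zero
contrasts, takes marginal (Type III) SSCP matrices per term, and computes
all four classical statistics from the eigenvalues of \(E^{-1}H\): Rao's F
for Wilks' Λ, the standard approximations for Pillai and Hotelling–Lawley,
and the upper-bound F for Roy's maximum root. `significance_summary()`
reports both the permissive reading ("significant by at least one
statistic", which is how Roy-only significance is usually quoted) and the
conservative all-four flag. With a single response all four reduce exactly
to the ANOVA F, which the tests assert to 1e-8.

## The complementation call

`classify_complementation()` is deliberately a pure decision rule:
failure-to-complement iff the interaction P < α (default 0.05), a marginal
flag for P in [α, 0.10]. The marginal band mirrors how borderline
interaction P values (e.g. 0.057) are reported in this literature; it never
changes the label, only annotates it. Because many traits are tested at a
nominal α after a MANOVA screen, a few false failures are expected across a
trait panel — the package matches that published workflow and applies no
multiplicity correction by default.

Sex is handled by a screen-then-pool rule: a MANOVA of the full
KO×QTL×sex factorial per trait group; where the three-way interaction is
non-significant by every statistic, the sexes are pooled for the per-trait
two-way ANOVA, otherwise sex and its interactions stay in the model.

## qPCR quantification

`delta_delta_ct()` averages replicate Cts per (sample, gene), forms
ΔCt = Ct_target − Ct_control, and references the calibrator *group's mean*
ΔCt, then rescales by the calibrator group's arithmetic mean so that the
group mean is exactly 1 while per-sample variation (hence a non-zero SEM
for the calibrator) is retained. The published tables report the calibrator
as 1.00 ± SEM, which forces a group-mean convention; whether that mean was
arithmetic or geometric is not stated, and arithmetic was chosen as the
declared convention (a single-reference-sample convention is available via
`convention = "reference_sample"`). Replicate aggregation is the arithmetic
mean of Ct; no outlier-replicate rejection and no amplification-efficiency
correction are implemented.

## The CIT

The component tests are plain conditional regressions with coefficient
t-test P values (`T ~ G`; `E ~ G + T`; `T ~ E + G` read twice, for the E
and the G coefficient), plus the unconditional `E ~ G` association for
reporting. The classification is

* `causal`: p1 < α, p2 < α, p3 < α, p4 ≥ α;
* `causal_marginal`: as above but α ≤ p3 ≤ 0.10;
* `not_causal`: anything else,

with strict inequalities at α — a printed P of exactly 0.050 does not pass,
which is required to reproduce the published 20-trait classification
exactly. Test 4 accepts the null: "G independent of T given E" is evidenced
by a *non-significant* coefficient, which conflates low power with
independence. This caveat is inherent to the plain-regression form and is
the reason the omnibus literature formulates Test 4 as an equivalence test.
The original intersection-union omnibus CIT (one P value as the maximum of
the four, Test 4 via an equivalence bootstrap) is *not* implemented: the
published table this package reproduces is obtainable only with the plain
form, and shipping a second, bootstrap-based decision surface alongside it
would invite silent mixing of the two. The limitation is documented here
instead.

Genotype enters numerically (0/1 in the two-genotype subset). Three-level
factors are rejected with an instruction to supply a numeric coding, since
heterozygote-vs-homozygote contrasts are outside this design's usage.

Litter handling in the CIT follows the residualization reading: expression
and traits are residualized against a litter random intercept (plus the
body-weight covariate for "adjusted" traits) before the component
regressions. The published table's footnote ("adjusted for a litter
effect") is ambiguous between this and including litter in the component
models; `run_cit_study(litter_adjust = "in_model")` provides the
alternative.

### Power under the calibrated regime

The default calibration puts the causal call in a modest-power regime at 12
animals per genotype: the conjunction needs p1 < 0.05 (marginal genotype
effect ≈ 0.35 g against a ≈ 0.39 g trait SD), p3 < 0.05 (partial
expression-trait correlation ≈ 0.3 after conditioning on a genotype that
explains most of the expression variance), and p4 ≥ 0.05. The acceptance
harness measures this power directly (about 0.15–0.25 across runs) and the
analysis driver reports it next to any single-run table, so an empty
12-vs-12 screen is read as one draw from that regime rather than as a
failure of the machinery. The same conjunction makes the false-causal rate
under the independent topology conservative (well below α), which the
type-I suite verifies over 1000 replicates.

A related structural fact, verified in the property tests: conditioning on
expression attenuates the genotype-trait partial correlation by
\(\sqrt{1 - r_{GE}^2}\) even when expression is *not* a mediator, so with a
very strong genotype-expression coupling the independent topology partially
mimics mediation in Test 4. The contrast the CIT exploits is cleanest at
moderate coupling.

## Problem sizes in the test suite

The suite checks exact identities at machine-level tolerances (ANOVA F
against projection-matrix oracles, Tukey P against a numerically integrated
studentized-range distribution, the single-response MANOVA reduction) and
stochastic calibrations at simulation scale: 1000 replicates for the two
type-I rates (four-way cohorts of 352; CIT subsets of 24), 150 replicates
for power and expression-ratio recovery, 100–300 replicates for variance
component and \(R^2\) sampling checks. These sizes give binomial standard
errors of under one percentage point for the type-I rates while keeping the
full suite to a few minutes on one core.

## Known limitations

* Gaussian traits and expression; no heavy tails, no floor effects beyond
  truncation at zero.
* The two-stage residualization propagates no adjustment uncertainty into
  the test statistics.
* Test 4's accept-the-null logic (see above); no equivalence-test mode.
* No multiple-testing correction by default, matching the screened-nominal
  workflow it reproduces.
* Litter assignment is round-robin and independent of genotype; confounded
  litter-genotype designs (e.g. single-genotype litters) will defeat the
  adjustment and are not guarded against beyond the degenerate-design error.
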