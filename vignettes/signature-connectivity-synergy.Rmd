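---
title: "Stage-monotone signatures, significant connectivity mapping and median-effect synergy: methods"
author: "sigconnect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-monotone signatures, significant connectivity mapping and median-effect synergy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconnect)
```

## Scope and rationale

`sigconnect` implements an in-silico drug-repurposing workflow for diseases
with an ordered severity scale, the motivating case being myelodysplastic
syndromes (MDS) progressing through prognostic risk strata to secondary
acute myeloid leukemia (AML). The workflow has three scientific stages —
deriving a gene signature of disease development and progression from a
staged expression cohort, interrogating a perturbagen reference database
for compounds whose expression profile *reverses* that signature, and
quantifying drug-pair interactions of candidate compounds with
Chou–Talalay Combination Indices — plus a synthetic-data layer that plants
known structure so every stage can be validated without access to patient
or compound-screen data.

This vignette documents the models, the parameters that matter, the
numerical conventions, and what the synthetic validation does and does not
establish.

## Signature derivation

**Input.** A normalized log2-scale gene-by-sample matrix (the package
consumes post-normalization data; array preprocessing is out of scope) and
a per-sample stage label whose factor-level order encodes disease
ordering. The default design has five stages (`normal`, `low`, `medium`,
`high`, `AML`) and requires at least two samples per stage.

**Model.** For each gene, a fixed-effects one-way ANOVA across all stages
gives the omnibus F and p-value, computed by vectorized sums of squares
and verified in the test suite against `stats::anova(stats::lm(...))` to
1e-10 relative tolerance. P-values are converted to q-values with
Benjamini–Hochberg step-up FDR control. Separately, the four
adjacent-stage contrasts `mean(stage k+1) − mean(stage k)` are computed;
in a balanced or unbalanced one-factor design these least-squares means
are the plain group means, so "fold change" throughout means a difference
of group means on the log2 scale.

**Monotone filter.** A gene enters the signature substrate when its
omnibus q-value is at or below the threshold (default 0.05) *and* all four
adjacent fold changes are strictly positive (increasing list) or strictly
negative (decreasing list). Strictness matters: a tied pair of stage means
breaks monotonicity and excludes the gene. Strict adjacent monotonicity of
the five stage means implies monotonicity of all ten pairwise stage
comparisons, which the tests assert on filter output. The FDR gate applies
to the omnibus ANOVA only; the adjacent contrasts supply directions, not
additional significance gates.

**Ranking and derivative signatures.** Both lists are ordered by ascending
p-value; ties are broken by the larger absolute first-to-last stage shift
and then lexicographic gene id, so derivation is fully deterministic (the
noise-free cohort, where all planted genes have p = 0, exercises exactly
this path). After optional restriction to the reference set's gene
universe, the top *d* genes per direction for depths 10, 20, 30, 40, 50
form five nested signatures of 20–100 genes. Signed query ranks are
assigned per direction — the most significant increasing gene gets `+d`,
down to `+1`; decreasing genes get the negated ranks. Whether ranks should
be assigned per direction or pooled across both is a genuine convention
gap; the scoring engine is deliberately agnostic (it accepts any nonzero
signed-rank multiset), so either convention scores correctly.

**Degenerate inputs.** A gene with zero total variance has an undefined F
ratio; it is reported as F = 0, p = 1 and thereby deterministically
excluded from signatures. The zero-variance test uses a tolerance scaled
to accumulated floating-point rounding so that noise-free null genes are
classified correctly.

## Connectivity mapping

**Reference profiles.** Each perturbagen instance is a full signed-rank
profile over a common gene universe of size *N*: the gene with the most
extreme differential statistic gets rank magnitude *N*, the least extreme
magnitude 1, and the rank's sign is the statistic's sign. Ties in
magnitude break lexicographically by gene id; statistics of exactly zero
take the smallest magnitudes with positive sign. Both conventions are
arbitrary but deterministic, and all extremal tests are written against
them.

**Connection score.** For a query signature with signed ranks `q_i` at
genes `g_i`, the raw score against profile `r` is `sum_i q_i * r(g_i)`,
normalized by the maximum attainable raw score (sorted signature
magnitudes paired with reference magnitudes `N, N-1, ...`), giving
`c` in `[−1, 1]`. `c = +1` means the signature genes occupy the extreme
reference positions with matching signs and magnitude order — the drug
*mimics* the disease signature; `c = −1` is the exact reversal — the drug
*inverts* it, the repurposing-relevant direction. The score is
antisymmetric in the signature's signs and invariant to relabelling
non-signature genes, both tested.

**Permutation p-values.** Significance comes from random signatures of
matching length: sample the signature's number of genes uniformly without
replacement from the universe and assign the observed signed-rank multiset
in random order. The two-sided empirical p-value is
`(#{|c_rand| >= |c_obs|} + 1) / (K + 1)`, never zero and never below
`1/(K+1)`. One random-signature set is drawn per query signature and
scored against every instance — the procedure the reference
connectivity-mapping tool uses — which also makes whole-refset scoring a
single sparse-by-dense matrix product. Per-signature seeds derive from the
master seed via a hash of the signature id, so results do not depend on
the order signatures are supplied in. An alternative null that also
randomizes signs is available in principle but off by default, since the
observed multiset is part of the query's identity. For universes small
enough to enumerate, the Monte-Carlo p-value is checked against exact
enumeration of all ordered assignments.

**Significance threshold and hits.** With an accepted false-positive rate
of one connection per analysis over *N* reference profiles, the cutoff is
`1/N` (for the canonical 3730-instance database, ≈ 0.00027, −log10 =
3.572). Comparisons are per instance; drug-level aggregation happens only
at hit selection, where a perturbagen is a hit when at least
`min_signatures` (default 2) distinct query signatures yield significant
connections of the required sign (default negative). On an all-null
refset the expected number of significant calls per analysis is the
accepted false-positive rate — the calibration property the acceptance
tests verify across 50 seeded repetitions, together with
Kolmogorov–Smirnov uniformity of the p-values. Note that with nested
derivative signatures the five analyses are positively correlated, so a
borderline null instance can occasionally cross a lenient cutoff (e.g.
1/100 on a small demonstration refset) in two or more signatures; at the
canonical `1/3730` this is correspondingly rarer.

## Median-effect synergy

**Normalization.** Raw luminescence is averaged per condition and divided
by the mean of the vehicle (dose-0) wells, giving percent viability and
fraction affected `fa = 1 − viability/100`. Conditions with `fa <= 0`
(including stimulation above vehicle) or `fa >= 1` carry no information on
the logit scale; they are excluded from fits but retained in reports — no
winsorizing or pseudo-data.

**Median-effect fit.** The dose–effect model is `fa/(1−fa) = (D/Dm)^m`.
Ordinary least squares on the linearized form
`log10(fa/(1−fa)) = m·log10 D − m·log10 Dm` gives the sigmoidicity `m` and
the median-effect dose `Dm = 10^(−intercept/m)`, which *is* the IC50 in
this framework (no four-parameter-logistic midpoint is involved). A
non-positive fitted slope is reported with a flag rather than hidden.
`fit_median_effect()` returns a classed object with `print`, `coef`,
`predict` and `plot` methods.

**Combination Index.** For a drug-pair grid (default the 5×5 design of 0,
0.25, 0.5, 1, 2 × each drug's IC50), each interior point's observed
replicate-mean `fa` is referred back to the two single-agent fits:
`Dx_i = Dm_i (fa/(1−fa))^(1/m_i)` is the dose of drug *i* alone producing
that effect, and the mutually exclusive Chou–Talalay index is
`CI = d1/Dx1 + d2/Dx2` (the mutually nonexclusive variant adds
`(d1·d2)/(Dx1·Dx2)` behind a flag; the exclusive form is the standard
report). This is the non-constant-ratio procedure — each grid point is
assessed at its own effect level — because the factorial grid is not a
constant-ratio design. Zero-dose rows and columns feed the single-agent
fits; CI is computed on the 4×4 interior. CI < 1 indicates synergy, > 1
antagonism; the textual classification uses a configurable band (default
±0.1) around 1, while the numeric CI is always reported. Points with
non-informative `fa` yield CI = NA, reported as undefined — at low doses
this is where the method's well-known apparent-antagonism artifacts live,
and the package reproduces rather than corrects that behavior.

## Synthetic data: what it emulates, and what it does not

The generators plant known structure under explicit integer seeds, with
no global RNG state:

- **Cohorts** (`simulate_expression_cohort`): planted increasing genes
  gain `step_effect` log2 units of mean per adjacent stage, decreasing
  genes lose the same, null genes are flat; i.i.d. Gaussian noise of SD
  `noise_sd` on the log2 scale. Defaults — 1000 genes, 50 + 50 planted,
  five stages of 20 samples, step 1.0, noise SD 0.25 — give a cohort on
  which the monotone filter recovers essentially all planted genes
  (measured 100 %; the frozen acceptance threshold is ≥ 95 %). With
  `step_effect = 0` the planted genes are statistically indistinguishable
  from nulls and the ANOVA p-values pass a KS uniformity test.
  `noise_sd = 0` is the noise-free validation mode in which recovery must
  be exact.
- **Refsets** (`simulate_refset`): null instances draw i.i.d. standard
  Gaussian latent statistics per gene; a planted inverter overwrites the
  latent statistic at the target signature's genes with
  `−alpha·sign(q)` plus Gaussian noise (mimics use `+alpha`), after which
  every instance is converted to a full signed-rank profile by the same
  builder real statistics would pass through. At the default strength
  `alpha = 3` against a 100-gene signature in a 1000-gene universe, the
  inverter scores below −0.9 and is significant in all five nested
  signatures.
- **Dose–response grids** (`simulate_dose_response`,
  `simulate_combination_grid`): exact median-effect curves with
  multiplicative Gaussian noise on luminescence. Combination grids solve
  the Loewe equation `d1/Dx1(fa) + d2/Dx2(fa) = interaction` for `fa` at
  every interior point, so `interaction = 1` is exactly additive
  (downstream CI = 1 to the root-finding tolerance, < 1e-6), and the
  planted `interaction` is exactly the CI the analysis should recover.

None of this mimics real microarray covariance structure, probe-level
artifacts, batch effects, plate effects, or the correlated biology of
real disease signatures. Passing the synthetic checks therefore
establishes that the *computations* are correct and calibrated under
their own assumptions — not that the defaults are tuned to any particular
real cohort. Effect-size defaults are the package's own realistic
choices, since no characterization of real signature effect sizes exists
to copy.

## Problem sizes and numerical choices

- `K = 10000` random signatures is the default for permutation p-values
  (the canonical run size). The bundled demonstration, calibration and
  acceptance runs use `K = 2000` with 100–1000-instance refsets: the
  p-value granularity `1/2001` fully resolves the `1/1000` cutoff used
  there, and a 50-repetition calibration completes in about two minutes.
- Calibration and recovery thresholds asserted by the tests (recovery
  ≥ 0.95; calibration t-test at 50 seeds; |median bias| of `Dm` and `m`
  < 2 % at 5 % CV, 6 doses × 3 replicates, 500 seeds) were frozen from
  derivation runs at the documented default settings before being
  asserted; measured values were 1.00 recovery, t-test p ≈ 0.4 and
  ≈ 0.2–0.7 % bias.
- The Loewe root is found with `stats::uniroot` on the log-odds scale
  (bracket ±60, tolerance 1e-14); the left-hand side is strictly
  decreasing so the root is unique.
- All tie-breaks (reference ranking, signature ordering) are
  lexicographic after the scientific keys, making every artifact
  bit-reproducible; the pipeline manifest records MD5 checksums and
  reruns are verified identical.
- Seeds are 32-bit safe: child seeds derive from one master seed through
  a fixed linear-congruential step (`child_seed()`), so no stage depends
  on execution order or global RNG state.

## Known limitations

- The monotone filter is a hard gate: genes monotone in truth but with
  one noise-tied adjacent contrast are excluded; no trend-test relaxation
  (e.g. Jonckheere–Terpstra) is offered.
- Connection p-values inherit permutation granularity; at `K` random
  signatures no p below `1/(K+1)` is representable.
- The CI machinery propagates no uncertainty from the single-agent fits;
  CI values are point estimates, as in the standard CalcuSyn-style
  report.
- Universe restriction assumes gene identifiers already harmonized
  between cohort and refset; no identifier mapping is performed.
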