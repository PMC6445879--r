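---
title: "Methods: two-sample Mendelian randomization of selenium and endometrial cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of selenium and endometrial cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selenomr)
```

## The question and the design

Observational studies have suggested that higher selenium levels might
protect against several cancers, but randomized trials of selenium
supplementation have been disappointing. For endometrial cancer no trial
exists, and the observational record is thin and vulnerable to confounding
and reverse causation. Two-sample Mendelian randomization (MR) sidesteps
both problems by using germline variants associated with selenium levels as
instrumental variables: genotype is fixed at conception, so the
variant-outcome association inherits none of the exposure's behavioural
confounding, and only GWAS summary statistics from two separate studies are
needed.

The packaged analysis instruments selenium with four variants (two
independent variants at each of two loci, 5q14 and 21q22) whose effects on
a composite of circulating and toenail selenium were estimated in GWAS
meta-analyses totalling n = 9,639, and takes variant-outcome associations
from an endometrial cancer GWAS of 12,906 cases and 108,979 controls. With
an exposure reported in Z-score units, all causal effects are expressed per
unit increase in the selenium Z-score; they carry direction and strength,
not interpretable physical units.

## Instrument assembly

Candidate variants are LD-pruned greedily: visited in ascending p-value
order (ties: larger |Z| first, then lexicographic rsid) and retained only
if their LD r² with every previously retained variant is below 0.05. The
source studies state only that pruning was performed; the greedy-by-p rule
with explicit tie-breaks was chosen because it is deterministic and
order-independent, which the tests assert directly. The packaged LD matrix
carries the two published within-locus r² values (0.04 and 0.03) and zeros
between loci.

A local confounder screen replaces the original web-based lookup: a table
of variant-trait associations is checked against the Bonferroni threshold
0.05/7 = 7.14e-3 for the seven established endometrial cancer risk factors
(body mass index, age at menarche, age at menopause, postmenopausal
estradiol, nulliparity, infertility, insulin levels). Variants failing the
screen are excluded. The packaged table is empty — none of the four
instruments shows such an association — but the mechanism is fully
functional and tested.

Harmonization aligns each outcome record to the exposure's effect allele:
swapped alleles negate the outcome beta and complement its allele
frequency; opposite-strand representations are resolved by complementing
before matching (non-palindromic pairs only). Palindromic A/T and C/G pairs
default to `keep_if_eaf_informative`: dropped when
min(eaf, 1 − eaf) > 0.42, otherwise oriented so allele frequencies agree
across studies. The 0.42 cutoff is the community convention; none of the
four selenium instruments is palindromic, so the default never touches the
packaged analysis. Variants absent from the outcome study are dropped with
a warning; proxy lookup in reference panels is deliberately out of scope.

## The Z-score conversion and instrument strength

With N the sample size and p the effect-allele frequency,

beta = Z / sqrt(N · p · (1 − p)),  SE = beta / Z = 1 / sqrt(N · p · (1 − p)).

Three conversion choices deserve comment, all fixed by reproducing the
published instrument table:

* **Effective N = 9,639**, the sum of the circulating (5,477) and toenail
  (4,162) selenium GWAS sizes. This value reproduces every published
  converted beta and SE at 2 decimal places.
* **Divisor p(1 − p), not 2p(1 − p).** Both forms circulate in the
  literature; the doubled form would give 0.21 instead of the published
  0.29 for the strongest variant. Both are implemented (`het_form`), the
  reproducing form is the default.
* **Two F statistics.** The tabulated instrument-strength "F statistic"
  equals the reciprocal of the converted SE, sqrt(N·p·(1−p)) — not the
  conventional (beta/SE)² = Z². `f_statistic()` exposes both as
  `mode = "paper"` and `mode = "conventional"`; the strength table reports
  both columns. The per-variant variance explained uses
  r² = Z²/(N − 2 + Z²), whose sum over the four instruments reproduces the
  published 2.9%.

## Estimators

All estimators consume harmonized instruments and report log-odds effects
with a 1.96-SE interval and an exponentiated odds-ratio view.

**Wald ratio.** ratio = beta_out/beta_exp with first-order SE
se_out/|beta_exp| by default (the weighting convention IVW assumes); the
second-order SE adding the exposure-uncertainty term is selectable.

**IVW.** Fixed effect: beta = Σwr/Σw, se = (Σw)^(−1/2), w = 1/se(r)².
The default random-effects flavour is multiplicative overdispersion with
the scale floored at 1 — the SE is inflated by max(1, sqrt(Q/(L−1))) —
matching mainstream two-sample MR practice when "a random-effects model"
is stated without detail. Additive DerSimonian–Laird re-weighting is also
available (cross-checked against `metafor` in the tests); on the packaged
fixture all three flavours give OR 0.99 at 2 dp, so the choice is
immaterial here.

**MR-Egger.** Weighted least squares of beta_out on beta_exp with a free
intercept and weights 1/se_out², after orienting every instrument to a
positive exposure effect (on an internal copy; caller data are never
mutated). The intercept estimates the average directional pleiotropic
effect; the slope is the pleiotropy-corrected causal estimate. SEs carry
the same floored residual scale; p-values default to t with L − 2 degrees
of freedom (normal selectable), while CIs use 1.96·SE in all methods for
consistency.

**Weighted median.** Wald ratios are sorted; cumulative weight fractions
p_j = (Σ_{k≤j} w_k − w_j/2)/Σw are interpolated linearly at p = 0.5.
The point estimate is deterministic; only its SE comes from a parametric
bootstrap (each ratio resampled from N(r_j, se_j), default 1000
replicates, mandatory seed, run under a local RNG state so the caller's
stream is untouched).

## Diagnostics

**Cochran's Q** with L − 1 degrees of freedom uses the exact chi-square
upper tail, no continuity correction. From the packaged 2-dp fixture Q
evaluates to ≈8.2 (p ≈ 0.042); the originally reported 7.22 (p = 0.07) was
computed from unrounded internal values that were never printed, so the
tests assert an agreement band [7.0, 8.5] rather than equality.

**I²GX** measures regression dilution of the MR-Egger slope under
measurement error in the exposure effects:
I²GX = max(0, (Q_GX − (L−1))/Q_GX) with Q_GX the weighted dispersion of
the oriented exposure effects. Weights default to the MR-Egger regression
weights 1/se_out² (≈0.93 on the fixture, bracketing the published 92%);
1/se_exp² weighting (≈0.89 here) is selectable and logged. Negative raw
values are reported but clamped at zero in the result.

## The synthetic-data generator

`simulate_dataset()` draws two-sample summary statistics directly on the
scale the estimators consume: per instrument, eaf ~ U(0.1, 0.9), true
exposure effect γ ~ U(0.1, 0.4) (the range of the real instrument),
se = 1/sqrt(n·eaf·(1−eaf)) in each sample, observed effects normal around
γ and θγ + α, with the direct effect α ~ N(pleiotropy_mean,
pleiotropy_sd), optionally correlated with γ (α gains a ρ·(γ − γ̄) term)
to violate the InSIDE assumption. Default sample sizes are the real ones
(n_exp = 9,639, n_out = 121,885). Datasets are pure functions of the
config including its seed; replicate seeds advance by increment, never
through global state.

The generator emulates independent, strongly associated instruments with
Gaussian summary-statistic noise. It deliberately does **not** model LD
between instruments, the binary-trait liability scale (outcome effects are
linear in γ, the standard two-sample approximation), winner's curse in
instrument selection, or sample overlap. Passing calibration tests
therefore demonstrate estimator correctness under the assumptions the
estimators themselves make — not robustness to those further
complications.

Problem sizes in the packaged experiments were chosen to make Monte-Carlo
error small relative to the quantities tested: 50-instrument panels, 500
replicates for the type-I-error and directional-pleiotropy experiments
(binomial SE ≈ 0.01 at the nominal 0.05), 100–200 replicates where only a
majority verdict is needed.

## Degenerate inputs and numerical conventions

Zero exposure effects make the Wald ratio undefined and are reported as
errors naming the variant. A single instrument is allowed only for
fixed-effect IVW (the result is its Wald ratio); MR-Egger and the weighted
median require three instruments and are skipped with a logged warning by
the pipeline below that. Exactly collinear Egger designs (all exposure
effects equal) are rank-deficient errors. Q = 0 yields p = 1; I²GX
truncates at 0; the multiplicative residual scale never drops below 1.
Validation tolerances: beta/se vs Z consistency at 1e-6 relative, LD
matrix symmetry at 1e-8.

## Interface shape

The package is organised as an analysis-first toolkit: the numbered
scripts under `analysis/` are thin narrative drivers (instrument assembly,
estimation + diagnostics, simulation calibration) over the exported
functions, and `run_analysis()` / `write_report()` provide the same
end-to-end run programmatically from a config object or YAML file. A
separate command-line wrapper would add nothing for the intended audience,
so none is shipped.

## Known limitations

The exposure scale is a Z-score composite of two selenium measures, so
effect sizes have direction and strength but no physical unit. The
instrument explains <3% of exposure variance, limiting power — a null
result here cannot exclude modest effects. The confounder screen is only
as good as the association table supplied to it. MR-Egger with four
instruments has very low power, and its intercept test inherits that. None
of the estimators handles correlated instruments; pruning must precede
them.
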