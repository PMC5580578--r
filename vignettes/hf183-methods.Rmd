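---
title: "Methods: censored qPCR quantification and site prioritization for the HF183 marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: censored qPCR quantification and site prioritization for the HF183 marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hf183monitor)
```

`hf183monitor` quantifies the human-associated HF183 *Bacteroides* marker in
drainage water by qPCR and ranks monitoring sites by the extent of human
fecal contamination. This vignette is the package's account of the models
behind each stage, the tunable parameters and why their defaults are what
they are, the numerical conventions, and what the synthetic-data generator
does and does not establish about real campaigns.

## Master calibration

Each laboratory runs a 6-point, 10-fold dilution standard curve
(10⁰ – 10⁵ copies/reaction, triplicate) on every plate. All of a lab's
standard points are pooled into one *master* fit,

$$C_q = b_0 + b_1 \log_{10}(\text{copies}),$$

by ordinary least squares. Pooling across plates rather than fitting
per-plate curves stabilizes the slope (hundreds of points instead of 18)
and is what makes a single pair of limits per lab meaningful.

Outliers — pipetting errors, evaporation, a contaminated standard vial —
are removed iteratively: compute externally studentized residuals, drop the
single worst point if its absolute value exceeds 3, refit, repeat until
none exceed 3. One-at-a-time removal is deliberate: a gross outlier
inflates the residual variance and can *mask* milder ones, so single-pass
sweeps under-remove. A single-pass mode is available
(`iterative = FALSE`) for sensitivity analysis. Two numerical guards
apply: a fit whose largest raw residual is below 10⁻⁸ cycles is treated as
exact (studentized residuals of floating-point noise are meaningless), and
fewer than 4 distinct concentrations, or a non-negative fitted slope, is an
error rather than a curve.

Amplification efficiency is $E = 10^{-1/b_1} - 1$; a slope of −3.32
cycles/decade is perfect doubling. Detection limits follow the two-tier
convention:

* **LOD** = 1 copy/reaction, expressed in Cq as the *mean observed* Cq of
  amplified 1-copy standards. Using the observed mean rather than the
  fitted prediction at log₁₀ = 0 keeps the threshold honest when the curve
  bends at the low end, where single-molecule stochasticity flattens the
  response.
* **LLOQ** = 10 copies/reaction, expressed as mean 10-copy Cq + 2 SD, so a
  replicate is only called quantifiable when it sits clear of the
  between-replicate noise at the lowest fully-amplifying concentration.

`derive_detection_limits()` requires at least two amplified replicates at
each level and rejects the degenerate case LLOQ ≥ LOD in Cq.

## Censored quantification

Replicates are classified against the limits in copy units:
**ND** (no amplification), **DBLOD** (amplified, < 1 copy), **DNQ**
(1 ≤ copies < 10), **QUANT** (≥ 10; the LLOQ boundary is closed on the
quantifiable side, and a relative tolerance of 10⁻⁹ keeps copy numbers that
hit a boundary exactly, up to floating point, on the closed side).

Censored replicates are substituted, never zeroed, because at low template
numbers non-amplification is an expected outcome of Poisson subsampling of
marker copies into the reaction, not evidence of absence. With mean
template λ copies/reaction, a replicate receives no copies with probability
$e^{-\lambda}$. The package assumes amplification is certain given ≥ 1
copy; extraction loss and inhibition, which lower detection probability in
real assays, are deliberately not modeled (they would be confounded with λ
without spike-in truth data).

Under the default `poisson` scheme, the sample-level estimate λ̂ is:

* the geometric mean of the replicates measuring ≥ 1 copy, when any exist
  (the measured replicates are the best evidence about the sample's
  template level); otherwise
* the posterior mean of λ under the pattern likelihood
  $(1-e^{-\lambda})^k (e^{-\lambda})^{n-k}$ for $k$ amplified of $n$
  replicates, with a uniform prior on [0, 10] copies/reaction. The prior
  upper bound is the LLOQ: a sample that needs pattern-based estimation is
  by construction below the quantifiable range. The posterior mean (unlike
  the MPN maximum-likelihood estimate $-\ln(1-k/n)$, which is 0 at
  $k = 0$ and undefined at $k = n$) is positive and finite for every
  pattern, which matters because all-ND samples still enter geometric
  means. It is computed by adaptive quadrature to a relative tolerance of
  10⁻⁹ and verified in the tests against closed-form integration of the
  binomially expanded likelihood.

An ND replicate is then replaced by λ̂ (the unconditional Poisson mean) and
a DBLOD replicate by $\hat\lambda/(1-e^{-\hat\lambda})$ — the Poisson mean
*conditional on at least one copy present*, which is always ≥ 1 and ≥ the
ND substitute, consistent with DBLOD being an observed amplification. The
`half_lod` alternative (ND → ½ LOD, DBLOD → LOD) is retained for
sensitivity analysis.

Concentrations convert as
$\text{copies}/100\,\text{mL} = \text{copies/reaction} \times
(V_\text{elution}/V_\text{template}) \times (100/V_\text{filtered})$.
The default volumes (394.5 µL elution, 5 µL template, 100 mL filtered)
give a composite factor of 78.9, chosen so that 1 and 10 copies/reaction
correspond to 79 and 789 copies/100 mL; programs with different bench
volumes set their own `volume_config()`.

## Weather stratification

A wet-weather event requires ≥ 0.10″ accumulated rainfall after ≥ 3
consecutive dry days at the sample's nearest gauge; samples within 72 h of
event start are wet-weather samples. Three conventions are the package's
own, since the trigger rule alone does not fully define a classifier:

* A day is *dry* when its total depth is below 0.01″ — trace rain neither
  breaks a dry spell nor counts toward the 0.10″ accumulation. The second
  clause is what guarantees that event windows of one gauge never overlap:
  an event can only start on a rainy day, which resets the dry-day counter,
  so the next event is at least 4 days away.
* Dry-weather samples must additionally clear a 72-h buffer *after* each
  event window, keeping storm tails out of dry-weather summaries, and fall
  inside the recreational season (1 April – 31 October). Wet samples are
  accepted year-round, matching how storm campaigns are actually run.
* No antecedent dry credit is assumed before a rain record begins.

Samples that are neither wet nor clean-dry are `EXCLUDED` and dropped from
site summaries. The classifier is verified in the tests against an
independent brute-force day-by-day implementation on 1000 random series.

## Site metrics

Seven positivity definitions are computed per sample: AMP1/2/3 (at least
1, 2, or 3 of the triplicate reactions amplified at any Cq), DET1/2/3
(at least 1, 2, or 3 replicates at or above LOD), and MEANGT_LOD (sample
geometric-mean concentration, with ND → ½ LOD and DBLOD → LOD, above the
LOD). AMP1 is the headline metric: it is the most health-protective, since
a genuinely positive sample at low concentration can produce
non-amplifying replicates purely by subsampling. The definitions form a
ladder (AMP1 ≥ AMP2 ≥ AMP3, AMPk ≥ DETk per site) that the test suite
asserts on every generated campaign. MEANGT_LOD is compared in
copies/100 mL; the comparison is invariant to the conversion factor, which
scales both sides.

The site concentration metric is the geometric mean of *all* replicate
concentrations pooled across samples (arithmetic mean on the log₁₀ scale,
back-transformed), after substitution — so frequency information enters the
concentration metric through the substitutes, which is precisely why
frequency- and concentration-based rankings agree at sites with persistent
sources. *Enterococcus* metrics (exceedance of the 104/100 mL single-sample
maximum, of 100× that value, and the geometric mean, with zero counts
floored at 1) use only the samples actually measured for *Enterococcus*;
missing FIB values never shrink HF183 denominators. Site–stratum cells with
ten or fewer samples are excluded from ranking.

## Prioritization

Rank 1 is the most contaminated site. Ties are broken deterministically —
by the geometric-mean concentration when ranking on a frequency, by AMP1
frequency otherwise, then lexicographically by site — so every ranking is a
permutation and re-runs are reproducible. Concordance between rankings is
Spearman's rank correlation (ranks are its native scale), reported with
per-site rank shifts and the maximum-shift site. Dry–wet comparisons
re-rank within the shared site subset before computing concordance, and
also list sites whose metric *decreased* in wet weather (candidate
storm-dilution sites).

## The synthetic-data generator

`simulate_campaign()` draws, per sample: contamination ~
Bernoulli(prevalence); given contamination, concentration ~ lognormal
(log₁₀ mean and SD per site, wet stratum scaled by a multiplier); expected
copies/reaction µ = concentration / conversion factor; three replicate
copy numbers ~ Poisson(µ); amplification iff copies ≥ 1, with
Cq = intercept + slope·log₁₀(copies) + Normal(0, σ). The zero-inflated
lognormal is the simplest structure that lets detection frequency and
signal magnitude vary separately across sites. Plates follow the shared
layout (18 standard + 6 NEC + 3 NTC + up to 66 sample wells); controls
amplify spuriously at a configurable rate (default 0.002, of the order of
2 per thousand seen in careful practice).

Two generator choices deserve emphasis:

* **Standards amplify at their nominal copy number**, with measurement
  noise but without Poisson subsampling. Prepared dilution standards at
  nominal 1 copy amplify in > 90% of replicates in practice, which is
  incompatible with literal Poisson draws ($P(0) = e^{-1} \approx 0.37$);
  treating the nominal value as delivered reproduces observed
  standard-curve behaviour and keeps the LOD definable on every plate.
* **The default scenario** (`default_study_like_scenario()`) uses 22
  sites × 50 samples per stratum × 8 labs, with dry prevalences of 0 at two
  sites, 0.10–0.34 at fifteen, 0.50–0.90 at four and 1.0 at one site, and
  concentration scale coupled to prevalence
  (log₁₀ mean = 1.8 + 2.2 × prevalence). This reproduces the regional
  pattern of interest — a broad low-frequency band around 10–35%, a
  high band up to always-positive, two never-positive dry sites — with
  enough signal at the bottom of the band that a 50-sample campaign does
  not spuriously produce extra zero-frequency sites. The bottom of the
  band sits slightly above the lowest frequencies seen in the field, a
  deliberate trade for that stability. Lab efficiencies are evenly spaced
  over 0.90–0.98 with Cq noise SD 0.3, placing fitted efficiencies within
  the 0.89–0.99 range typical of multi-lab programs; note that at this
  noise level the fitted R² (≈ 0.998 over five decades) is *better* than
  field curves, whose R² of 0.95–0.99 implies cycle-level noise severalfold
  larger.

What passing tests on generated data do **not** show: the generator has no
inhibition, no extraction loss, no marker decay between source and sample,
no spatial or temporal autocorrelation within a site, no gauge-to-site
mismatch, and Enterococcus–HF183 coupling is a single mixing parameter.
Estimator recovery on this generator therefore validates the arithmetic and
the statistical machinery, not the field accuracy of HF183 monitoring.

## Problem sizes and numerical conventions

The test and validation runs use, as the package's chosen study sizes:
200 simulated plates for calibration recovery (Cq noise SD 0.2, median
absolute slope error well under 0.05 cycles/decade); 20 sites × 50 samples
for ranking recovery (Spearman vs. true prevalence ≥ 0.9); the full
22 × 50 × 2 default scenario for the structural checks; 1000 random
60-day rain series for the classifier equivalence; and 10⁵ Monte-Carlo
draws for the conditional-mean substitute. Quadrature tolerance is 10⁻⁹
relative; noise-free calibration recovers parameters to 10⁻⁹; summary
CSVs round-trip numeric values at 6 significant digits.

## Known limitations

Only the HF183 channel of the duplex assay is modeled; the internal
control enters solely as the sketa22 inhibition screen (flag at ΔCq > 3
versus a reference, configurable — field programs report inhibition as a
qualitative judgement and no numeric criterion is standard). CFU and MPN
Enterococcus values are pooled without conversion. Timestamps are
timezone-naive local time. Nearest-gauge assignment is taken as an input
column, not computed from coordinates. Flow-weighted loading metrics and
risk-assessment layers are out of scope.
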