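---
title: "qSIP enrichment, detection thresholds, and growth rates: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{qSIP enrichment, detection thresholds, and growth rates: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsipr)
```

## The estimation problem

Quantitative stable-isotope probing (qSIP) asks, for each taxon in a
community, how much of a heavy-isotope tracer (here ¹³C) it incorporated
into its DNA. The raw observable is the taxon's distribution of DNA along
a CsCl density gradient, measured twice: in an unlabeled reference sample
and in the labeled treatment. Incorporation shifts the distribution toward
higher buoyant density; the size of the shift, relative to how far the
fully substituted genome could shift, is the atom fraction excess.

The pipeline decomposes into four stages, each its own module:

1. **Tables** (`read_qsip_tables()` and friends): per-fraction density and
   DNA concentration, per-taxon relative coverage, sample design.
2. **Enrichment** (`estimate_enrichment()`): abundance-weighted mean
   densities per taxon and treatment, converted to APE by the isotope
   substitution model.
3. **Detection threshold** (`detect_labeling_threshold()`): segmented
   regression on the rank–APE curve with a Davies test, and the
   breakpoint-plus-3-SE rule.
4. **Growth** (`estimate_growth()`): linear-growth net and gross rates.

## The isotope substitution model

All conversions live in one constants object (`qsip_constants()`), with the
standard ¹³C parameterization:

| quantity | form | constants |
|---|---|---|
| GC from unlabeled density | $G = (W_{light} - a)/b$ | $a = 1.646057$ g/ml, $b = 0.083506$ g/ml |
| unlabeled nucleotide weight | $M_{light} = 0.496\,G + 307.691$ | g/mol |
| max weight, full ¹³C | $M_{heavy} = M_{light} + 9.974564 - 0.4987282\,G$ | g/mol |
| labeled weight | $M_{lab} = M_{light} \cdot W_{lab}/W_{light}$ | — |
| atom fraction excess | $A = \frac{M_{lab}-M_{light}}{M_{heavy}-M_{light}}(1 - 0.01111233)$ | natural ¹³C abundance 0.01111233 |

`density_from_afe()` is the exact algebraic inverse and drives the
simulator, which makes the model self-checkable: the round trip is exact to
well below 1e-10 across the whole GC × AFE grid.

Assumptions worth stating. GC is *inferred from the unlabeled density*,
never from sequence, so any density offset shared by both treatments (GC,
methylation, instrument calibration) cancels; an offset present in only one
treatment does not. A taxon's APE of zero is exactly recovered whatever its
GC. Negative APE — the labeled density falling below the unlabeled one — is
pure measurement noise and is deliberately *retained* (no flooring) because
the detection threshold stage needs the noise floor to locate the
breakpoint. Out-of-range inferred GC is flagged, not clamped, so QC can
drop the taxon explicitly.

## Enrichment estimation

The abundance metric is $y_{ijk} = p_{ijk} f_{jk}$. Relative coverage $p$
is read depth per million mapped reads of the fraction library
(`normalize_coverage()`). The dialect matters less than it seems: the
weighted mean density is invariant to any constant applied per taxon or
per sample. It is **not** invariant to arbitrary per-library constants —
those would reweight fractions against each other — which is precisely why
depth must be normalized by library size before use: per-million
normalization reduces the remaining arbitrary factors to per-taxon and
global ones, which cancel.

Replicate structure: weighted densities are computed per sample and then
averaged within treatment, so replicated designs work unchanged; with
n = 1 the mean is the identity. Taxa undetected (total $y = 0$) in either
treatment are reported in a skip list with a reason, never assigned APE 0 —
absence of evidence is not zero enrichment.

Bacterial genome bins aggregate scaffold depths length-weighted
(`aggregate_bin_coverage()`), equivalent to mapping against the whole bin;
eukaryote taxa are one-scaffold bins (their 18S-bearing scaffold as genome
proxy); phage genomes are used directly. All three classes flow through the
same estimator and differ only in a metadata column.

### Pooled bins

When light/middle/heavy bins rather than individual fractions are
sequenced, `derive_bin_boundaries()` reproduces the profile-based rule: the
heavy bin starts where the unlabeled concentration profile reaches zero
(fluorometry rarely returns exact zeros, so "zero" is a configurable
ε = 0.05 ng/µl), and the middle bin starts at the highest crossing of the
labeled and unlabeled concentration curves below that point, located by
linear interpolation. Bin upper bounds are inclusive. A combined bin's
pseudo-fraction density is the DNA-mass-weighted mean of its member
densities — the expected buoyant density of the DNA actually sequenced —
and its concentration conserves total DNA mass exactly.

Three-bin pooling is information-lossy by construction: every taxon's
density is summarized by at most three support points shared across taxa.
On communities whose GC spread (≈ 0.04 g/ml across GC 0.30–0.75) is large
relative to per-step enrichment shifts (≈ 0.005 g/ml per 10 APE), heavily
labeled taxa collapse onto the heavy bin's single density and their
relative order is set by GC rather than enrichment; rank fidelity
(Spearman ρ against truth) then sits near 0.91 rather than 1. With the
structured enrichment layout of `rhizosphere_preset()` the rank order
survives pooling at ρ ≥ 0.95. Per-fraction data recover APE essentially
exactly (max error < 1e-7 APE, noiseless).

## The detection threshold

With unreplicated gradients no per-taxon confidence interval exists, so
detection is population-based: sorted ascending, APE values form a curve
that is flat (noise around zero) until true incorporation begins, then
rises. `fit_segmented()` fits
$y = \beta_0 + \beta_1 x + \beta_2 (x-\psi)_+$ by iterative linearization:
at the current $\psi$ the model is refitted with the working covariate
$V = -\mathbf{1}(x > \psi)$ and $\psi$ is updated by $\hat\gamma/\hat\beta_2$
until $|\hat\gamma| < 10^{-8}$ (at most 50 iterations);
$SE(\psi) = SE(\hat\gamma)/|\hat\beta_2|$ at convergence. Because the
profile RSS over $\psi$ is piecewise smooth with kinks at the data points,
the iteration can stall in a local minimum: every fit is therefore verified
against a 0.1-rank grid scan, restarting from the global basin when
needed, with a 0.001-rank local refinement if the iteration cannot settle.
Ties in the grid take the smallest $\psi$ — the most conservative
threshold. $|\hat\beta_2| < 10^{-10}$ raises a no-breakpoint flag, and
fewer than 3 points on either side a boundary warning.

The fit is restricted to the lowest 90 ranks (`restrict_window()`):
including the strongly enriched tail, where the rank–APE slope declines
again, drags the single breakpoint toward zero APE and inflates the
labeled set.

`davies_test()` handles the nonstandard inference (ψ vanishes under the
null): the Wald statistic for $\beta_2$ is evaluated at K = 10 equally
spaced interior candidates (margin 2 ranks) and the p-value is the Davies
(1987) upper bound $\Phi(-M) + V e^{-M^2/2}/\sqrt{8\pi}$ for the maximum
M of the correlated statistics, V being their total variation. The bound
makes the test conservative (measured type-I error ≈ 0.04 at α = 0.05 on
500 white-noise datasets). The default alternative is a positive slope
change — the direction a labeling signal produces; a two-sided variant
doubles the bound.

The threshold is $\psi + m\,SE(\psi)$ with m = 3 (the upper 99.7%
confidence limit under normality), and the APE cutoff is read off the
sorted APE sequence at that fractional rank by linear interpolation. Taxa
strictly above the cutoff are flagged labeled. Monte-Carlo behavior under
heavy noise is worth knowing: with a slope change of 0.5 APE/rank and
noise sd 2, even the exhaustive-search estimator localizes ψ within ±2
ranks only about two-thirds of the time, and ±3 SE intervals cover the
truth at roughly 95–97% — the SE from the linearization is mildly
optimistic when the hinge is shallow relative to noise. With sharper
hinges (as in the preset, slope change ≈ 1.4) localization is sub-rank.

When multiple weeks are analyzed, `run_qsip_pipeline()` estimates
enrichment per week (each week's bulk sample is its own unlabeled
reference) but pools the per-week APE values into a single ranking for one
breakpoint fit and one cutoff, so "labeled" means the same thing in both
weeks. Per-week thresholds are available by calling
`detect_labeling_threshold()` on a single week's table.

## Growth rates

The linear model $N_t = N_0 + r\,t$ (t = 7 days × week) gives the net rate
from total abundances, $N = P \cdot \mathrm{yield}$, where P is the
taxon's share of summed fraction abundances and yield is ng DNA per g dry
soil. The gross rate on labeled carbon partitions the time-t pool by the
measured enrichment: the new-DNA fraction is
$\varphi = (APE/100)/(A_{source} U)$, capped at 1, and
$r_{gross} = N_t\,\varphi / t$. U (fraction of new-DNA carbon from labeled
substrates) defaults to 1.0 — in a rhizosphere experiment all new carbon
can derive from root inputs. $A_{source}$, the enrichment of the
assimilated pool, also defaults to 1.0 but is exposed because every gross
rate scales by $1/A_{source}$ and the effective value (growth-chamber
atmosphere ≈ 0.90, shoot tissue ≈ 0.94, or 1.0) is an experimental
judgment, not something the data identify. Negative APE yields a gross
rate of exactly 0 (noise, not negative growth); negative *net* rates are
real population declines and are reported as-is. By construction
$0 \le r_{gross} \le N_t/t$.

## The simulator

`simulate_gradient()` places each taxon's DNA at the buoyant density
implied by its GC and true APE (via the exact forward model), spreads it
as a Gaussian with sd `sigma_density` = 0.005 g/ml — a lumped stand-in for
diffusion and fragment-length effects, sized so a 32-fraction gradient
resolves labeled from unlabeled at roughly 20 APE — and integrates the
Gaussian over equal-width fraction intervals. Real gradients are
nonlinear in collection order, but the estimator consumes (density,
concentration) pairs, so the interval shape is immaterial. Relative
coverage is the taxon's mass share of each fraction; sequencing noise, when
enabled, is a single multinomial draw per library at the configured read
depth (no GC bias, no mapping error, no chimeric assembly — the
simulator validates the *estimator*, not the upstream bioinformatics).
More than 1% of a taxon's mass falling outside the collected density range
triggers a warning naming the taxon; scenarios should choose
`density_min`/`density_max` to cover their community's bands (the default
1.692–1.765 g/ml matches a typical collected range; the preset uses
1.65–1.80 to hold GC 0.35–0.70 at up to 90 APE).

`simulate_timepoints()` evolves abundances linearly and labels only DNA
synthesized during the incubation: at week w a taxon's measured APE is its
new-DNA fraction times $A_{source}$, which makes the growth stage's
inversion exact on noiseless data (recovery well within 5%).
`rhizosphere_preset()` fixes a 92-taxon community (55 bacterial bins, 10
phage, 27 eukaryote scaffolds; ≈ 78% of bacteria above a 2.5-APE hinge;
phage the most labeled, eukaryotes barely labeled) whose rank–APE curve
has the flat-then-rising shape the threshold stage requires.

What passing simulator-based tests does *not* show: robustness to
GC-dependent extraction bias, mapping error, inter-gradient calibration
drift, or compositional distortions from incomplete genome recovery — none
of which the noise model contains.

## Problem sizes and numerics

Test and acceptance runs use desk-scale sizes chosen to exercise every
code path in seconds: 60-taxon recovery grids, 200-replicate breakpoint
Monte Carlo, 500 null datasets for the Davies type-I check, 20 instances
for the grid-search cross-validation (0.01-rank resolution). Convergence
tolerances: $10^{-8}$ on the linearization working coefficient, $10^{-10}$
for the no-breakpoint slope test, $10^{-12}$ relative for mass-conservation
identities. All simulations are reproducible via explicit seeds; the
analysis pipeline itself draws no random numbers.
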