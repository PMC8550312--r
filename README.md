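# qsipr

Genome-resolved **quantitative stable-isotope probing (qSIP)** in R: estimate
per-taxon ¹³C enrichment from density-fractionated metagenome coverage, derive
a data-driven labeling detection threshold by breakpoint analysis, and
estimate taxon-specific growth rates on labeled carbon.

## The problem

In a ¹³C labeling experiment (e.g. plants grown under ¹³CO₂, with rhizosphere
soil as the labeled community and bulk soil as the unlabeled reference), DNA
from organisms that assimilated the tracer becomes denser. CsCl density-gradient
centrifugation separates each DNA sample into ~32 fractions of known buoyant
density and DNA concentration; sequencing the fractions (or pooled
light/middle/heavy bins) yields per-taxon coverage along the gradient. qSIP
turns the *shift* of a taxon's DNA between the unlabeled and labeled gradients
into an estimate of its ¹³C **atom percent excess (APE)** — and from there into
a growth rate on labeled substrates. The method is taxon-resolved and, because
it works on density shifts rather than positions, insensitive to genome size
and GC content.

## The model

For taxon *i*, fraction *k*, replicate *j*, abundance is

> *y*<sub>ijk</sub> = *p*<sub>ijk</sub> × *f*<sub>jk</sub>

where *p* is read-depth-normalized relative coverage and *f* the fraction's
total DNA concentration. The taxon's weighted mean buoyant density in a sample
is *W* = Σ *x*<sub>k</sub>·*y*<sub>k</sub> / Σ *y*<sub>k</sub> with
*x*<sub>k</sub> the fraction densities. The isotope-substitution model maps the
unlabeled density *W*<sub>light</sub> to GC content, GC to the average
nucleotide molecular weight *M*<sub>light</sub> and to the fully-substituted
maximum *M*<sub>heavy,max</sub>, and the observed labeled density
*W*<sub>lab</sub> to *M*<sub>lab</sub> = *M*<sub>light</sub> ·
*W*<sub>lab</sub>/*W*<sub>light</sub>; the atom fraction excess is

> *A* = (*M*<sub>lab</sub> − *M*<sub>light</sub>) / (*M*<sub>heavy,max</sub> −
> *M*<sub>light</sub>) × (1 − 0.01111233),  APE = 100·*A*.

Because single measurements carry no replicate error, the detection threshold
comes from the rank–APE curve: a single-breakpoint segmented regression
*y* = β₀ + β₁·rank + β₂·(rank − ψ)₊ is fitted to the lowest 90 ranks, the
Davies test checks that a slope change exists, and taxa above the APE at rank
ψ + 3·SE(ψ) are called detectably labeled. Growth on labeled carbon uses the
linear model *N*<sub>t</sub> = *N*₀ + *r·t* (ng DNA g soil⁻¹ day⁻¹); the gross
rate is the labeled-new fraction of the DNA pool per day.

A forward simulator (`simulate_gradient()`, `simulate_timepoints()`,
`rhizosphere_preset()`) generates gradient fractionation data with known
ground truth so every stage is testable.

## Worked example

```r
library(qsipr)

preset <- rhizosphere_preset(seed = 42)          # 55 bins, 10 phage, 27 18S scaffolds
sim    <- simulate_timepoints(preset$taxa, preset$cfg, weeks = c(0, 6))
out    <- run_qsip_pipeline(sim, weeks = 6)
str(out$summary)
#> $ n_taxa                         : int 92
#> $ psi                            : num 39.7
#> $ psi_se                         : num 0.597
#> $ davies_p                       : num 0
#> $ threshold_rank                 : num 41.5
#> $ ape_cutoff                     : num 6.05
#> $ n_labeled                      : int 51
#> $ n_labeled_bacterial_bin        : int 41
#> $ n_labeled_phage                : int 10
#> $ mean_r_gross_bacterial_bin     : num 0.628
#> $ mean_r_gross_eukaryote_scaffold: num 0.0369
#> $ mean_r_gross_phage             : num 8.82
```

The breakpoint sits at rank ψ = 39.7 ± 0.6: below it the rank–APE curve is
flat (background noise around zero enrichment), above it APE rises steeply.
The Davies p-value ≈ 0 confirms the slope change. The labeling threshold is
rank ψ + 3·SE = 41.5, whose interpolated APE (6.05%) is the cutoff: 51 of 92
taxa are detectably ¹³C-labeled, including all 10 phage and 41 of 55 bacterial
bins. Mean gross growth on labeled carbon is highest for phage (8.8 ng DNA g⁻¹
d⁻¹) and lowest for the eukaryote scaffolds (0.037) — the labeled community is
bacteria- and phage-dominated, matching the simulated truth.

Real data enter through `read_qsip_tables()` (fraction metadata, scaffold
coverage, scaffold→bin map, sample design, library metadata as TSV), with
`aggregate_bin_coverage()`/`coverage_records()` building per-taxon relative
coverage, `derive_bin_boundaries()`/`combine_fractions()` handling pooled
light/middle/heavy bins, and the same `run_qsip_pipeline()` downstream.

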