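# septaquant

Quantitative analysis of the cardiac compartment boundary of the
interventricular septum (IVS) and its disruption in mouse models of
congenital heart disease.

During ventricular septation, a compartment boundary restricts the
intermingling of the two cardiomyocyte lineages that build the septum.
When the boundary fails — through reduced Tbx5 dosage or loss of the
guidance genes *Slit2* / *Ntn1* — the boundary lineage mispositions and
disorganizes, and ventricular septal defects (VSDs) appear. septaquant is
for developmental biologists and imaging scientists who need the
quantitative readouts of that process as tested, reusable code:

* **Lineage linear profiles** — rolling-ball background subtraction, slab
  maximum projections, midline-anchored profile sampling and aggregation,
  and boundary statistics: intensity-weighted position
  `m = Σ wᵢxᵢ / Σ wᵢ` and spread `s = sqrt(Σ wᵢ(xᵢ−m)² / Σ wᵢ)`, with
  Welch t / F group tests and pointwise Welch tests along the right–left
  axis.
* **Orientation scoring** — structure-tensor orientation θ and coherency
  `C = (λ₁−λ₂)/(λ₁+λ₂)`, gradient-weighted directionality histograms
  aligned to the dominant direction, pooled angle scores (0°±5°, 90°±5°),
  the two-sample Watson U² circular test (permutation or asymptotic), and
  the continuity-corrected Wilcoxon rank-sum test.
* **Serial-section morphometry** — on class-label stacks at 5 µm slice
  thickness: IVS fill, attached-trabeculation fraction, apical
  compact-layer thickness, VSD detection by LV/RV lumen contact,
  closing-path defect area `A = Σ cₖ·t`, membranous/muscular subtype
  assignment, and WGA/DAPI cell morphometry.
* **Genetic-interaction GLM** — a bias-reduced (Firth / Jeffreys-prior)
  binomial logistic regression
  `logit p = β₀ + β_T·d_T + β_G·d_G + β_TG·d_T·d_G` on allele-dose
  incidence counts, finite even for zero-event control groups, with an
  independent grid-search oracle of the penalized likelihood.
* **Synthetic phantoms** — ground-truthed generators for every input class
  (boundary reporter volumes, oriented textures, heart-like label stacks
  with drilled septal holes, elliptical cell masks, binomial incidence
  tables), so the whole pipeline is testable without external data.

## Worked example

Fit the bias-reduced allele-dose model to the packaged membranous-VSD
incidence counts of the Tbx5 × Slit2 cross (wild type 0/14, Tbx5 het 5/8,
Slit2 het 1/8, Slit2 hom 3/4, double het 5/8):

```r
library(septaquant)
counts <- read_genotype_counts(system.file(
  "extdata", "slit2_membranous_counts.csv", package = "septaquant"))
fit <- fit_allele_dose(counts)
print(fit)
#> Bias-reduced binomial GLM (Jeffreys-prior penalized likelihood)
#>             estimate     se       z      p
#> intercept    -4.1658 1.5543 -2.6801 0.0074
#> tbx5_dose     4.6177 1.7152  2.6923 0.0071
#> gene_dose     2.5025 1.0750  2.3280 0.0199
#> interaction  -2.5025 1.4858 -1.6843 0.0921
#> converged: TRUE in 10 iterations; penalized logLik -15.1874
reported_effects(fit)[c("het_logOR", "hom_logOR", "int_logOR")]
#> $het_logOR
#> [1] 2.50253
#> $hom_logOR
#> [1] 5.00506
#> $int_logOR
#> [1] -2.50253
```

Reading: each *Slit2* mutant allele multiplies the odds of a membranous VSD
by `exp(2.50) ≈ 12` in a Tbx5 wild-type background (log-odds 2.50 per
allele, 5.01 for homozygotes), while the negative interaction (−2.50)
means the double heterozygote shows *fewer* membranous defects than the
main effects predict — a genetic interaction between *Tbx5* and *Slit2*.

End-to-end phantom pipeline:

```r
cfg <- list(seed = 11, out_dir = tempfile(), stages = list(
  simulate = list(what = "boundary", boundary_center_um = 40,
                  boundary_width_um = 15, noise_sd = 0, cells = FALSE,
                  background_level = 0, shape_px = c(4, 24, 161),
                  voxel_size_um = c(10, 4, 4)),
  profiles = list(channel = "boundary", slab_um = 20)))
res <- run_pipeline(cfg)
mean(vapply(res$profiles$boundary, `[[`, 0, "m"))
#> [1] 40   # recovered boundary position, true 40 um
```

A command-line front-end with the same stages is installed at
`inst/cli/septaquant`
(`septaquant glm --config cfg.json --seed 1 --out dir/`).

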