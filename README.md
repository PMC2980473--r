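# transprot

Trans-organism proteome characterization against near-neighbor genomes.

## What it does

Global protein identification by shotgun proteomics needs a sequenced
genome to search against — which unsequenced environmental isolates do not
have. Their sequenced relatives, however, share enough protein-level
homology that spectra from an unsequenced bacterium can be matched against
a *near neighbor's* genome: every tryptic peptide whose sequence is
perfectly conserved in the neighbor is still identifiable. The usable
fraction decays with evolutionary divergence, measured here as the
pairwise 16S rDNA distance.

`transprot` implements that strategy end to end:

- **in-silico tryptic digestion** of reference proteomes into fully
  tryptic peptides (length ≥ 6, ≤ 2 missed cleavages, K/R|P block) and a
  peptide → protein index per genome;
- **PSM filtering**: log₁₀ E-value ≤ −8.3 (inclusive), length ≥ 6,
  fully tryptic, best E-value per peptide, and the ≥ 2-unique-peptide
  protein rule; E-value distributions summarized into percentile
  intervals A–E;
- **16S distances**: uncorrected p-distance from pairwise global
  alignment with affine gaps (optional Kimura correction);
- **conservation analysis**: the trans-organism search as exact peptide
  membership in the neighbor's digest, normalized observation ratios
  `r = n_neighbor / n_self`, ortholog category conservation, and
  genomic coverage-gap detection (TSV + BED output);
- **regression**: one-phase exponential decay
  `y = plateau + (Y0 − plateau)·e^(−k·x)` and the sigmoidal
  dose-response (4-parameter logistic)
  `y = bottom + (top − bottom)/(1 + 10^((x − m)·h))`, adjudicated by the
  extra-sum-of-squares F-test, with 95% *prediction* bands (the interval
  for a single future observation) via the delta method;
- **isolate characterization**: per-neighbor conserved counts, ratios,
  within-band flags, closest/furthest relatives, and coverage gaps along
  the closest relative's genome;
- a **clade simulator** (star phylogeny, per-site substitution at
  `κ·d` for proteins and `d` for the 850-bp 16S marker, seeded and fully
  reproducible) so the whole pipeline runs and is validated without raw
  MS data.

Fits are returned as classed S3 objects (`decay_fit`, `sigmoid_fit`) with
`print`, `summary`, `coef`, `predict` (with `interval = "prediction"`),
`residuals` and `plot` methods. See the vignette
`vignettes/trans-organism-proteomics.Rmd` for the models, assumptions and
design choices.

## Worked example

```r
library(transprot)

cl  <- simulate_clade(synthetic_config(
         target_16s_distances = c(0, 0.01, 0.02, 0.05, 0.1), seed = 1))
inp <- lapply(names(cl$taxa), function(tx)
         simulate_observation(cl$taxa[[tx]], digest_params(),
                              detection_config(seed = match(tx, names(cl$taxa)))))
names(inp) <- names(cl$taxa)

res <- run_panel(cl$taxa, cl$markers, inp)
subset(res$points, query == "T1")
#>    query neighbor distance   level n_self n_neighbor    ratio
#> 1     T1       T1  0.00000 peptide   3382       3382 1.000000
#> 6     T1       T2  0.00706 peptide   3382       1167 0.345062
#> 8     T1       T3  0.02941 peptide   3382        507 0.149911
#> 12    T1       T4  0.04941 peptide   3382         97 0.028681
#> 18    T1       T5  0.10353 peptide   3382          3 0.000887
```

Each row is one trans-organism search: of the 3382 peptides taxon T1
identifies against its own genome, 1167 are perfectly conserved in the
genome of its neighbor at 16S distance 0.007, for a normalized
observation ratio of 0.35 — and by distance 0.10 essentially nothing
survives exact matching.

```r
res$fit
#> One-phase exponential decay fit
#>          Y0     plateau           k
#>   0.9981120   0.0279131 151.3210000
#> n = 25, R2 = 0.9906, residual SD = 0.03987

round(prediction_interval(res$fit, 0.03), 3)
#>       lwr   upr
#> [1,] -0.047 0.123
```

The fitted decay starts at a ratio of ~1 at distance 0 and decays at rate
`k ≈ 151` per distance unit toward a ~0.03 plateau; the 95% prediction
interval at distance 0.03 brackets where a *single new* organism's ratio
should fall — the test applied to unsequenced isolates by
`characterize_isolate()`.

The canonical worked ratio: an organism with 4594 self-search peptide
identifications and 3067 against a neighbor genome has

```r
round(normalized_ratio(3067, 4594), 2)
#> [1] 0.67
```

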