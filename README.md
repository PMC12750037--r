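# caspr

Assessment of predicted protein monomer structures, in the style of the
CASP community experiments: structure-comparison metrics, composite
z-score rankings with bootstrap significance, and difficulty-matched
cross-experiment comparison — all exercisable on synthetic targets,
decoys and score tables, so the whole pipeline is testable without any
external data.

The package is aimed at assessors and method developers who need a
transparent, reproducible reimplementation of the standard evaluation
machinery: how a model is scored against an experimental target, how
per-metric scores become a ranking, and how claims like "group A
significantly outperforms group B" or "this round improved on the last
one" are given statistical backing.

## What it computes

**Structure metrics** (per evaluation unit, EU — a domain or group of
domains evaluated as one unit):

- `GDT_TS` / `GDT_HA` — percentage of CA atoms simultaneously fittable
  under one rigid superposition within cutoffs {1, 2, 4, 8} Å
  ({0.5, 1, 2, 4} Å for HA), averaged over cutoffs. The superposition
  search is seed-and-extend, validated against an exhaustive-subset
  oracle on small instances.
- `GDC` (all / mc / sc) — threshold-weighted distance agreement,
  `100 · Σₖ (11−k) Pₖ / 55` over thresholds `k·0.5` Å, k = 1…10, under
  the GDT reference superposition; `sc` uses one characteristic distal
  sidechain atom per residue type.
- `AL0_P` — percentage of residues whose model CA is both within 3.8 Å
  of and nearest to its target counterpart under the superposition.
- `lDDT` — superposition-free fraction of preserved inter-atomic
  distances (< 15 Å, thresholds {0.5, 1, 2, 4} Å).
- `ASE` (a.k.a. QSE) — self-assessment agreement,
  `100 − mean |pLDDT − lDDT|`, with pLDDT read from the model B-factor
  column.
- `AAA` — sidechain accuracy: per residue, the percentage of χ-angles
  within 40° of the target (symmetric terminal groups compared modulo
  180°), averaged over χ-bearing residues.

**Ranking** — the composite weighted z-score

```
Z = Σ_target Σ_EU w_EU [ 1/6 (z_GDT_HA + z_QSE + z_reLLG) +
                         1/8 (z_SphGr + z_CAD_AA) +
                         1/16 (z_GDC_SC + z_AL0_P + z_lDDT + z_MolProbity) ]
```

with `w_EU = 1/n_EUs` per target, two-round z-scores (outliers below −2
excluded, recomputation, final floor at −2, missing submissions at −2),
best-model and first-model selection rules, head-to-head bootstrap
significance (EU resampling, tie-splitting), and first-model-best
statistics against the 20 % random baseline. MolProbity, CAD_AA, SphGr
and reLLG_const are consumed as externally computed table columns.

**Cross-experiment progress** — Hungarian one-to-one matching of EUs on
a baseline-predictor difficulty scale, Gaussian-KDE weighted bootstrap
resampling, and a paired progress test.

**Synthetic data** — toy targets built from ideal internal coordinates,
decoys with graded coordinate/χ/pLDDT noise, and score tables drawn from
a latent group-skill × target-difficulty model.

## Worked example

Score a graded decoy against a synthetic 30-residue target:

```r
library(caspr)
spec   <- synthetic_spec(seed = 42, sigma_xyz = 1, sigma_chi = 20, plddt_tau = 5)
target <- build_target(spec, id = "toy")
model  <- make_decoy(target, spec, seed = 43, id = "toy_model")
round(compute_metrics(target, model)[c("gdt_ts", "gdt_ha", "gdc_sc",
                                       "al0_p", "lddt", "aaa", "ase")], 1)
#> gdt_ts gdt_ha gdc_sc  al0_p   lddt    aaa    ase
#>   75.8   54.2   53.5  100.0   65.5   32.3   94.8
```

At 1 Å coordinate noise, three quarters of the backbone still fits
within the GDT_TS cutoffs but the high-accuracy score is already down to
54; every residue remains correctly aligned (`AL0_P` 100) while 20°
χ-noise destroys most rotamers (`AAA` 32); the simulated predictor's
pLDDT tracks its realized lDDT to within ~5 points (`ASE` 94.8).

Rank simulated groups and recover the latent skill ordering:

```r
x   <- latent_experiment(n_groups = 8, n_targets = 10, seed = 3)
tab <- simulate_experiment(x)
aggregate_ranking(tab, attr(tab, "eus"), mode = "best")
#> Group ranking (total composite z, EU-weighted)
#>   group    total_z n_submitted
#> 1   G08 11.1073359           9
#> 2   G03 -0.3796889           8
#> 3   G05 -0.4539260           8
#> 4   G07 -0.5854940           9
#> 5   G06 -0.8451322           9
#> ...
```

which matches the true latent skill order (G08 > G03 > G05 > G07 > …).

A full assessment over PDB files on disk — scoring, external-metric
merging, both rankings, head-to-head bootstrap, manifest — runs through
`run_config()` / `run_assessment()`; see `?run_assessment` for the file
layout.

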