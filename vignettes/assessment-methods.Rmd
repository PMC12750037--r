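---
title: "Methods: metrics, rankings and statistics in caspr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metrics, rankings and statistics in caspr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caspr)
```

caspr reimplements the evaluation machinery used to assess protein
monomer structure predictions: per-model structure-comparison metrics,
a composite z-score ranking with an outlier-robust two-round protocol,
bootstrap head-to-head significance, and difficulty-matched comparison
between prediction experiments. This vignette is the package's own
account of those methods: the conventions it fixes, the parameters that
matter, what the synthetic-data generator does and does not emulate, and
the numerical choices behind edge cases.

## Structures and correspondence

Structures are read from PDB or minimal mmCIF (`atom_site` loop) into a
flat atom table. Alternate locations resolve to the highest-occupancy
copy (ties to the first in file). Hetero groups are kept separately and
survive EU extraction only within 5 Å of a kept residue, which is how
functional-site analyses find their ligands and metals.

Model residues are paired with target residues by identical author
numbering (chain, residue number, insertion code) — the submission
convention in community assessments, where models inherit target
numbering. There is deliberately **no sequence-alignment fallback**: a
renumbered model is an error, and residue-name mismatches at paired
positions are reported rather than repaired. Common nonstandard residues
(MSE, SEC, PYL, HYP) map to their parent standard type for metric
purposes; unmapped ones are kept but excluded from χ computation.

## Metrics

All internally computed metrics live on a 0–100 scale, score 100 exactly
on identical structures, and are invariant to rigid motions of either
input (lDDT exactly so, since it never superposes).

**GDT.** The score at one cutoff is the maximal fraction of paired CA
atoms that fit simultaneously under one rigid, reflection-free
least-squares superposition with deviation at most the cutoff; GDT_TS
averages cutoffs {1, 2, 4, 8} Å and GDT_HA {0.5, 1, 2, 4} Å. Finding
that maximum is a search problem. The implementation seeds a
superposition from every contiguous window of length 3, 5 and 7 (plus
the full set), iteratively re-fits on the residues within the cutoff
until the selected set is stable (at most 10 iterations), and
additionally re-fits on the j closest residues over a coarse ladder of
j, which keeps the search from being trapped by one inconsistent far
atom. Every evaluated superposition competes for the best count. For
small instances — at most ~1000 candidate subsets, i.e. up to 10
residues — the implementation simply enumerates all subsets of size ≥ 3,
making the search provably optimal there; the `exhaustive` mode exposes
the same enumeration (up to 12 residues) as an independent oracle, and
the test suite pins heuristic = oracle on randomized 8-residue
instances. The returned reference superposition is polished by re-fitting
on the full within-cutoff set, so downstream metrics see the
least-squares fit over the largest consistent residue set, not a raw
seed fit.

**GDC.** `100 · Σₖ (11−k) Pₖ / 55` with `Pₖ` the fraction of selected
target atoms whose model counterpart lies within `k · 0.5` Å (k = 1…10)
under the GDT reference superposition (fit at the classical 4 Å
distance). Selectors: `mc` = N, CA, C, O; `all` = all heavy atoms; `sc`
= one characteristic distal atom per residue type (Ser OG, Leu CD1, Phe
CZ, …; the table ships in the package since no canonical list is
universal). Missing model atoms stay in the denominator and fail every
threshold — incomplete models are penalized, not silently excused.

**AL0_P.** A residue is correctly aligned iff its fitted model CA is
within 3.8 Å of the target CA *and* that target CA is the nearest target
CA to it. The 3.8 Å value (one CA–CA step) and the nearest-neighbor
condition are the package's fixed convention for this score.

**lDDT.** Reference set: all heavy-atom pairs from different target
residues closer than 15 Å. A pair is preserved at threshold t ∈
{0.5, 1, 2, 4} Å iff the model reproduces its distance within t; pairs
with missing model atoms count as not preserved. Per-residue lDDT is the
mean preserved fraction over thresholds among pairs involving the
residue; the global score is the mean over residues (so sparse residues
are not over-weighted). No stereochemistry check is applied.

**ASE.** The self-assessment score compares submitted pLDDT (model CA
B-factor, 0–100) with realized per-residue lDDT. The functional form is
`100 − mean |pLDDT − lDDT|`, clamped to [0, 100] — the simplest form
consistent with "agreement between pLDDT and lDDT"; it is linear, has a
perfect score of 100, and penalizes over- and under-confidence
symmetrically. This is a documented package choice; other monotone
transforms of the mean absolute difference would rank similarly.

**AAA.** Per residue with at least one target χ-angle, the percentage of
target-defined χ-angles whose model counterpart deviates by at most 40°
(circular difference); the comprehensive score is the unweighted mean
over such residues. Terminal groups with twofold symmetry (Asp, Phe, Tyr
χ2; Glu χ3) are compared modulo 180°, so a flipped ring is not an error.
A missing model χ (truncated sidechain) fails. Because AAA depends only
on dihedrals it is independent of backbone accuracy, which is exactly
why it complements the superposition-based GDC_SC.

**Alternative conformations.** When a target has several deposited
conformations, every metric is evaluated against each version and the
maximum is kept — a model matching *any* experimentally observed state
is credited.

## Ranking

Raw scores enter as a long table (group, target, EU, phase, model,
metric, value). Externally computed metrics (MolProbity, CAD_AA, SphGr,
reLLG_const) are merged by key; they are consumed, never recomputed.

**Within-model imputation.** A submitted model lacking one metric gets
the worst observed value of that metric on the EU (minimum, or maximum
for lower-is-better metrics) — missing pieces of a submission should not
beat scored ones. Entirely missing submissions are handled later, at the
z level, and the two stages apply per metric independently.

**Two-round z.** Per EU and metric (lower-is-better metrics negated
first): z from the mean and *population* standard deviation of all
values; entries below −2 are excluded as outliers; mean/sd are
recomputed from the remainder and applied to **all** groups, including
the excluded ones; final z floors at −2; groups with no submission get
−2. Conventions fixed here because no universal ones exist: population
rather than sample sd (the group set is the population being ranked);
zero round-2 spread gives members z = 0; round-1 outliers are re-scored
from round-2 parameters and then floored (their information content is
"bad", and the floor caps how bad). A floor at 0 is available as an
alternative strategy; on dominance cases both floors agree on the top
ranks, and the −2 floor is the default because it discriminates better
among consistently good groups.

**Composite and totals.** The composite is the weighted sum of the nine
per-metric z-scores — 1/6 for GDT_HA, QSE/ASE and reLLG_const, 1/8 for
SphGr and CAD_AA, 1/16 for GDC_SC, AL0_P, lDDT and MolProbity (weights
sum to 1). Group totals weight each EU by `1/n_EUs` of its target so
every target counts equally. Best-model selection maximizes a per-model
composite z computed across all models of the EU (ties to the lowest
model index, for determinism); first-model selection takes index 1 or
the lowest submitted index. Model 6 — the constrained-input extra model
— is excluded from first/best pools and evaluated separately through
ratio statistics (`model6_ratio()`).

**Bootstrap significance.** Head-to-head comparisons resample the common
EUs of a pair with replacement (1000 replicates by convention), compare
EU-weight-weighted composite sums, and split ties 0.5/0.5 so that a
group against itself is exactly 0.5. Significance at confidence α means
a win fraction of at least 1 − α; groups are ordered by win-fraction row
sums. One random stream per unordered pair keeps the matrix exactly
complementary. No multiple-testing correction is applied, matching
assessment practice.

## Cross-experiment comparison

Comparing two experiment rounds is confounded by target difficulty, so
both comparison routes first equalize difficulty, proxied by a fixed
baseline predictor's first-model GDT_HA per EU:

- `hungarian_match()` finds the one-to-one assignment of the reference
  round's EUs to source-round EUs minimizing the total absolute
  difficulty difference (shortest-augmenting-path assignment, O(n³);
  surplus source EUs stay unmatched; ties break to the lower source
  index). `progress_test()` then applies a paired t-test (or Wilcoxon)
  to the matched best scores; with zero variance in the differences the
  p-value is taken as the analytic limit (1 for zero mean difference, 0
  otherwise). The paired t-test is the default because the matched
  difficulty differences are small and approximately symmetric; both
  tests are available since the choice is a convention.
- `kde_weighted_resample()` fits Gaussian kernel density estimates
  (Scott's rule bandwidth `sd · n^{-1/5}` by default) to both difficulty
  distributions and resamples source EUs with weights ∝ f_ref/f_src, so
  each bootstrap sample mimics the reference difficulty distribution;
  the default sample size is the reference set size. Densities below a
  documented floor are clipped with a warning.

## Synthetic data: what it emulates, and what it does not

`build_target()` grows a backbone from ideal internal coordinates
(helix φ/ψ = −57/−47, strand −120/+120, coil drawn from allowed
Ramachandran regions) and places sidechains from ideal rotamer templates
for a curated palette (Ser, Leu, Phe, Arg, plus Gly/Ala) — enough
χ-complexity to exercise every sidechain metric without a full rotamer
library. `make_decoy()` perturbs each χ by Gaussian noise (rotating the
distal atoms about the bond), adds i.i.d. Gaussian noise to every atom,
and writes pLDDT = clamp(per-residue lDDT + Gaussian(0, τ), 0, 100) into
the B-factors, so the simulated predictor's confidence tracks its true
local accuracy up to τ. `simulate_experiment()` draws score tables from
value = base + skill(group) − difficulty(target) + noise, clipped to
each metric's range, with whole submission blocks dropped at the
missingness rate; defaults (20 groups, 30 single-EU targets, noise sd 5,
skill spread twice the noise, 10 % missingness) define the regime in
which ranking recovery is expected and tested.

What the generator does **not** emulate: correlated, segment-wise errors
(real model errors move rigid pieces, not atoms independently);
physically plausible bond geometry in noisy decoys; heteroatom sites in
targets (ligands must be added explicitly); metric-specific biases of
the externally computed scores. Consequently, passing tests demonstrate
the *evaluation machinery* — not that the metrics capture every
pathology of real predictions.

One consequence of i.i.d. atomic noise deserves note: beyond roughly
2 Å, dihedrals computed from noisy coordinates are essentially random,
so AAA saturates at its random-rotamer floor (about 25 with this
palette) and differences between high-noise levels become small relative
to replicate noise. The monotonicity harness therefore couples χ noise
to the grid at 5° per 0.1 Å of coordinate noise, which spans AAA's
sensitive range at the low end while the floor region contributes only
weakly-powered (though still genuinely decreasing) differences.

## Numerical choices and edge cases

- Rigid fits use the SVD (Kabsch) solution with the reflection branch
  forbidden; sets with fewer than 3 points or collinear geometry are
  errors. The GDT inner loop inlines the same mathematics for speed.
- Population sd throughout the z machinery; sd = 0 ⇒ z = 0 for members.
- Quantiles (e.g. GDT_TS95 for difficulty classification) use R's
  default type-7 linear interpolation, stated here because difficulty
  labels can sit on the boundary.
- Grishin merge check: degradation = median over models of
  min(part scores) − merged score; merge iff degradation ≤ tolerance
  (boundary merges). The median resists a few outlier models.
- Best-model ties, Hungarian ties, and altloc ties all break toward the
  lower index/first occurrence — determinism over cleverness.
- EU residue ranges are inclusive on both ends, in author numbering.
- All randomness (bootstrap, KDE resampling, generators) flows through
  explicit integer seeds; identical inputs and seeds give byte-identical
  pipeline outputs.

## Problem sizes in the test and acceptance runs

The shipped tests run on 30-residue targets (20 replicates per noise
level in the monotonicity harness), 200 randomized 6–8-residue instances
for the GDT oracle comparison, 100 000 simulated EUs for the
first-model baseline, 20 × 30 latent score tables over 10 seeds for
ranking recovery, and 1000-replicate calibrations for the bootstrap and
the progress test. These sizes were chosen so each property is measured
with comfortable statistical power while the whole suite stays quick on
a single CPU.

## Known limitations

- No sequence-alignment fallback for renumbered models, by design.
- No symmetry/assembly expansion and no hydrogen handling.
- The GDT heuristic is provably optimal only for small instances; at
  realistic sizes its quality is supported by the oracle tests at small
  n and the monotonicity/identity properties, not by proof.
- MolProbity, CAD_AA, SphGr and reLLG_const are external inputs; when
  absent, the weight scheme renormalizes (with a prominent warning)
  rather than failing, and a strict mode refuses instead.
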