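---
title: "Methods: clustering, damage screening, scaling and pruning in isomerge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering, damage screening, scaling and pruning in isomerge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Crystals of membrane proteins and other difficult macromolecules rarely
survive long enough in the beam to yield a complete diffraction dataset:
radiation damage limits each crystal to a small wedge of reciprocal space.
A complete dataset must then be assembled by merging wedges from many
crystals — but only crystals that are genuinely isomorphous (structurally
close enough, proxied by their unit-cell parameters) can be merged without
degrading the data. `isomerge` manages this workflow end to end: it
clusters datasets on cell parameters, annotates the clusters with an
isomorphism score, screens each dataset for radiation damage and usable
resolution, scales and merges any chosen group with standard quality
statistics, and optimises merges by pruning damaged image tails.

# Isomorphism scoring: LCV and aLCV

For each unit cell the three cell faces — (a, b, gamma), (b, c, alpha),
(a, c, beta) — define parallelograms; `face_diagonals()` returns the longer
diagonal of each, `max` over the sign in `sqrt(p^2 + q^2 ± 2pq cos θ)`.
Both diagonals coincide at 90°, the dominant crystallographic case; the
longer-diagonal convention is stated here because it matters for strongly
oblique cells, and it is isolated in one function.

Across a group of cells, the **absolute Linear Cell Variation (aLCV)** is
the largest pairwise difference of matching face diagonals, in Å; the
**LCV** expresses that worst pair as a percentage of the smaller diagonal
of the pair. Experience places the onset of problematic non-isomorphism
near LCV = 2 %. Both are monotone under cluster growth: a superset's
maximum cannot shrink, so annotations never decrease towards the root of
the tree.

# Clustering

Datasets are described by their six cell parameters, each component
standardised to zero mean and unit variance across the input (constant
components are left at zero), and clustered agglomeratively with Ward
linkage on Euclidean distances (`stats::hclust(method = "ward.D2")`).
Internal nodes are numbered n+1 … 2n−1 in merge order above the n leaf
serials, and every node carries the LCV/aLCV of its members' *raw* cells.

Standardisation has a consequence worth knowing: a component that carries
only measurement jitter is inflated to the same unit variance as a
component that carries real group structure. A between-group offset
confined to a single cell edge can therefore be washed out by jitter on
the other edges no matter how small that jitter is in Å. Real
non-isomorphism in this class of crystals is predominantly an overall
cell-size change (solvent/detergent swelling), which is what the synthetic
generator emulates — its `group_shift` moves all three edges together, and
such groups are recovered exactly.

Merge heights are linkage-dependent quantities; they are useful for
choosing a cut ("any value above the root height merges everything") but
have no absolute physical meaning, and no attempt is made to reproduce any
particular height value.

Outlier flagging (`flag_outliers()`) peels the root's smaller child branch
repeatedly until the survivors' LCV drops under the threshold. Peeling
branches rather than individual leaves matters: when several gross
outliers are present, removing any single one barely changes the max-pair
LCV, and a leaf-wise greedy search would start peeling extreme members of
the isomorphous core instead. The result is advisory — the package never
deletes datasets; the user edits the input list and re-runs, as in the
manual workflow the tool supports.

# Radiation-damage screening

Within each of (by default) 10 equal-population resolution shells in
s = 1/d², the mean positive intensity per image is modelled as a single
exponential: `ln(mean I)` is regressed on image number by ordinary least
squares, giving a per-shell decay rate (per image). Damage is declared
when decay *increases with resolution*: a weighted regression of decay on
shell s-midpoint (weights 1/se² from the shell fits) with a one-sided
t-test on the slope at α = 0.05. The realised false-positive rate on
undamaged simulations is close to the nominal 5 % (slightly above it at
times, since the weights are themselves estimated).

When a dataset is flagged, the suggested last accepted image comes from
the highest-resolution usable shell's decay B — damage bites there first —
as `first_image − 1 + floor(ln(1/RADFRAC)/B)`, clamped to the image range;
`RADFRAC` (default 0.75) is the retained-intensity fraction. Flooring
keeps the retained wedge conservative. Wedges of fewer than 5 images are
not assessed: the model needs a minimal dose range.

Two honest limitations. First, the log-mean fit is biased once the
decaying signal falls to the noise floor (the mean *positive* intensity
flattens at the background level), so under very heavy damage the fitted
decay under-estimates the true rate and the trend test loses power; the
image-pruning mode is the safety net for exactly those datasets. Second,
the procedure assumes a stable beam and constant exposed crystal volume —
for long sweeps of large crystals its suggestions should be reviewed, and
they are always overridable.

# Resolution estimation

Shell-averaged mean intensity, mean sigma and their ratio are computed on
*all* images of the raw, unscaled data (20 equal-population shells by
default; fewer for small datasets, aiming at ≥ 5 observations per shell).
A polynomial of degree min(10, n_shells − 1) is fitted by least squares to
ratio versus s — with the default 20 shells this is a smoothing fit, an
exact interpolant only when the shell count makes it so. The fit is
evaluated on a 1000-point grid over the observed s range; the first grid
point (scanning from low resolution) where the curve falls below `ISIGI`
(default 1.5, deliberately conservative) is reported as d = 1/sqrt(s),
rounded to 3 decimals in the output files. If the curve never crosses, the
dataset's own resolution limit is returned; if even the first shell is
below threshold, the lowest-resolution grid point is returned with a note.
Fitting against s (not d or shell index) is this package's convention.

# Scaling and merging

Observations are mapped to canonical unique reflections (lexicographically
greatest triple of the symmetry orbit; Friedel mates equivalent by
default). Shipped operator sets cover P1, P2, P2₁, P222, P2₁2₁2₁, P4 and
P6 — rotation parts only, which is all index mapping needs; arbitrary
groups can be supplied as matrices. Space-group *determination* is out of
scope: the header symbol is trusted.

Before scaling, a tolerance check refuses groups whose cells differ by
more than `TOLERANCE` percent on an edge or degrees on an angle (default
2; 100 disables the check, the escape hatch for deliberately merging
heterogeneous crystals).

The scale model per dataset j is the standard two-parameter correction
`I_corrected = k_j · exp(−2 B_j s) · I_obs`, fitted by alternating least
squares: (1) merged means per unique reflection under current scales;
(2) per-dataset `(ln k_j, B_j)` from a closed-form regression of
`ln(I_obs/⟨I⟩)` on s over positive-intensity, multiply-observed
reflections. The lowest-serial dataset is pinned at k = 1, B = 0; the loop
stops when the largest scale change falls below 1e−6 (100 iterations
maximum, with a warning). Merged means in the loop are unweighted, which
keeps the iteration independent of the concurrent sigma rescaling. This is
a deliberate minimal replacement for a full scaling engine: no absorption
surfaces, detector corrections, partiality or per-observation outlier
rejection.

A subtlety of B recovery on synthetic data: B multiplies the dataset's
*own* s, so when cells within a group differ (jitter), each dataset's
s-scale differs by O(δcell/cell) and the planted B is only identifiable up
to an O(B · δs/s) frame ambiguity (≈ 3e−3 relative at 0.05 Å jitter on a
40 Å cell with B up to 10 Å²). Strict recovery benchmarks therefore use
cell-identical groups; under jitter the same scaling is validated through
the merged statistics (noiseless groups reconcile to R_meas < 0.01).

Merging is the inverse-variance weighted mean per unique reflection, with
merged sigma `(Σ 1/σ²)^(−1/2)`. Quality statistics use the textbook
definitions over reflections with ≥ 2 observations (⟨I⟩ the plain mean):

* `R_merge = ΣΣ|I − ⟨I⟩| / ΣΣI`
* `R_meas` weights each reflection by `sqrt(n/(n−1))`, `R_pim` by
  `sqrt(1/(n−1))`; hence `R_meas ≥ R_merge ≥ R_pim` always.
* completeness = observed unique / theoretical unique to d_min, the
  denominator by direct enumeration of the index box (exact for the
  near-orthogonal cells used here; for extremely oblique cells the box
  margin of +1 index per axis could in principle clip corners).
  Epsilon/centric corrections and screw-axis absences are ignored — a
  documented approximation affecting absolute completeness marginally.
* CC½ by a seeded random half-split of each reflection's observations
  (deterministic given `SEED`; the σ-τ closed form is not used).
* Per-shell versions of everything in 10 equal-population shells, plus
  three resolution criteria: finest shell with CC½ > 0.3, finest with
  Mn(I/sd) > 2, and the applied limit itself. Thresholds are configurable.

# Modes, combination syntax and pruning

The five execution modes mirror the data-management workflow: quick
clustering (`mode_dendrogram_only()`), full screening
(`mode_analysis()`, writing the six-column final list), per-node merging
under a height or aLCV cut (`mode_synthesis()`, statistics table sorted by
descending completeness), free grouping (`mode_combination()`, selections
like `"[49] [[41]]"` — include tokens resolve to cluster ids first, then
dataset serials; double brackets exclude), and graphics. A thin CLI
(`inst/exec/isomerge`) dispatches the same functions with keywords read
from standard input.

Pruning (`mode_pruning()`) addresses damage that survives the image
cutoff: cycle 0 merges the selection unchanged; each cycle then removes
the trailing 10 % (`PRUNEFRAC`, minimum one image) of the currently
accepted images of the dataset with the worst per-dataset R_merge
contribution (its own Σ|I − ⟨I⟩| / ΣI over multiply-observed reflections,
on the current scaling), and re-merges. Images are removed from the tail
because damage accumulates with dose. Cycling halts when completeness
falls below the target (default 95 %, that cycle discarded), at
`MAXCYCLES` (default 20), or when a dataset would be eliminated entirely;
the victim is re-selected every cycle. The cycle with the lowest R_pim
wins, cycle 0 included — so on clean data the procedure is a no-op by
construction, which the tests verify.

# The synthetic generator

No suitable multi-crystal reflection data can be bundled, so every test
runs on `synthgen` simulations with known ground truth:

* **Truth**: unique reflections of the base cell to d_min with intensities
  drawn from an exponential (acentric Wilson) distribution whose mean
  falls as `exp(−2 B_wilson s)`, B_wilson = 20 Å². The Wilson scale
  (default mean 5000 at s = 0) is chosen so the highest shells sit clearly
  above the background noise floor — data should be usable to their
  nominal d_min, and a scale that buries the top shells in noise mostly
  tests the noise floor, not the procedures.
* **Cells**: groups differ by an overall size offset on all three edges
  (`group_shift`); within-group edges jitter with sd `cell_jitter`;
  outliers get a gross shift on every edge.
* **Wedges**: a shuffled walk through the unique list assigns
  `obs_per_image` observations per image (recycling gives within-dataset
  multiplicity); each observation records a random symmetry mate. This is
  deliberately *not* a geometric diffraction simulation — no Ewald-sphere
  geometry, mosaicity or partiality — which is irrelevant to everything
  tested here.
* **Physics**: `I = k · e^(−2Bs) · e^(−2 B_dam (img−1) s) · I_true` plus
  Gaussian noise with `σ = sqrt((noise_frac · I)² + background²)`. Damage
  is a per-image B-factor growth, so the apparent per-shell decay is
  `2 B_dam s`, fastest at high resolution — the signature the damage test
  looks for. A dose-uniform (resolution-flat) decay would be invisible to
  that test by design.
* **Rogues**: per-image log-normal scale jitter, an error no smooth
  (k, B) model can absorb; a plain global scale error would be fitted away
  exactly and could never make a dataset "rogue".

Named scenarios fix the study conditions: `teha_like` (67 short wedges:
two tight sub-groups of 31+32 plus 4 gross outliers, 20–40 images,
damage widespread), `h1r_like` (18 long sweeps in 3 loose groups),
`two_group` (2 × 5 noiseless wedges, shift 2 Å, jitter 0.05 Å),
`rogue` (6 datasets, one planted rogue) and `damaged` (5 full-coverage
datasets, one with a heavily damaged tail; true scales kept homogeneous so
damage is the *only* quality defect — otherwise pruning would also,
correctly, chase genuinely weaker crystals and the clean-data no-op check
would be confounded). Everything is deterministic under the seed, and a
JSON manifest records all ground truth for recovery tests.

What passing these tests shows — and what it does not: the procedures
recover planted structure under counting-type noise and idealised wedge
geometry. Real data add absorption, non-isomorphism beyond cell size,
partiality and indexing ambiguities that the generator intentionally omits;
results on real crystals therefore still require the interactive scrutiny
(dendrogram reading, combination experiments) the tool is built around.

# Problem sizes and numerics

The shipped tests and the acceptance script use the scenario defaults
above (e.g. the 67-wedge clustering bed merges all 62 nodes of its
63-dataset tree in well under a minute). Tie-breaks are deterministic
throughout: serial order for reference-dataset choice, lexicographic key
canonicalisation, seeded half-splits for CC½. Degenerate inputs (single
dataset, empty shells, all-singleton reflections, unconnected groups) are
either handled with documented conventions or refused with specific
errors; R statistics are reported as absent when no reflection has two
observations.
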