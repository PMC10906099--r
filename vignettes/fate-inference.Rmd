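---
title: "Timecourse fate inference with optimal transport: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timecourse fate inference with optimal transport: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatecourse)
```

## Overview

`fatecourse` implements the computational core of optimal-transport
trajectory inference for a developmental single-cell timecourse: from raw
counts with per-cell time point, batch and anatomical section labels to
fate probabilities, fate-bias statistics, descendant allocations, and
fate predictions for mapped query cells. This vignette explains the
models and the numerical and design choices, stage by stage, and states
what the synthetic validation does and does not establish about real
data.

## The synthetic timecourse generator

Validation needs ground truth, so the package ships a generator whose
statistical structure matches what the analysis assumes.

**Lineage model.** A rooted tree of cell states: each state has a
nonnegative per-gene expression program, a strictly positive exponential
growth rate (per day), a birth time, and (unless terminal) a branch time
at which its children appear. `build_lineage_tree()` spaces branch
levels evenly across the timecourse and derives each child's program from
its parent's by perturbing a fraction of genes (30% by default) with
lognormal fold changes, so sibling branches are separable but related.

**Occupancy.** The deterministic branch-mass model: the root carries mass
1 at birth, mass grows as `exp(g·t)` while a state is active, and at a
branch time the parent's mass splits equally among its children.
`state_occupancy()` evaluates this in closed form; cells at each grid
time are sampled from the normalised active-state masses. A test verifies
the closed form against an independent forward-Euler integration, and
that sampled state fractions converge to it.

**Expression.** A cell's latent mean interpolates linearly from its
parent's program (at the state's birth) to the state's own program (at
its branch time), so trajectories are transcriptionally continuous —
the property the landscape construction downstream relies on. Counts are
negative binomial around the mean scaled to the target depth
(`variance = mu + dispersion·mu^2`); dispersion 0.1 is a typical
single-cell overdispersion, and `dispersion = 0` gives Poisson noise.

**Ground-truth fates.** Each cell carries the analytic probability of
ending in each terminal state: unit mass pushed from the cell's state and
time through the tree to the end of the grid under the stated growth
rates, split equally at branch points (mass still sitting in an internal
state at the horizon is divided equally among its terminal descendants).
For a two-branch tree this reduces to the two-type growth equations; the
test suite checks it against a `deSolve` integration. One structural
consequence worth knowing: at the branch time itself the two sibling
states still share the parent's program, so cells there are labelled but
not yet transcriptionally distinguishable — expectations about branch
recovery are therefore evaluated from the first post-branch time point.

**Batch structure.** `inject_batch_effect()` adds a per-batch, per-gene
offset on the log2 scale (re-rounded to counts), with the first batch as
the zero-offset reference and the drawn offsets stored for oracle
checks. This is exactly the additive structure mutual-nearest-neighbour
correction is designed to remove; the generator makes no attempt at
nonlinear or cell-type-specific batch distortions.

**Defaults as study conditions.** The default configuration — 5 time
points at 6-hour (0.25-day) spacing, 500 cells per time point, 300
genes, count depth 5000, dispersion 0.1, two batches with log2-offset
magnitude 0.25 — is the scale at which all end-to-end properties are
evaluated. It is a deliberately desk-sized analogue of an atlas-scale
timecourse (hundreds of thousands of cells across 13 stages): large
enough that KNN, MNN and OT behave in their asymptotic regimes, small
enough that the full pipeline runs in seconds.

## Preprocessing

**QC.** Cells with fewer than 10,000 total counts (the conventional
cutoff for deep plate-based libraries) or a mitochondrial fraction above
4% are removed, with a per-cell report of totals, genes detected, mito
fraction and failure reason.

**Size factors.** Library-size factors rescaled to geometric mean 1.
Pooling-based deconvolution factors would differ on strongly
composition-biased data, but on the generator's data (where library size
is the only depth signal) they coincide, and the centred-at-unity
contract is what downstream log-normalisation depends on.

**Normalisation.** `log2(count / sf + pseudocount)` with pseudocount 1,
so zeros map to zero and the transform is monotone.

**Highly variable genes.** A loess trend (degree 1, span 0.05 as a
fraction of genes) of per-gene variance on per-gene mean; each gene's
variance ratio above the trend is tested with a scaled chi-square
approximation, `(n−1)·var/trend ~ chi²(n−1)` under the null, and
Benjamini–Hochberg correction selects genes at FDR < 0.05. Genes with
mean log2 normalised count below 1e−3 and genes on a user blacklist
(sex-linked genes, reporter constructs) are excluded regardless of
variance, with the exclusion reason recorded. The chi-square
approximation is the simplest test consistent with a BH-adjusted p <
0.05 selection rule; it is anti-conservative if the normalised values
are heavy-tailed, which matters little here because selection feeds a
PCA rather than an inference.

**PCA.** Centred, unscaled PCA on the selected genes; 50 components by
default (configurable to 75 for an atlas-like embedding). Component
signs are fixed by making the largest-magnitude loading positive, so the
embedding is fully deterministic.

**MNN batch correction.** Batches are merged sequentially (largest
first by default). For each incoming batch, mutual nearest neighbour
pairs (k = 20 each way) against the accumulated reference define
correction vectors (reference minus incoming position); every incoming
cell receives a Gaussian-kernel-weighted average of these vectors. Two
choices deserve comment:

* *Kernel bandwidth.* The bandwidth is 0.5 times the mean
  reference–incoming distance. A narrow kernel lets each cell's
  correction be dominated by its own pairs, whose mean is displaced
  toward the local neighbour centroid; on two identical batches this
  distorts neighbourhoods enough that duplicated cells no longer map to
  their originals. A wide kernel makes the correction field
  near-constant per batch — the correct behaviour under the additive
  batch model — and leaves coinciding batches essentially untouched. We
  verified both regimes on the identity and constant-shift fixtures and
  chose the wide default accordingly.
* *Location re-matching.* Mutual pairs form only between the facing
  surfaces of the two batch clouds, which systematically underestimates
  a shared shift (the "kissing" effect). After the smoothed per-cell
  correction, the incoming batch is translated along the mean pair
  vector so the median projections of the two batches coincide — but
  only when the mean pair vector is distinguishable from its sampling
  noise (above 3 standard errors), so batches that already coincide are
  not nudged. With this step a constant 10-dimensional shift is
  recovered with under 10% relative error at 500 cells per batch.

## Query mapping and label transfer

Reference and query counts are merged on shared genes, normalised and
log-transformed together, and HVGs and PCA are computed once on the
merged data; the query is then rescaled onto the reference by MNN
correction, treating the query as the incoming batch. Queries larger
than `chunk_size` (default 10,000 cells) are split into contiguous
blocks after a seeded shuffle; each chunk is corrected against the
reference independently and results are concatenated in the original
order. Computing the joint PCA once (rather than once per chunk) keeps
all chunks in a common coordinate system; chunked and unchunked mapping
agree for over 95% of transferred labels in the tests.

Labels transfer as the mode of the k nearest reference neighbours
(exact Euclidean KNN — no approximate index at these scales), with
confidence = mode count / k. Ties are broken by the label of the nearest
neighbour among the tied labels, then lexicographically — deterministic
and auditable. Conventional choices of k: 30 for stage (time-point)
transfer, 10 for fine cell types, 15 for deep-coverage query cells.
`nearest_reference_cells()` provides the exact closest-atlas-cell lookup
used for fate prediction. Note that the mode-of-KNN stage accuracy is
bounded by genuine temporal continuity: on a timecourse whose stages
overlap transcriptionally no transfer rule can reach near-perfect stage
recovery, so the ≥99% stage bar is evaluated on stage-separated
references.

## Unbalanced entropic optimal transport

Between consecutive time points the coupling `γ` minimises

    <γ, C> + ε·KL(γ || a⊗b) + λs·KL(γ1 || a) + λt·KL(γᵀ1 || b)

with `C` squared Euclidean distance in the corrected embedding
(optionally divided by its median so `ε` is scale-free; the pipeline
does this by default). Defaults `ε = 0.05`, `λs = 1`, `λt = 50` mirror
the published defaults of the unbalanced-OT trajectory framework this
module implements: a soft source marginal lets proliferation and death
reweight ancestors, while the near-hard target marginal keeps the
observed later population fixed. `λ = Inf` makes a marginal exact
(balanced transport).

**Solver.** Alternating Sinkhorn scaling, `u = (a/(Kv))^(λs/(λs+ε))` and
symmetrically for `v`, with `K = exp(−C/ε)`; iteration stops when the
successive change of the log scaling vectors falls below the tolerance
(1e−8) or at `max_iterations` (5000, with a warning and a non-converged
flag — never a silent failure). When `ε` is below 1% of the median cost,
or whenever the plain scalings overflow, the solver switches to
log-domain updates on the potentials (`phi = ε·log u`) with log-sum-exp
reductions, which is how the 2×2/3×3 oracle problems at `ε = 1e−3` are
solved; the brute-force LP comparison there enumerates permutation
vertices, valid for uniform marginals by Birkhoff's theorem.

**Growth learning.** Three alternations by default: set source weights
`a_i ∝ g_i^dt` (normalised), solve, then update
`g_i = (row mass_i / mean row mass)^(1/dt)`, floored at 0.05. Growth is
initialised at 1 for synthetic data; `initial_growth` accepts
user-supplied per-cell proliferation scores where signature-based
estimates exist. Because `1/dt` is 4 at 6-hour spacing, the update
amplifies row-mass variation; learned rates are diagnostic of relative
expansion (the tests check ordering, and symmetry of the fixture returns
rates within 0.05 of 1) rather than calibrated absolute rates.

**Composition and pushing.** Couplings are row-normalised into
transition matrices and multiplied left to right; composition is
associative and always row-stochastic regardless of input scaling.
Forward pushing propagates a distribution through the row-normalised
chain (descendants); backward pushing uses the column-normalised chain
in reverse (ancestors). `collapse_timepoints()` merges stages whose
developmental age overlaps (the analogue of collapsing the last two
stages of an atlas before computing maps); merging non-adjacent time
points is allowed but warned about.

## Fate matrices, log odds, landscapes, descendants

The **fate matrix** toward named, disjoint terminal target sets assigns
every cell the row of the composed transition matrix summed within each
set and within the complement ("other_fate"); terminal cells get
indicator rows. Rows sum to 1 by construction — the machine-checkable
form (±1e−9, observed at ~1e−15) of the statement that fate matrices
are transition probability matrices.

The **log odds** is `ln(p/(1−p))` with `p` the summed probability over
the fates of interest, clipped to `[1e−12, 1−1e−12]` so the statistic
stays finite at the simplex boundary (`ln` at the clip is ±27.6).
Natural log is the odds convention. The statistic is 0 exactly at
`p = 0.5`, strictly increasing, and antisymmetric. Landscape selection
keeps cells with log odds strictly greater than the threshold —
matching the printed conventions `> 0` (clearly fate-biased), `> −0.5`
and `> −1` (complex landscapes where near-threshold cells may still
contribute) — optionally restricted to eligible state annotations;
masks are nested across decreasing thresholds, and the selected subset
carries all metadata forward for re-running HVG/PCA/MNN.

**Descendant allocation** pushes each source population's indicator
forward and assigns every later cell to the population of maximal pushed
mass. Masses are unnormalised by default (each source cell contributes
1), so larger populations claim proportionally more descendants — the
natural reading of "maximum mass"; `normalize_populations = TRUE`
switches to per-population-normalised masses for the other reading.
Exact ties go to the lexicographically first population and are flagged.

## Fate prediction and concordance

A query cell's predicted fate is the arg-max of the fate-matrix row of
its nearest atlas cell (ties lexicographic, flagged), with the
probability reported. The fate matrix may be built to an intermediate
reference time rather than the terminal point, so predictions can be
capped at the stage where experimental fate readouts exist.
`fate_fraction_table()` tallies assignments into region × fate fractions
(rows sum to 1; cell-count and embryo-count bases are recorded, the
latter row-normalised before comparison). `concordance_score()`
harmonises fate names through an explicit user-supplied mapping (never
fuzzy matching), restricts to shared fates, and reports per-region
cosine similarity and Spearman rank correlation plus their means — two
metrics so neither is privileged, since observed-versus-predicted
comparisons in this field are typically qualitative — against a seeded
shuffled-region permutation baseline.

## Marker detection

Two parameterisations, matching the two conventional tools:

* `markers_pairwise()`: per cluster, Welch t-tests against every other
  cluster (computed from per-cluster summary statistics), per-comparison
  ranks combined by their minimum (a gene ranks high if it separates the
  cluster from at least one other), p-values combined by Simes' method,
  BH-adjusted within cluster. Moderated variance estimation is
  deliberately replaced by plain Welch tests — a documented
  simplification that the null-calibration test shows costs nothing at
  these cluster sizes. The reporting filter is adjusted p < 0.05 and
  |LFC| > 0.5, displayed to dense rank ≤ 20 (ties at the boundary all
  kept, so lists may exceed 20 genes).
* `markers_onevsrest()`: Wilcoxon rank-sum one-vs-rest with the
  conventional pre-filters — expressed in at least 25% of the cluster's
  cells and log2 fold change at least 0.25 — applied before testing, and
  BH adjustment over tested genes only.

LFC is computed on the log2-normalised layer; "expressing" means a
positive normalised value, i.e. a nonzero count at pseudocount 1.

## Orchestration

`run_pipeline()` chains simulate → preprocess → transport → fate →
descendants, validates its YAML/list configuration against a closed
schema (unknown keys are rejected), writes TSV/JSON artifacts with a
manifest of per-stage MD5 checksums, and echoes the full configuration
into the manifest. All randomness flows through explicit seeds; reruns
with the same seeds produce byte-identical outputs. `pipeline_report()`
collates QC pass rates, solver convergence, landscape sizes across the
threshold ladder and descendant counts, flagging missing stages instead
of failing. The package's functions are the interface; the pipeline
entry points are ordinary R calls scriptable from `Rscript`.

## What the synthetic validation does and does not show

Passing tests establish that every algorithmic contract holds: exact
row-stochasticity, agreement of the entropic solver with a brute-force
LP oracle, recovery of injected batch shifts, held-out label-transfer
accuracy on separated states, and recovery of simulated branch ancestry
and fates at the default conditions. The generator's data are idealised:
batch effects are additive and global, expression programs drift
linearly, noise is negative binomial with a single dispersion, and
branches separate cleanly. Real timecourses have nonlinear batch
distortions, cell-type-specific depth, doublets and ambient
contamination (removed upstream of this package), and fate boundaries
that are genuinely gradual — so quantitative accuracies reported here
are upper bounds on what the same pipeline achieves on real data, while
the structural guarantees (row sums, monotonicity, nesting,
determinism) hold identically.

## Known limitations

* Growth learning returns relative, floored rates; absolute growth
  calibration requires external proliferation signatures.
* KNN and MNN are exact brute-force implementations — appropriate up to
  tens of thousands of cells, not millions.
* The per-time-pair local PCA variant of the transport step is
  deliberately not implemented (the corrected global embedding is used,
  matching the skip-dimension-reduction configuration).
* Force-directed layouts, clustering and pseudotime over selected
  landscapes are out of scope; the selection mask and subset dataset are
  the hand-off points to third-party tools.
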