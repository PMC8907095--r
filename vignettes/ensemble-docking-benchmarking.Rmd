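---
title: "Methods: benchmarking ensemble docking with ensdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking ensemble docking with ensdock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Ensemble docking (the Relaxed Complex Scheme) replaces the single rigid
receptor of classical docking with a set of conformations sampled from
molecular dynamics, docks the ligand library against each, and collapses
the per-conformation scores into one prediction per ligand. Whether this
actually improves affinity *rank ordering* depends on choices that are
rarely examined in isolation: which atoms to featurize, how to reduce and
discretize the trajectory, how to aggregate the score ensemble, and how to
judge the resulting Kendall's τ against chance. `ensdock` implements that
benchmark loop so each choice can be exercised on inputs with known ground
truth.

The package deliberately contains no physics. MD engines and docking
engines are upstream; their outputs (a multi-model PDB trajectory, a
ligand × conformation score matrix, an experimental affinity table) are
this package's inputs, and synthetic generators stand in for them when
real data are absent.

## Discretization model

**Features.** A frame is featurized as the flattened positions of a
selection — backbone (N, CA, C, O), C-alpha, or *binding atoms* (receptor
atoms within 2 Å, inclusive, of any supplied docked ligand pose; the union
is taken over poses). Each frame is first Kabsch-superposed onto a
reference frame over the same selection, so rigid-body motion is removed
and the features reflect internal geometry only. The superposition rotation
is constrained proper (determinant +1); fewer than three or collinear fit
atoms raise a geometry error because the optimal rotation is then
underdetermined.

**TICA.** With mean-free features, the instantaneous covariance $C_0$ and
the symmetrized lagged covariance $\bar C_\tau = (C_\tau + C_\tau^T)/2$
are accumulated over the $F-\tau$ lagged pairs (per trajectory, so pairs
never straddle a replica boundary), and the generalized eigenproblem
$\bar C_\tau v = \lambda C_0 v$ is solved after adding a ridge of
$10^{-10}\,\mathrm{tr}(C_0)/d$ to the diagonal of $C_0$. Symmetrization
enforces reversibility at the estimator level and guarantees real
eigenvalues; the ridge guards the whitening step against the near-null
modes that alignment necessarily leaves in position features (six rigid
degrees of freedom). Components are sorted by $\lambda$ descending and the
retained dimension is the smallest $m$ with
$\sum_{i\le m}\lambda_i^2 / \sum_j \lambda_j^2 \ge$ cutoff (default 0.95).
λ² ("kinetic variance") is the standard convention; a plain-λ variant is
available via `variance_kind = "lambda"`.

The lag is specified in *frames*. Upstream trajectory metadata rarely pins
down the saved-frame spacing reliably, so no physical-time default is
inherited; `frame_spacing` metadata is carried on trajectories for callers
who want to convert.

**Kinetic-map scaling in the pipeline.** `project()` returns plain TIC
coordinates, which are $C_0$-normalized: every TIC, slow or noise, has
unit variance. Finite-sample theory puts the spurious eigenvalues of
whitened white noise on a scale of $2\sqrt{d/N}$, so at realistic feature
dimensions the λ² cutoff retains many noise TICs, and k-means distances in
the raw projection are dominated by them (we verified this empirically:
planted-state recovery collapses). The pipeline therefore weights each
retained TIC by $|\lambda_i|$ before k-means — kinetic-map scaling, the
default in the field's reference implementations — which restores recovery
without touching the spec'd projection formula. Users composing stages by
hand should do the same (see the README example).

**VAMP2 feature choice.** Candidate feature sets are compared by a
cross-validated VAMP2 score: per fold, half-weighted covariances from the
training pairs are whitened, the top-k singular functions (including the
constant, which contributes the baseline 1) are fixed, and the score is
recomputed from the held-out block's covariances of those functions. Folds
are *contiguous blocks* of lagged pairs: shuffled frames would leak
temporal correlation between train and test. For a two-state chain with
flip probability $p$ the expected score at $k = 2$ is
$1 + (1-2p)^{2\tau}$; for white noise it is 1. Ties between candidates
break to the lexicographically first label; candidates too short for the
lag/fold structure are skipped with a warning rather than failing the
comparison.

**k-means.** k-means++ seeding from an explicit seed, Lloyd iterations to
a $10^{-6}$ center-shift tolerance, emptied clusters reseeded to the
farthest point. One run per seed by default (a `restarts` argument
exists); clusters are relabelled by decreasing population; the exported
"centroid" is the *medoid frame* — the real trajectory frame closest to
the continuous center in the reduced space, ties to the lowest frame
index. Centroid structures are exported exactly as extracted, with no
geometry cleanup. k defaults to 10; there is no automatic selection rule,
matching common practice of fixing k after inspecting the projection.

**GROMOS.** The greedy neighbor-counting algorithm on a pairwise RMSD
matrix: the unassigned frame with the most unassigned neighbors within the
cutoff (inclusive) seeds each cluster; ties break to the lowest frame
index; singletons are allowed; sizes are non-increasing by construction.
The cutoff is chosen as the first candidate (in the given order) whose
clustering satisfies: largest cluster < 70 % of frames, first 10 clusters
≥ 80 % of frames, and ≥ 20 frames in each of the first 10 clusters. With
fewer than 10 clusters the last two criteria are evaluated over all
existing clusters — the criteria presuppose ≥ 10 and are silent otherwise,
and rejecting a 3-cluster solution with 100 % coverage would be perverse.
If no candidate passes, a classed `selection_failure` error carries the
full per-candidate report. The cutoff is a free parameter in coordinate
units (Å): published per-system values are not hard-coded because reported
cutoffs in the literature are sometimes afflicted by nm/Å unit slips.
Because the algorithm is quadratic in frames, the pipeline subsamples the
trajectory by a stride before GROMOS, mirroring standard practice.

## Scoring and evaluation model

Scores are lower-is-better; pIC50 is higher-is-better. Three aggregation
schemes: minimum, mean of present scores, and the population-weighted mean
$s_l = \sum_i P_i s_{l,i}$ with $P_i = f_i / f_T$ from the cluster
populations. Missing cells (`NA`, never a numeric sentinel) are ignored by
min and mean; the weighted scheme renormalizes $P$ over each ligand's
present entries — the weighted formula assumes a complete matrix and
renormalization is the least-surprising completion. Ligands with no
present score are excluded *and reported* via an attribute, never silently
dropped. These conventions give the dominance invariant
min ≤ weighted mean ≤ max per ligand, which the tests enforce on random
matrices.

Kendall's τ is tie-aware tau-b (ties in real pIC50 data are common, and
standard statistics routines default to tau-b). Predicted and experimental
rankings are both oriented best-first, so a perfect prediction scores
τ = +1. The permutation null draws uniformly random orderings against a
fixed reference (the identity — any fixed reference is equivalent under
uniform permutation) with a seeded generator; its analytic standard
deviation $\sqrt{2(2n+5)/(9n(n-1))}$ is exposed separately and the two are
cross-checked in the tests. The τ grid (3 schemes × methods) mirrors the
benchmark-table layout of ensemble-docking studies; its real-data entries
require an external docking engine and are out of scope by design.

## The synthetic world

`build_toy_protein(n)` lays four backbone atoms per residue along a
regular helical curve and places a small ligand 1.5 Å outside the
"binding loop" (the middle third of residues — a localized binding-site
region, like the mobile loop that frames real protease pockets).

`simulate_markov_trajectory()` realizes a Markov chain over conformational
states (started from its stationary distribution, computed as the leading
left eigenvector, so no burn-in contaminates TICA estimates) and renders
frame $t$ as: base coordinates, plus a state-specific deformation of the
loop atoms, plus isotropic Gaussian noise on every coordinate, optionally
followed by a random rigid rotation and translation. Sub-streams (chain,
noise, jitter) are seeded independently from the one spec seed, so
toggling the rigid jitter does not change the noise realization — which is
what makes the superposition-invariance tests exact.

The deformation deserves a note: state $j$ displaces the loop atoms along
a fixed per-state unit direction with signs *alternating residue by
residue*. A uniform shift of the whole loop would be a rigid translation
of the subset, and Kabsch superposition over that same subset (exactly the
binding-atoms featurization) would absorb it completely, leaving zero
signal — an artifact of the generator, not of the method. The alternating
pattern makes the state change an internal deformation, the synthetic
analog of a side-chain/loop rearrangement rather than a domain shift.

`simulate_score_matrix()` plants $s_{l,i} = a_l + b_i + c_{l,i} +
\varepsilon_{l,i}$: a true per-ligand affinity uniform on the affinity
range, a per-conformation bias, a ligand × conformation compatibility
term, and noise, with a stated fraction of cells missing at random.
`simulate_experimental_affinities()` returns
$\mathrm{pIC50}_l = -a_l \cdot \mathrm{scale} + \mathcal N(0,\sigma^2)$, so
the planted best binder has the highest pIC50. With all nuisance terms
zero, every scheme must reproduce the planted ordering exactly (τ = 1) —
the end-to-end recovery test.

**Default scales.** The benchmark default world is a 10-residue toy
receptor, 3 states, stay-probability 0.9, 6 Å displacement against 0.1 Å
noise, rigid jitter on, and (for the recovery acceptance test) 20,000
frames with a GROMOS stride of 40. 20,000 frames is the desk-scale analog
of production trajectories (hundreds of thousands of saved frames): it
keeps the finite-sample TICA noise scale $2\sqrt{d/N} \approx 0.15$ well
below the slow eigenvalues ≈ 0.85 implied by the chain. These values were
fixed from this reasoning, not tuned against test outcomes.

**What a green test establishes — and what it does not.** The synthetic
trajectory has exactly piecewise-constant states with isotropic
uncorrelated noise; real MD has continuous transitions, anisotropic
correlated fluctuations, and many more degrees of freedom. The synthetic
score matrix is additive Gaussian; real docking scores have heavy tails,
systematic pose failures, and ligand-series correlation. Green tests
therefore establish that the *algorithms* are implemented correctly and
behave as theory predicts on their stated models — not that ensemble
docking will rank any particular real ligand set well.

## Numerical and interface choices

* Coordinates are Å throughout; residue numbers 1-based; atom and frame
  indices 1-based (R convention); cluster ids 0-based labels, 0 = largest.
* The binding-atoms cutoff is inclusive (≤ 2.0 Å) and unions over poses.
* RMSD is plain coordinate RMSD, not mass-weighted.
* PDB I/O is fixed-column; write→read→write is byte-stable after the
  first write; inconsistent atom counts across models and unparseable
  coordinate fields raise format errors naming the model / line.
* Degenerate inputs raise classed errors (`degenerate_input`,
  `geometry_error`, `empty_selection`, `pairing_error`, ...) rather than
  returning NaN.
* All randomness flows through one integer seed per call, with
  deterministic child seeds for sub-streams; two runs with the same config
  and seed are byte-identical, which the pipeline tests assert.
* Conformation ids follow `<method>_<feature>_c<id>` everywhere (files,
  manifests, score columns), so cross-referencing needs no joins on
  position.

## Known limitations

* Linear, feature-space TICA and VAMP only; no kernel variants, no Markov
  state model estimation, no implied-timescale analysis.
* The GROMOS stage materializes the full pairwise RMSD matrix
  (quadratic memory): use the stride for long trajectories.
* The trajectory reader supports multi-model PDB only — no binary
  trajectory formats (DCD/XTC/NetCDF).
* Scoring assumes the score matrix is already reduced to the best pose per
  ligand-conformation pair, as docking engines report; no pose geometry is
  handled anywhere.
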