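# ensdock

Benchmarking toolkit for **ensemble docking** (the Relaxed Complex Scheme):
dock a ligand library against multiple rigid receptor conformations sampled
from molecular dynamics, combine the per-conformation scores into one
prediction per ligand, and ask whether the predicted affinity ranking beats
a random ordering.

The package is aimed at people who want to study the *methodology* — which
trajectory-discretization scheme to use, which score-aggregation rule, how
to judge a Kendall's τ against its permutation null — without needing an MD
engine or a docking engine. Every stage can be driven either by real inputs
(multi-model PDB trajectories, score-matrix CSVs) or by built-in synthetic
generators with planted ground truth.

## What it computes

**Discretization.** A conformational ensemble (frames × atoms × 3, Å) is
featurized as superposition-aligned atom positions for one of three
selections — backbone (N, CA, C, O), C-alpha, or *binding atoms* (all
receptor atoms within 2 Å of docked ligand poses, the "CBA" focus on
binding-site fluctuations). Features are reduced by PCA or TICA. TICA
solves the generalized eigenproblem

    C_tau v = lambda C_0 v

between the instantaneous covariance C₀ and the symmetrized lag-τ
covariance; eigenvalues λ are the autocorrelations of the slowest linear
collective coordinates, and the retained dimension is set by a cumulative
kinetic-variance (λ²) cutoff. The reduced trajectory is clustered by
k-means (k-means++ seeding, medoid frame per cluster exported for docking)
or, on the pairwise-RMSD matrix directly, by GROMOS neighbor counting with
a cutoff chosen by population criteria (largest cluster < 70 % of frames,
top 10 clusters ≥ 80 %, ≥ 20 frames each). Feature sets can be compared by
a 10-fold cross-validated VAMP2 score (sum of squared singular values of
the whitened time-lagged propagator; baseline 1 from the constant
function).

**Scoring.** Given a ligand × conformation docking-score matrix *s*
(lower = better, missing entries allowed) the per-ligand score is

    minimum:          s_l = min_i s_{l,i}
    average:          s_l = mean_i s_{l,i}
    weighted average: s_l = sum_i P_i s_{l,i},   P_i = f_i / f_T

with P the cluster populations. Rankings are compared to experimental
pIC50s with tie-aware Kendall's τ (tau-b), judged against the τ
distribution of uniformly random orderings, whose standard deviation is
also available in closed form, `sqrt(2(2n+5)/(9n(n-1)))` — 0.031 at
n = 459 ligands.

## Worked example

```r
library(ensdock)

# 1. synthesize a metastable ensemble: 3 states, binding-loop deformation
toy  <- build_toy_protein(10)
spec <- trajectory_spec(n_states = 3, n_frames = 2000,
                        state_displacement = 6, noise_sigma = 0.1, seed = 42)
sim  <- simulate_markov_trajectory(toy$structure, spec)

# 2. featurize (aligned backbone positions), reduce with TICA,
#    cluster on kinetic-map-scaled TICs
X   <- featurize_positions(sim$trajectory, select_atoms(sim$trajectory, "backbone"))
tic <- fit_tica(X, lag = 1)
round(tic$eigenvalues[1:3], 3)
#> [1] 0.837 0.829 0.322          # two slow processes = three states
Y   <- project(X, tic)
Y   <- sweep(Y, 2, abs(tic$eigenvalues[seq_len(tic$retained_m)]), "*")
km  <- kmeans_cluster(Y, k = 3, seed = 1)
adjusted_rand_index(km$labels, sim$state_labels)
#> [1] 1                          # planted states recovered exactly

# 3. synthetic docking scores for the centroids, evaluated against
#    synthetic experimental affinities
sc  <- simulate_score_matrix(score_spec(n_ligands = 50, n_conformations = 3,
                                        noise_sigma = 0.8, seed = 7))
aff <- simulate_experimental_affinities(sc$true_affinity, noise_sigma = 0.3, seed = 8)
grid <- evaluate_grid(list(tica = sc$scores),
                      list(tica = cluster_populations(km)), aff)
round(grid, 3)
#>          tica
#> Minimum 0.767
#> W. Avg. 0.763
#> Avg.    0.767

# 4. how surprising is that tau under random ligand ordering?
tau_null_distribution(50, n_samples = 10000, seed = 1,
                      observed = grid["Minimum", "tica"])
#> <ens_null_distribution> n = 50 items, 10000 samples: mean = 0.0002, std = 0.0987
#>   observed tau = 0.7665 (percentile 1.0000, z = 7.77)
analytic_tau_sigma(50)
#> [1] 0.0976
```

The τ ≈ 0.77 of the noisy synthetic scores sits ~7.8 null standard
deviations above random — with planted ground truth the pipeline behaves
as designed; with noise-free scores every scheme returns τ = 1.

## Full pipeline and CLI

`run_pipeline(pipeline_config(...))` executes the whole benchmark — six
method × feature combinations (TICA/PCA on backbone, GROMOS on C-alpha,
all three on binding atoms), centroid extraction with manifests,
pairwise-RMSD and RMSF diagnostics, the 3-scheme × 6-method τ grid, the
permutation null, and a checksummed run manifest — reproducibly from one
seed. The same thing from the shell:

```sh
Rscript inst/cli/ensdock.R all --config config.json --out run_dir --seed 3
```

where `config.json` holds `pipeline_config()` arguments.

## Limitations

No docking engine, force field, or MD integrator is included or emulated:
score matrices are inputs (or synthetic), and the trajectory generator is
a Markov chain over geometric states, not dynamics. See the methods
vignette (`vignettes/ensemble-docking-benchmarking.Rmd`) for the model,
parameter choices, and what the synthetic world does and does not
establish.
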