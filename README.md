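# msmhdx

Kinetic characterization of a protein monomer's structural ensemble from
molecular-dynamics trajectories, and estimation of per-residue
hydrogen–deuterium exchange (HDX) protection factors from the resulting
cluster decomposition.

The package is aimed at simulators who have many unbiased trajectories of a
small protein (the motivating system is the insulin monomer at low pH, with
chains A and B) and want to answer two questions:

1. **What metastable conformations does the protein visit, how populated are
   they, and how fast do they exchange?**
2. **What does that ensemble predict for amide-site protection factors
   measured by hydrogen-exchange experiments?**

## The analysis chain

Every stage is an exported function operating on plain, documented
containers:

| Stage | Function(s) | Method |
|---|---|---|
| Featurization | `pairwise_ca_distances()` | pairwise Cα distances of a residue selection (d = n(n−1)/2 features, nm) |
| Slow modes | `fit_ivac()`, `project_tics()`, `spectral_gap()`, `select_seeds()` | integrated VAC: sums symmetrized time-lagged correlation matrices over a lag range and solves C_int v = λ C(0) v; robust to the single-lag choice |
| Microstates | `kmeans_cluster()` | seeded k-means++ plus Lloyd iterations in tIC space |
| Markov state model | `estimate_msm()`, `implied_timescales()`, `ck_test()`, `frame_weights()` | sliding-window transition counts at a lag, symmetrized (detailed-balance) estimator, largest strongly connected set; t_i = −τ/ln λ_{i+1}; Chapman–Kolmogorov validation; per-frame equilibrium weights π_s/n_s |
| Metastable clusters | `pcca()`, `macro_populations()`, `macro_fluxes()` | Perron cluster analysis (robust simplex-vertex memberships) on the leading MSM eigenvectors; clusters labeled 0..m−1 by decreasing population; equilibrium fluxes F_AB = Σ π_i T_ij |
| Hydrogen bonds | `count_hbonds()`, `hbond_criteria()` | per frame and per backbone amide site, bonds to protein acceptors (HB_p) and to water oxygens (HB_w) under a distance cutoff (N···acceptor) and a hydrogen–donor–acceptor angle cutoff; cell-list search identical to brute force |
| Protection factors | `pf_structure()`, `pf_cluster()`, `pf_ensemble()`, `compare_experimental()`, `variable_sites()` | four per-structure models (below); cluster means PF_ij over 4000 weighted sample structures; ensemble PF_i as the population-weighted average over the top clusters; Pearson comparison against experimental tables |
| Exchange kinetics | `exchange_kinetics()`, `ex2_observed_rate()`, `pf_from_rates()` | two-state opening model, PF = k_cl/k_op, EX2 limit k_obs = k_int/PF |
| Disorder annotation | `classify_elements()`, `element_percentages()`, `helix_content()`, `backbone_dihedral()`, `plane_side()` | configurable geometric rules (helix i→i+4 bonds, inter-segment distances, reference-plane crossings, β-turn hydrogen-bond swaps), aggregated as physically weighted percentages per cluster |
| Synthetic ground truth | `toy_chain_spec()`, `generate_ensemble()`, `stationary_distribution()` | hidden discrete-state Markov chain emitting per-state geometry templates plus Gaussian noise; populations, timescales and per-site hydrogen-bond patterns known a priori |

### Protection-factor models

With `NH_i = min(HB_i^p, 1) − min(HB_i^w, 1)` per structure:

* **Park**: `f_i = b^{NH_i}` with base parameter `b` (default 500);
* **Ratio**: `f_i = HB_i^p / max(HB_i^w, 1)` (the max guard keeps it finite
  when a structure has no water bonds);
* **Difference**: `f_i = HB_i^p − HB_i^w`;
* **Bound-Difference**: `f_i = NH_i`, which can only take the values 1, 0, −1.

All four are non-decreasing in HB_p and non-increasing in HB_w; the suite
asserts this over the exhaustive count grid.

## Worked example

A synthetic three-state ensemble with populations (0.5, 0.3, 0.2), designed
per-site hydrogen-bond patterns, and 4 × 20 000 frames:

```r
library(msmhdx)
P <- ...  # reversible 3-state matrix with stationary (0.5, 0.3, 0.2)
hb_p <- rbind(c(2,1,0,0,1,0), c(2,0,0,0,0,0), c(2,1,0,0,0,0))
hb_w <- rbind(c(0,0,1,2,0,1), c(0,1,2,2,1,1), c(0,0,2,2,1,1))
spec <- toy_chain_spec(P, n_res = 6, hb_p = hb_p, hb_w = hb_w)
g <- generate_ensemble(spec, n_traj = 4, n_frames = 20000, seed = 1)

fm    <- pairwise_ca_distances(g$ensemble, data.frame(chain = "A", resno = 1:6))
model <- fit_ivac(fm, lag_min = 1, lag_max = 20)
Y     <- project_tics(model, fm, spectral_gap(model$eigenvalues))
mic   <- kmeans_cluster(Y, k = 30, seed = 2)
msm   <- estimate_msm(mic, lag = 5)
cl    <- pcca(msm, 3)

counts <- count_hbonds(g$ensemble, hbond_criteria(0.5, 70))
pt <- pf_cluster(counts, frame_macro_labels(cl, mic), frame_weights(msm, mic),
                 pf_model_spec("park", b = 500), n_sample = 4000, seed = 3)
pf_ensemble(pt, macro_populations(cl), included_clusters = 0:2)
```

Output (abridged):

```
tic_model: lags 1 - 20, 15 components, 80000 frames
leading integrated eigenvalues: 16.34, 16.2, 0.1178, 0.06739, 0.04905
spectral gap after 2 tICs
slowest implied timescales (frames): 52.4 49.2
true timescales (frames):            54.0 49.5
macro_clustering: 3 clusters over 30 microstates
populations: 0.518, 0.301, 0.181
    A1     A2     A3     A4     A5     A6
500.00 349.53   0.00   0.00 258.84   0.00
```

Reading this: the integrated spectrum shows exactly two slow modes (three
hidden states), the MSM timescales match the generator's analytic values
within a few percent, the recovered cluster populations match (0.5, 0.3, 0.2)
within sampling error, and the ensemble Park protection factors separate the
designed sites — A1 is protein-bonded in every state (PF 500), A2 and A5 are
protected only in a subset of clusters (intermediate PF), and the
water-exposed sites A3, A4, A6 are essentially unprotected (PF ≈ 1/500).

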