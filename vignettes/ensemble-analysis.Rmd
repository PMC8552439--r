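---
title: "Ensemble kinetics and hydrogen-exchange protection factors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble kinetics and hydrogen-exchange protection factors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmhdx)
```

This vignette is the package's account of its methods: the models and
estimators, the parameters that matter with their defaults and units, the
numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## The problem

A long molecular-dynamics dataset of a small protein — the motivating case is
a two-chain insulin monomer — samples many conformations. The analysis
questions are kinetic and thermodynamic: which metastable states exist, with
what equilibrium populations, and on what timescales do they exchange?  And,
once the ensemble is decomposed into clusters, what does it predict for
per-residue amide hydrogen-exchange protection factors, which experiments
measure site by site?

The package implements the full chain from raw coordinates to those answers,
and ships a synthetic trajectory generator with exactly known ground truth so
that every stage is testable without any external dataset.

## Featurization

`pairwise_ca_distances()` computes the pairwise distances between the
alpha-carbons of a residue selection, in nanometres; for `n` residues that is
`n(n-1)/2` features per frame, ordered lexicographically by (chain, residue
number) pair.  Distances are invariant to rigid motion, which the test suite
asserts directly, so no trajectory alignment is required.  A small,
well-spread selection (the motivating study used 9 residues, 36 distances)
keeps the dimensionality low while covering all large-scale rearrangements.

No periodic-boundary minimum-image correction is applied: the intended input
is a single solvated monomer in a box much larger than the protein.  Readers
(`read_ensemble()`) accept a PDB topology plus CSV (nm), DCD or multi-model
PDB coordinates (Angstrom, converted); XTC has no R reader available, so CSV
is the lossless interchange format (`write_ensemble()` round-trips through
it).

## Slow modes by integrated VAC

Plain VAC/tICA solves a generalized eigenproblem between a time-lagged and an
instantaneous covariance matrix at a single lag, and its output can be
sensitive to that lag.  `fit_ivac()` instead sums the lagged covariance over
a lag range,

$$C_{\mathrm{int}} \;=\; \sum_{\tau=\tau_{\min}}^{\tau_{\max}}
\tfrac12\left(C(\tau) + C(\tau)^{\mathsf T}\right),
\qquad C_{\mathrm{int}}\,v \;=\; \lambda\, C(0)\, v ,$$

with the data mean-centered and time-lagged pairs never straddling a
trajectory boundary.  Numerical choices:

* **Symmetrization of each `C(τ)`.**  Finite samples of an equilibrium
  process give slightly asymmetric estimates; symmetrizing enforces a real
  spectrum, the standard practice for variational conformational analysis.
* **Lag units are frames** throughout the package; conversion to physical
  time is the caller's one multiplication by `frame_interval` (ps).  This
  avoids silent unit mistakes.
* **Lag schedule.**  Whether the sum runs over every integer lag or a sparser
  schedule is an open estimator choice; the `stride` argument (default 1,
  i.e. every lag) exposes it.
* **Regularization.**  If `C(0)` has condition number above `1e12`, a ridge
  `eps I` with `eps = 1e-10 * trace(C(0))/d` is added.  On well-conditioned
  data this changes nothing at machine precision; genuinely collinear
  features still produce an instructive error.
* **Eigenvector normalization** is `v' C(0) v = 1`.  A consequence worth
  knowing: comparisons between models must use the `C(0)` metric.
  `subspace_angles()` computes principal angles between leading tIC
  subspaces in that metric; in the Euclidean metric the same subspaces can
  appear degrees apart simply because feature variances differ by orders of
  magnitude.

`spectral_gap()` picks the component count as the largest consecutive drop in
the integrated spectrum (first occurrence on ties). `select_seeds()` supports
the adaptive-sampling loop (`expand_sampling()`): it returns the lowest
kernel-density frames in the first three tIC dimensions, at least one
bandwidth apart, ties broken by frame index.  The original workflow selected
poorly sampled structures by hand; a deterministic automated stand-in was
required here, and a Gaussian kernel with a Scott-rule default bandwidth is
the least surprising choice.  For very large datasets the density is
evaluated against a seeded random subsample (`max_eval`, default 20 000
reference points), which is the only use the function makes of its `seed`.

## Microstates, Markov model, validation

`kmeans_cluster()` runs Lloyd iterations (via `stats::kmeans`) from a seeded
k-means++ initialization, then re-assigns every frame to its nearest final
center so the stated invariant holds exactly.  The conventional default of
1000 microstates suits datasets of millions of frames; the examples and tests
use proportionally fewer.

`estimate_msm()` counts sliding-window transitions at one lag within each
trajectory (every frame a window start; counting statistics are maximized and
the estimator choice is exposed, since either convention is defensible).  The
default `symmetrized` mode row-normalizes `(C + C')/2`:

* it guarantees detailed balance, hence a real spectrum — which the
  metastable coarse-graining assumes;
* its stationary distribution is available in closed form (row sums of the
  symmetrized counts), so `pi T = pi` holds to machine precision.

A `naive` mode (row-normalized raw counts) is provided for comparison.  The
model is restricted to the largest strongly connected set of the count graph
(largest by frame count, found with igraph); dropped microstates are recorded
and their frames get zero weight in `frame_weights()`, with a logged count —
standard ergodic trimming.

`implied_timescales()` reports `-lag / ln(lambda)` in frame units; eigenvalues
at or above one give `Inf`, non-positive ones have no defined timescale and
are reported `NA` rather than silently skipped.

`ck_test()` validates Markovity by comparing set-to-set transition
probabilities of the propagated model `T(τ)^k` against a model re-estimated
at lag `kτ`; both sides are computed from the same estimator, so factor 1 is
exactly zero by construction.  Standard errors use effective counts
`n / (kτ)` rather than the raw sliding-window pair count: overlapping windows
are serially correlated, and the naive count would understate the error by
roughly the window overlap factor, making the test reject valid models.

`frame_weights()` turns the MSM into per-frame equilibrium weights
`pi_s / n_s`; weighted statistics (cluster populations, disorder
percentages, protection-factor sampling) are then equilibrium expectations
even when the raw trajectories oversample some states.

## Metastable clusters, populations, fluxes

`pcca()` implements Perron cluster analysis in its robust simplex-vertex
form: rows of the leading right-eigenvector matrix lie approximately in an
(m−1)-simplex whose vertices are the metastable sets; vertices are located by
successive orthogonal farthest-point search, and fuzzy memberships are the
barycentric coordinates, clipped at zero and row-renormalized.  No subsequent
objective optimization is performed: the variant implemented degenerates to
exact indicator memberships on uncoupled chains, which is the regime every
test and the synthetic ground truth exercise.  Crisp labels are argmax
memberships.

Clusters are relabeled `0..m-1` by decreasing stationary population (ties by
ascending original label, for determinism).  `macro_fluxes()` reports the
equilibrium probability mass exchanged per lag step,
`F_AB = sum_{i in A, j in B} pi_i T_ij`, from crisp labels — matching the
cluster-network description the method is used for; whether a flux should be
quoted per lag step or per unit time is a units question left to the caller,
who can divide by `lag * frame_interval`.  The edge list carries each flux as
a fraction of the maximum and a highlight flag for edges at or above 25% of
the maximum.

## Hydrogen bonds

`count_hbonds()` counts, per frame and per backbone amide site, hydrogen
bonds donated to protein acceptors (`HB_p`) and to water oxygens (`HB_w`).
A bond requires `distance(N, acceptor) <= distance_cutoff` and
`angle <= angle_cutoff`, both inclusive so behaviour at a cutoff is
deterministic.  Conventions:

* **Angle vertex at the donor nitrogen** (between N→H and N→acceptor) by
  default.  Published criteria with loose cutoffs up to 90° are only
  meaningful under this convention; the hydrogen-vertex alternative
  (deviation from N–H···A linearity) is available as a configuration option.
* **Acceptor set**: all protein O and N atoms except the donor's own
  backbone N and its hydrogen.  Same-residue side-chain acceptors are
  included by default — deliberately, because the known artifact of tight
  distance plus loose angle criteria (a site's own side-chain oxygen counted
  while a well-placed water is missed) is something users should be able to
  reproduce and then switch off (`include_self_residue = FALSE`).
* **Search**: cell lists with cell edge equal to the distance cutoff, with
  the contract (enforced by test against an independent brute-force oracle
  over the full 4×4 grid of published cutoffs) that output is identical to
  the all-pairs search.

Counts are monotone under loosening of either cutoff and invariant under
rigid motion; both are asserted as properties.

## Protection factors

Per structure and site, four models map `(HB_p, HB_w)` to a protection score
`f_i`, all encoding "more protein bonds, fewer water bonds ⇒ more protected".
With `NH_i = min(HB_p, 1) − min(HB_w, 1)`:

| model | `f_i` | notes |
|---|---|---|
| `park` | `b^NH` | `b > 0`, default 500; the historical range is 1e4–1e6, and the default keeps maxima near the largest experimentally reported values |
| `ratio` | `HB_p / max(HB_w, 1)` | max guard keeps it finite at `HB_w = 0` |
| `difference` | `HB_p − HB_w` | |
| `bound_difference` | `NH` | takes only the values 1, 0, −1 |

All four are non-decreasing in `HB_p` and non-increasing in `HB_w`
(asserted by exhaustive enumeration over `{0..10}^2`).

`pf_cluster()` averages `f_i` over `n_sample` structures per cluster
(default 4000), drawn with probability proportional to the frames'
equilibrium weights — weighted sampling is the default because cluster means
should be equilibrium expectations; uniform sampling is available by passing
uniform weights.  Clusters smaller than `n_sample` are sampled with
replacement (logged), which keeps the estimator defined on small synthetic
clusters.  `pf_ensemble()` renormalizes the populations of the included
clusters (default: the five most populated) and returns the weighted average;
the identity `PF_i = sum_j w_j PF_ij` holds to 1e-10 and is asserted.

`variable_sites()` offers both published senses of "variable across
clusters": variance at least 10× the mean, and coefficient of variation at
least 10%.  Neither is privileged; zero-mean sites are skipped (with a
message) under the variance-ratio rule rather than producing a 0/0.

`compare_experimental()` matches sites by exact chain+residue label — no
fuzzy matching, since a silently wrong alignment is worse than an error —
and reports Pearson's R with per-site residuals and the unmatched labels.

The exchange-kinetics utilities implement the classical two-state opening
model: closed ⇌ open with rates `k_op`, `k_cl`, followed by intrinsic
exchange `k_int` from the open state; `PF = k_cl / k_op`, and in the EX2
limit (`k_cl ≫ k_int`; flag threshold `k_cl/k_int ≥ 100`, configurable) the
observed rate is `k_obs = k_int / PF`.  Outside the regime the function still
computes the EX2 value but attaches and raises a warning.

## Disorder annotation

The collective variables that define "elements of disorder" (helix melting,
chain-terminus detachment, reference-plane crossing, β-turn hydrogen-bond
swaps, dihedral flips) are data, not code: `classify_elements()` evaluates a
list of typed rules, and `default_disorder_rules()` ships an editable
insulin-flavoured default set.  The defaults are documented stand-ins — the
thresholds (e.g. detachment at 1.0 nm minimum heavy-atom distance, melting at
helical fraction < 0.5) are plain list entries meant to be replaced by a
user with system-specific definitions.  Partial and total N-terminus
detachment use disjoint distance bands, so the two flags are mutually
exclusive by construction.

Geometry kernels: dihedrals follow the IUPAC sign convention in (−180, 180]
(validated against an independent reference torsion implementation);
`helix_content()` calls residue `i` helical when its carbonyl O accepts a
bond from the N–H of `i+4` under configurable criteria (default 0.35 nm,
40°), with the fraction taken over the testable residues of the range
(those with an `i+4` partner inside it), so breaking one bond lowers the
value by exactly one over that count; `plane_side()` fixes its sign per frame
by a recorded reference atom, so the convention is stable across a run.
A hydrogen-bond-based helix criterion was chosen over a DSSP port because it
reuses the package's one geometry kernel; a dihedral-window rule type is
available as an alternative.

`element_percentages()` aggregates flags as physically weighted percentages
per cluster (weights from `frame_weights()`), bands them green (≥ 80%),
orange (20–80%) and white (< 20%), and can report the total weight fraction
carrying at least one of a named set of headline elements.

## The synthetic generator

`toy_chain_spec()` + `generate_ensemble()` emulate the one thing the analysis
needs from data: a hidden discrete-state Markov process observed through
noisy geometry.

* Frames are emitted as the hidden state's coordinate template plus iid
  Gaussian noise (default sigma 0.01 nm, small against the 0.28–0.31 nm
  hydrogen-bond design margins, so designed bond patterns survive the noise).
* Trajectories start from the stationary distribution, so empirical
  occupancies are unbiased; an explicit `initial` distribution supports
  reducible (e.g. absorbing) chains.
* One topology is shared by all states; disorder lives purely in coordinates,
  as in real trajectories.  Water oxygens are template pseudo-atoms — there
  is no solvent dynamics, because hydrogen-bond counting only needs acceptor
  geometry relative to the amide sites.
* Per state and site, 0–2 protein acceptors and 0–2 water oxygens are placed
  at ideal bonding geometry or far away, making the expected `(HB_p, HB_w)`
  pattern exact (the suite verifies exactness under both the tightest and
  loosest published criteria).
* States displace the chain's C-terminal half along state-specific directions
  with state-specific magnitudes, including an axial component on alternating
  states: the displacement then enters inter-residue distances both linearly
  and quadratically, so the state centroids genuinely span `n_states − 1`
  feature-space dimensions.  (A purely transverse rigid shift would collapse
  all centroids onto a one-dimensional `|shift|` coordinate and make the
  second slow mode unidentifiable — a real pitfall found while designing the
  generator.)

What the generator does **not** emulate: continuous within-state dynamics
(noise is white, so within-state relaxation is instantaneous), force-field
energetics, solvent structure, and realistic protein geometry.  Consequently,
passing tests demonstrate the correctness of the estimators and bookkeeping
— populations, timescales, fluxes, weights, hydrogen-bond counting and the
protection-factor pipeline — on data whose generating process satisfies the
methods' assumptions exactly.  They do not demonstrate that any particular
MD dataset satisfies those assumptions; for real data the Chapman–Kolmogorov
test and the lag-range/discretization robustness checks are the relevant
diagnostics, and both are part of the API.

## Problem sizes used in the checks

The statistical end-to-end check runs the full chain on ten trajectories of
50 000 frames each (a three-state chain with populations 0.5/0.3/0.2 and a
slowest relaxation near 54 frames), 50 microstates, and asks for macro
populations within 2 percentage points and the slowest implied timescale
within 15% — comfortable bounds at this sampling (the observed errors are a
few tenths of a point and a few percent).  Unit-level checks use
1 000–30 000 frames.  These sizes were chosen so the whole suite documents
the estimators' behaviour at desk scale; the estimators themselves are
vectorized and handle millions of frames.

## Known limitations

* The MSM estimator is the symmetrized-count one: simple, deterministic and
  detailed-balanced, but it biases transition probabilities when the data are
  far from equilibrium sampling; maximum-likelihood reversible estimators
  with uncertainty quantification are out of scope.
* PCCA memberships come from the simplex-vertex construction without a
  subsequent optimization pass; on strongly overlapping metastable sets the
  fuzzy memberships are cruder than a full PCCA+ refinement (crisp labels,
  which all downstream quantities use, are much less sensitive).
* Hydrogen-bond counting has no periodic-image handling and no energetic
  criterion; it is a geometric counter by design.
* Intrinsic exchange rates `k_int` are inputs, never predicted from sequence;
  EX1-regime modelling and fitting of the base parameter `b` to data are
  non-goals.
* The annotation defaults are stand-ins; quantitative use on a real system
  requires system-specific collective-variable definitions supplied as rules.
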