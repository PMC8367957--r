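---
title: "Methods: Markov state model analysis of heterogeneous ice nucleation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov state model analysis of heterogeneous ice nucleation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icekinetics)
```

# The problem

Water freezing on a foreign surface — heterogeneous ice nucleation — can
proceed classically (direct formation of a hexagonal-ice nucleus over a
single free-energy barrier) or non-classically (through an intermediate
disordered mixture of surface-stabilized rhombic ice and hexagonal ice,
over two barriers). Telling these pathways apart, quantifying how the
nucleation flux divides between them, and locating the critical nucleus
requires a statistical model of the kinetics rather than inspection of
individual trajectories. This package implements that analysis chain:
molecule-level ice classification, collective-variable (CV) construction
and selection, Markov state model (MSM) estimation and validation,
metastable coarse-graining, and transition path theory (TPT).

# Ice classification

Each water molecule `i` (oxygens only; all rules are oxygen-geometric,
hydrogens are carried through I/O but ignored by the classifier) gets the
averaged Steinhardt bond-order parameters

$$\bar q_l(i) = \left( \frac{4\pi}{2l+1} \sum_{m=-l}^{l}
  \Big| \frac{1}{N_i + 1} \sum_{j \in \{i\}\cup \mathrm{nbrs}(i)}
  q_{lm}(j) \Big|^2 \right)^{1/2},
\qquad
q_{lm}(j) = \frac{1}{N_j} \sum_{k \in \mathrm{nbrs}(j)}
  Y_{lm}(\mathbf r_j - \mathbf r_k),$$

for $l = 4, 6$, where neighbor lists use minimum-image distances in the
orthorhombic box and exact distance ties go to the lower molecule index
(determinism on ideal lattices). The outer average over the molecule and
its neighbors is what makes $\bar q_l$ sharp enough to separate ice
polymorphs from liquid.

Rules and defaults (`DetectionParams`):

* bulk molecules, $N = 4$: hexagonal ice iff $\bar q_6 > 0.45$, never
  rhombic (rhombic ice is a surface motif);
* interface molecules (within `interfaceZCutoff` = 0.35 nm — about one
  hydrogen-bond length — above the topmost surface-atom layer), $N = 3$:
  rhombic iff $\bar q_4 > 0.6$, otherwise hexagonal iff $\bar q_6 > 0.5$
  and $\bar q_4 < 0.6$. When a molecule satisfies both the rhombic and the
  hexagonal condition, rhombic wins: the rhombic condition is stated
  unconditionally on $\bar q_4$, and on ideal planar nets both conditions
  do fire simultaneously.
* Each molecule uses its own rule-dependent neighbor count inside
  $q_{lm}$, including when it appears as a neighbor of a molecule under
  the other rule.

The largest ice nucleus is the biggest connected component of ice-labeled
molecules with O–O edges at `clusterCutoff` = 0.35 nm (the first minimum
of the O–O pair correlation of simulated water); layers are
`floor((z - z_surface) / layerSpacing)` with `layerSpacing` = c/2 =
0.368 nm, half the hexagonal-ice c axis, so one layer is one molecular
bilayer. Both cutoffs are configurable.

Numerics: spherical harmonics are built from the associated Legendre
functions of pracma (Condon–Shortley convention); the test suite checks
the full $\bar q_l$ pipeline against an independently coded
direct-summation oracle using closed-form $Y_{4m}$/$Y_{6m}$ polynomial
tables, to $10^{-12}$, and checks rotational invariance to $10^{-10}$.
A zero-length separation vector (overlapping molecules) is a hard error,
not a silent skip.

# Collective variables

The CV pool (18 members, `cvPoolNames`) counts hexagonal and rhombic
molecules in the largest nucleus resolved by layer, whole-frame totals,
and geometric descriptors of the nucleus (xy extent, height, and a
gyration-tensor sphericity, defined as the smallest-to-largest eigenvalue
ratio — 1 for a sphere, 0 for a plane). The selected subset
(`cvSelectedNames`) is: total ice in the largest nucleus, rhombic ice in
the largest nucleus, and hexagonal ice in the 2nd, 3rd and upper layers
of the nucleus ("2nd layer" is 1-based, i.e. layer index 1). The exact
composition of the 13 non-selected candidates and the original spherical
parameter are not fully specified in the source material; the pool here
is a documented reconstruction, and the analysis rests only on the five
selected CVs, which are fully specified.

Selection uses a greedy spectral-oASIS criterion: for a candidate column
set $S$, the time-lagged covariance $C_\tau$ is Nyström-reconstructed as
$\hat C_\tau = C_{:,S} C_{S,S}^{+} C_{S,:}$, and the selection error is
the summed deviation of the top-$m$ generalized eigenvalues of
$(\hat C_\tau, C_0)$ from the full-pool values. Columns are added one at
a time (ties to the lower index). Because the CVs are mean-free, the
constant eigenfunction is projected out and the slowest dynamical mode is
the *top* generalized eigenvalue. $C_0$ is regularized by
$10^{-10}\,\mathrm{tr}(C_0)/K$ on the diagonal before the generalized
solve; eigenvalues are clipped to $(0, 1)$ before taking logarithms and
non-positive eigenvalues yield timescale 0 with a warning. Observation
noise attenuates lag-1 correlations, biasing timescales low; the bias
decays with lag, so timescale readouts should use a modest lag (the tests
use lag 20 on noisy emissions).

# Markov state model

* **Discretization**: greedy k-centers on standardized CVs (zero mean,
  unit variance — the counts live on different scales), carrying the
  classical 2-approximation covering-radius guarantee. The first center
  is a seeded random frame; seeds are explicit arguments everywhere and
  no global RNG state leaks (`withSeed` saves and restores
  `.Random.seed`). k-centers is deliberately outlier-seeking; with very
  few states on noisy data it can split on noise directions, which is
  one reason the state count is chosen by cross-validation, not by hand.
* **Counting**: sliding-window pairs $(t, t+\tau)$, never across
  trajectory boundaries; strided counting is available.
* **Trimming**: estimation is restricted to the largest strongly
  connected component of the count graph (igraph), dropped states are
  reported in the model's `active` map.
* **Estimation**: non-reversible = row normalization. Reversible
  (default) = maximum likelihood under detailed balance via the
  self-consistent symmetric-edge-weight fixed point, converged when the
  stationary vector moves by less than $10^{-10}$ (cap $10^6$ sweeps,
  non-convergence is an error). Detailed balance holds exactly at every
  iterate by construction.
* **Validation**: implied timescales $t_i(\tau) = -\tau/\ln\lambda_i(\tau)$
  (non-positive eigenvalues reported as undefined, never negative);
  Chapman–Kolmogorov comparison of $T(\tau)^k$ residence probabilities
  against re-estimation at lag $k\tau$, with bootstrap bands over
  trajectories (a single trajectory is split into 10 segments first);
  GMRQ cross-validation — the sum of generalized Rayleigh quotients of
  train-set eigenvectors on test-set indicator correlation matrices —
  for the state-count choice. On scarce data the training score
  overshoots the variational bound $\sum_i \lambda_i$ while the
  cross-validated score does not, which is the overfitting signal.

For study-scale data the defaults mirror the published protocol
(1000 microstates chosen by GMRQ, 8 macro-states); the package-level test
and acceptance runs use 64 microstates on the synthetic network, a size
chosen so the full pipeline runs in seconds while leaving ~8 microstates
per generative basin.

# PCCA+ and coarse graining

Macro-states come from PCCA+ on the top-$n$ right eigenvectors of the
reversible transition matrix ($\pi$-orthonormalized via the symmetrized
$\mathrm{diag}(\sqrt\pi)\,T\,\mathrm{diag}(1/\sqrt\pi)$): the
inner-simplex vertex search picks $n$ spread-maximizing microstates, the
linear transform mapping their eigenvector rows to unit vectors defines
fuzzy memberships, and negative entries are clipped and rows renormalized
(feasibility projection). This deterministic construction was chosen over
iterative rotation optimization for reproducibility; crisp assignments
are the row argmax with ties to the lower macro index. Non-reversible
input is refused, degenerate eigenvalues at the cut warn and fall back to
index order. Coarse transition matrices use
$T^{\mathrm{macro}}_{AB} = \sum_{i\in A}\sum_{j\in B}\pi_i T_{ij} / \pi_A$
with crisp assignments (fuzzy aggregation is not used downstream). For
cross-temperature comparisons the discretization and lumping learned on
the reference ensemble are reused unchanged on the other ensembles
(`assignToCenters`).

# Transition path theory

Committors solve the discrete boundary-value problem by a direct linear
solve (exact and deterministic at these sizes; the backward committor
comes from the time-reversed chain, and $q^- = 1 - q^+$ is verified for
reversible chains). Reactive flux
$f_{ij} = \pi_i q^-_i T_{ij} q^+_j$, net flux $\max(0, f_{ij} - f_{ji})$,
total flux $\sum_{i \in A, j \notin A} f_{ij}$. Pathways come from
iterative max-bottleneck (widest-path) removal — the standard TPT
decomposition; the stop threshold `minFraction` is a reporting filter
(e.g. 0.05 reproduces a "pathways above 5%" display), with full
decomposition conserving the total flux to $10^{-10}$. Transition states
are microstates with $q^+$ in a window defaulting to $[0.45, 0.55]$; the
two competing critical nuclei are obtained from two independent TPT runs
(source = early basin; sink = the rhombic-rich intermediate for the
non-classical barrier, or the hexagonal critical basin for the classical
one). MFPTs solve $m = \tau + T m$ on non-target states; the nucleation
rate is $J = 1/(\mathrm{MFPT}\cdot V)$, normalized by volume (a
surface-area normalization is a documented alternative the user can apply
by substituting $V$).

# The synthetic generator

`buildTwoPathwayNetwork()` encodes the qualitative topology of the
studied system as ground truth: liquid (I) → early nucleus (II), then a
classical branch II→IV and a non-classical branch II→III→{IV, V}, both
draining via growth (VI) into grown states (VII, VIII). Edge weights are
symmetric, so the chain is exactly reversible with uniform
self-probability `metastability` (default 0.98, giving a slowest implied
timescale of ~200 steps — slow enough to be metastable, fast enough that
10⁵–10⁶-step trajectories contain many reactive events). The branch
weight at II is tuned by bisection until TPT on the exact matrix puts the
requested fraction (default 0.5, the "comparable fluxes" regime) of the
I→{VII,VIII} flux through the classical edge, within 0.01. Emission means
trace a plausible nucleation progression in the five selected CVs
(nucleus growth from ~5 to ~630 molecules, transient rhombic enrichment
in III, layer-by-layer hexagonal growth); the default emission standard
deviation of 8 molecules keeps adjacent states separable (nearest mean
pairs are ≳4 SD apart) without being trivially clusterable.

`buildLattice()` provides the detector's ground truth: the wurtzite
oxygen sublattice of hexagonal ice (a = 0.4519 nm, c = 0.7357 nm, every
interior molecule 4-coordinated at ~0.276 nm), a planar square-like
rhombic monolayer with 4 intralayer neighbors at 0.276 nm, and a
hard-sphere-rejection liquid at 33 molecules/nm³ with a 0.2 nm exclusion.
The default positional noise for robustness tests is 0.01 nm, well below
the classification boundaries.

What the generator does *not* emulate: real hydrogen-bond topology and
proton disorder, thermal vibration spectra, diffusive CV dynamics within
basins (emissions are i.i.d. given the hidden state), surface-strain
effects, and any temperature dependence. Passing the recovery tests
therefore demonstrates correctness of the estimators on data satisfying
their assumptions — not that a particular MD system is Markovian in these
CVs; that judgement always rests on the implied-timescale and
Chapman–Kolmogorov diagnostics applied to the real data.

# Degenerate inputs and tie-breaks

Parsers reject malformed blocks rather than skipping them; triclinic
boxes are rejected (the study box is orthorhombic). Neighbor ties break
to the lower index; k-centers ties resolve by `which.max`'s first
maximum; PCCA+ crisp ties go to the lower macro index; cluster-size ties
go to the component with the smallest member index. Empty ice sets give
empty nuclei (not errors); committor systems with absorbing intermediates
raise a diagnostic naming the states; `nHex = 0` makes disorderliness an
error rather than an infinity.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data: 10⁶-step chains for parameter recovery, 10 × 10⁵-step emitted
trajectories with 64 microstates for the end-to-end flux-split recovery,
50-molecule frames for oracle comparisons, and ~100–400-molecule lattices
for the detector. These sizes give sampling errors comfortably inside the
stated tolerances (e.g. the flux split is recovered within ~2 percentage
points against a 5-point criterion) while a full run of the suite plus
the acceptance script completes in a few minutes.

# Known limitations

* Orthorhombic periodic boxes only; no triclinic support.
* The committor, MFPT and PCCA+ solvers use dense linear algebra —
  appropriate up to a few thousand microstates, not for 10⁵-state models.
* Bayesian/posterior MSM uncertainty is out of scope; uncertainties come
  from bootstrap resampling where offered (CK test, TS ensemble stats).
* Potential energies of transition-state ensembles are consumed from a
  user-supplied table; no force field is evaluated.
* The rhombic monolayer generator is planar; real rhombic ice is slightly
  buckled. The detector thresholds are insensitive to this at the noise
  levels tested.
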