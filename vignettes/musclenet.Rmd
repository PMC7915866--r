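---
title: "Muscle functional networks and EMG sensor selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle functional networks and EMG sensor selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclenet)
```

## The problem

A lower-limb prosthesis is driven by surface electromyography (EMG)
recorded from the residual limb. Where to place the electrodes is not
obvious: the residual musculature differs from anatomical expectation, and
dense grids (here 33 channels, `V1`–`V33`, covering the front, back and
outer side of the limb) are impractical inside a socket. `musclenet`
implements a network-based selection strategy: treat every electrode as a
node, measure pairwise statistical dependence between channels, analyse
the resulting *muscle functional network* across movement conditions, rank
muscles by structural importance, infer directed muscle-to-muscle
information flow, and finally pick a small sensor set that sits at the
sources of that flow while covering all limb surfaces.

The movement protocol emulated throughout is a repeated leg swing —
lift (1.5 s), hold (1 s), lower (1.5 s), ten repetitions — recorded at
2000 Hz under three conditions: an appropriate swing angle, an excessive
angle (forward traction) and a too-small angle (backward resistance).

## Pipeline stages

### Preprocessing

Channels are band-pass filtered (Butterworth, default order 4, 20–450 Hz,
zero-phase forward–backward application) and mean-centred. Zero-phase
filtering is used because later stages compare lagged envelopes across
channels, and a phase-shifting filter would bias those lags. Centring is
applied both before and after filtering; removing the DC component first
prevents it from ringing through the filter's edge transients. Analysis
windows are the per-repetition lift phases: interaction between socket and
stump concentrates in the lift.

### The weighted network

Dependence between channels `S` and `Q` is histogram mutual information

$$MI(S,Q) = H(S) + H(Q) - H(S,Q), \qquad
  H(S) = -\sum_i p_i \log_2 p_i,$$

estimated on `B = 16` equal-width bins per channel over each segment's
observed range. `MI` is zero exactly when the binned channels are
independent. Per-segment matrices are averaged over the ten repetitions.
Two normalizations are offered: the default divides by
$\sqrt{H(S)\,H(Q)}$, which is intrinsically bounded in $[0,1]$ and
comparable across recordings; min–max rescaling of the averaged raw MI is
available by configuration. The bin count trades bias (too many bins)
against resolution (too few); 16 bins on 3000-sample windows keeps the
independent-channel bias of the *normalized* score well below 0.1, which
the test suite verifies on the generator's independence null.

### Binarization

An edge is drawn when the normalized weight strictly exceeds a threshold
`TH`. `select_threshold()` scans a grid (step 0.01) and keeps thresholds
whose network is connected — a single component, hence no isolated nodes —
and has average degree $\langle k \rangle > 2 \ln n$ (≈ 6.99 for
n = 33). Among feasible values the *largest* is chosen: the sparsest
network that still satisfies both principles. The full diagnostic trace
(average degree and isolated-node count per threshold) is returned, and an
infeasible weight matrix raises an error carrying that trace. When several
conditions are analysed together the pipeline takes the minimum of the
per-condition selections, so one common threshold is feasible everywhere
(thresholding is monotone, so lowering the threshold preserves
connectivity).

### Topology and importance

`network_summary()` provides degrees $k_i$, the degree distribution
$P(k) = n_k/n$, per-node clustering $C_i = 2E_i/(k_i(k_i-1))$ (zero when
$k_i < 2$, where the formula is undefined), the network clustering
coefficient (the mean of $C_i$), and the average shortest-path length
$L = \sum_{i \ne j} d_{ij} / (n(n-1))$ by breadth-first search.
`area_degree_profile()` averages degrees within six electrode areas (two
per surface); the default 33-channel map assigns `V1`–`V12` to the front,
`V13`–`V23` to the back and `V24`–`V33` to the side, with each surface
split in two along the limb. Which half is nearer the wound is not an
anatomical claim and the map is fully user-overridable.

Node importance uses the *node-contraction* criterion. The cohesion of a
connected network is $\partial(M) = 1/(nL)$; contracting node $i$ merges
it with its entire neighbourhood into one supernode, and

$$IMC(i) = 1 - \frac{\partial(M)}{\partial(M \times i)}$$

measures the relative cohesion gain. A node whose contraction collapses
the network to a single node gets the maximal score ($\partial := 1$ for a
single node, the natural limit of the definition and the only consistent
choice where the formula's denominator is otherwise undefined). Key nodes
are those with `IMC > 0.5`; with several movement conditions the selection
is the union of per-condition selections, since a muscle important in any
condition must remain instrumented. Ties are reported as equal.

### Directed network and sensor selection

Directedness comes from convergent cross-mapping (CCM). Series are delay
embedded, $x(t) = \langle x[t], x[t-\tau], \ldots, x[t-(E-1)\tau]\rangle$,
and the skill of estimating $x$ from the manifold of $y$ (Pearson $r$
between simplex-projection estimates and the observed values) is evidence
that the information of $x$ is contained in $y$, i.e. that $x$ drives $y$.
Estimates use the $E+1$ nearest library neighbours with exponential
weights $w_i \propto \exp(-d_i/d_1)$; a printed uniform-weight variant is
available (`weights = "as_printed"`) because the ratio form of the
published weighting is degenerate — its exponent is identically $-1$ —
and the exponential form is the standard simplex weighting it plainly
intends. Neighbour searches exclude a Theiler window of $(E-1)\tau$
samples around the target so temporal adjacency cannot masquerade as
dynamical proximity. Skill is evaluated over an ascending grid of library
sizes with seeded random draws; the same draws serve both directions, so
draw-composition noise largely cancels in the skill difference the rules
act on. Convergence (skill rising with library size, summarized by a
Spearman trend per direction) is the CCM signature of genuine coupling.

With converged skills `Mx` (x from the y-manifold) and `My`, and
`D = Mx − My`, the four-rule table is applied exactly as stated:
`D > 0.3` gives one-way causality x→y; `D < 0.1` gives none;
`0.1 < D < 0.3` gives none when `Mx > 0.5` and x→y when `Mx < 0.5`; the
mirrored test decides y→x. Boundary conventions: `D = 0.1` falls to rule
2, `D = 0.3` to rules 3/4, `Mx = 0.5` to rule 3. Rules 3 and 4 reward
*lower* absolute skill inside the intermediate band, which is
counterintuitive but faithful to the stated table; the docs flag it.

Per-condition directed networks are synthesized by union; an edge whose
reverse also appears (in any condition) is flagged bidirectional. Nodes
are then ranked by a declared key — longest directed path from any source
ending at the node (sources first), then out-degree minus in-degree, then
label order, with strongly connected components condensed and their
members sharing rank — and the top `m` (default 5) are selected, minimally
adjusted so every limb surface with at least one candidate is represented.
The rank key formalizes "information sources first"; the original
narrative ranking procedure is not stated algorithmically, so this
package's key is its own declared choice.

### Movement comparison

For the induced key-node subnetworks the three features — clustering
coefficient, average degree, average path length — are tabulated per
condition, standardized to zero mean and unit variance, and clustered by
average-linkage agglomeration on Euclidean distances. Partitions, not
dendrogram heights, are the contract: the published rescaled-distance axis
is an SPSS display convention with no analytical content. On the published
mean feature values of the three movement conditions this procedure
separates the unrestrained movement from the two restrained ones at the
two-cluster cut, which the test suite verifies by direct computation.

## The synthetic-data generator

No recordings are deposited with the motivating study, so `musclenet`
ships a generator whose outputs carry known ground truth.

Each channel is a band-limited stochastic carrier (white Gaussian noise
band-passed to 20–450 Hz) multiplied by the deterministic per-repetition
activation envelope (ramp up over the lift, plateau over the hold, ramp
down over the lower; resting floor 0.1 so no sample is exactly silent).
Dependence is planted at two levels: a global common-drive source shared
by all channels and one latent source per channel group, mixed with
weights `global_strength` and `group_strength` (scalar or per channel).
Every latent source and noise stream additionally carries a slow
amplitude modulation (unit-variance spline noise, default knot frequency
2 Hz, depth 0.35): real EMG amplitude drifts on the 0.3–1 s timescale
(common drive), and without it activation envelopes would be
unpredictable over the lags that envelope-level cross-mapping probes.

Directed couplings are planted at the modulator level: the driver
channel's activation is modulated by a free-running chaotic logistic map
(r = 3.8) stepped every `lag` seconds, and each target's by a logistic map
(r = 3.72) receiving the driver map's lagged quadratic influence
($m_T \leftarrow m_T(r_t - r_t m_T - \beta m_D)$). A literal memoryless
envelope transfer was rejected during design: without recurrent dynamics
in the response, cross-map skill is symmetric and no method can orient the
edge. The map-level construction keeps the planted influence lagged and
quadratic while giving the response the internal state that convergent
cross-mapping requires; `depth` raises the modulation contrast of the
coupled channels (power-law, smooth and invertible). The truth record
echoes groups, directed edges and the exact modulator series.

What the generator does *not* emulate: motor-unit physiology, electrode
lift-off or motion artifacts, fatigue, inter-subject variability.
Passing tests therefore demonstrate correctness of the computational
chain and recoverability of planted structure, not clinical validity on
human recordings.

## Numerical choices and problem sizes

* Histogram entropy treats $0\log 0 = 0$; constant channels have zero
  entropy and normalized MI is defined as 0 when a marginal entropy
  vanishes.
* Envelopes for cross-mapping are rectified low-pass (default 10 Hz,
  order 4, zero-phase) envelopes of the *continuous* filtered recording,
  decimated and windowed afterwards — filtering short windows separately
  would corrupt a large fraction of every 1.5-s segment with edge
  transients. Before cross-mapping, the protocol-locked mean activation
  profile across repetitions is removed by ratio (`env/profile − 1`):
  every channel shares the deterministic movement ramp, and leaving it in
  (or removing it by subtraction, which leaves a ramp-weighted
  heteroscedastic residual) produces spurious symmetric predictability.
* The embedding delay defaults to the first minimum of the
  autocorrelation, capped; embedding dimension defaults to 3. Both are
  stated nowhere in the source material and are exposed as parameters.
* Exact zero distances on a manifold put all weight on the tied exact
  matches.
* The validation suite runs the full pipeline on 33 channels × 10
  repetitions × 3 conditions (the emulated protocol), cross-mapping on
  1000-sample logistic benchmarks with 20 seeds, and exhaustive
  brute-force comparison of every graph metric on all 27 475 connected
  graphs with up to six nodes.

## Known limitations

The canonical-system validation shows the CCM chain is correct: on
unidirectionally coupled logistic maps the classifier recovers the true
direction in at least 90% of seeded runs and essentially never the
reverse. Recording-level direction calling is much harder. The skill of
recovering a driver through the rectified-envelope observation chain is
limited by carrier-induced envelope estimation noise (the amplitude of a
band-limited stochastic carrier can only be estimated to ~20% at a 10 Hz
envelope bandwidth), and on a 15 s analysis record the sampling noise of
a converged skill estimate is of order 0.1 — the same order as the rule
table's weak-evidence band. Consequently rule 4, which calls causality on
a moderate skill difference at low absolute skill, fires on an
appreciable fraction of unrelated channel pairs, and the synthesized
directed network over many key nodes is noise-dominated at these data
sizes; the planted driver's out-edges are recovered only intermittently.
The package implements the stated rules exactly and reports skills,
trends and rules per edge so users can apply stricter evidence standards;
for reliable directed inference substantially longer records (or fewer,
pre-selected node pairs with surrogate-based significance testing, which
is out of scope here) are required.

The importance threshold of 0.5 is sharply density-dependent: in sparse
networks no node reaches it, in dense networks most do. The threshold
selection rule (largest feasible) together with the connectivity
constraint tends to produce dense networks on homogeneous synthetic data,
so key-node sets are correspondingly large; on real recordings with
stronger degree heterogeneity the cut is more selective.
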