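---
title: "Topology-only simulation of signal transduction: model and design notes"
author: "signalsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-only simulation of signal transduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalsim)
```

## The problem

Kinetic models of signal transduction need rate constants and
concentrations that are rarely available for whole pathways. signalsim
takes the nonparametric route: the only inputs are a signed directed
graph — nodes are signaling components, an edge `i -> j` with sign +1
(activation) or -1 (inhibition) is a direction of information flow —
and a handful of dimensionless simulation settings. The state of node
j at step t, X_j(t) in [0, 1], is read as the proportion of its
molecules in the active (e.g. phosphorylated) form, comparable to a
normalized bead-based micro-ELISA readout.

## Edge weighting: the Normalized Similarity Index

Signal transmission efficiency along an edge is estimated from shared
neighbourhood structure. For an edge (i, j), with neighbourhoods taken
ignoring direction and sign and excluding i and j themselves:

* M — matching connections, |N(i) ∩ N(j)|;
* D — distinct neighbours, |N(i) ∪ N(j)|;
* C — number of directed edges between i and j (1 or 2);

$$\mathrm{NSI}_{ij} = \frac{M + C}{D + C} \in (0, 1].$$

Endpoints that share four neighbours, have eight distinct neighbours
in total and one connecting edge (the [nsiMotif()] fixture) give
5/9 ≈ 0.556. Highly interconnected modules therefore transmit signal
efficiently; edges bridging unrelated neighbourhoods attenuate it.

Design choices made here, where the definition leaves room:

* Neighbourhoods are direction- and sign-blind: signs encode
  regulation, not connectivity, and the worked motif counts common
  nodes without reference to direction.
* C counts both directions of a reciprocal pair, so mutual regulation
  raises efficiency: (M + 2)/(D + 2) > (M + 1)/(D + 1).
* Self-loops get weight 1 (neutral) and are excluded from M and D;
  autoregulation is accepted by the parser but should not distort the
  similarity of its neighbours.

## Dynamics: semi-synchronized stochastic update

`simulateNetwork()` first restricts the graph to the subnetwork
reachable from the configured source nodes (unreachable nodes cannot
receive signal and are ignored), assigns each node its BFS layer
(shortest directed distance from any source), then runs T sweeps. In
each sweep, nodes are updated in ascending layer order with ties
broken lexicographically, and node j combines:

* `act` = 1 − Π over activators i of (1 − w_ij · x_i) — independent
  binding: each activator independently contributes its weighted
  activity, combined as a probabilistic OR;
* `rep` = Π over repressors i of (1 − w_ij · x_i);
* `retained` = R · X_j(t−1), where R is the relative stability of the
  active form, drawn fresh per node per step;
* X_j(t) = clamp to [0,1] of `retained + (1 − retained) · act · rep + ξ`.

A node with no activators purely decays (`act` = 0). The clamp — not
the parameters — guarantees boundedness for any topology and noise
level, which the test suite exercises over randomized configurations.

**Semi-synchrony.** A regulator contributes its *fresh* step-t value
if it was already updated in the current sweep (upstream layer, or
same layer but earlier in the fixed order), and its step t−1 value
otherwise. On a feed-forward cascade a signal therefore traverses the
whole chain within one sweep, while feedback edges act with a
one-step delay — the intended middle ground between fully synchronous
updating (every reaction takes exactly one tick) and event-level
asynchrony. A fully synchronous mode (`schedule = "synchronous"`) is
kept for comparison and testing only; on an n-deep chain its
trajectories are exactly the semi-synchronous ones shifted by layer
depth, which the suite asserts.

**Source driving.** A source node with user activity a is driven by
the linear ramp a · t / (divisor · T). The default divisor 10 caps
receptor engagement at a/10, reflecting that only about a tenth of a
receptor pool is typically in the high-affinity, ligand-bound form; T
(default 100) controls only the ramp resolution.

**Stability and half-life.** R encodes how much of the active pool
survives one step. It is drawn uniformly per node per step: U(0, 1)
by default, U(0, 0.5) for short-half-life nodes, U(0.5, 1) for
long-half-life ones. Because protein half-life is predicted from
topology (hubs with total degree ≥ 6, ligand/receptor sources with
in-degree 0 and sink outputs with out-degree 0 cannot be assigned a
single class confidently), such *ambiguous* nodes are simulated in
both a short and a long variant when `halfLifeMode = "both"`; both
variants consume identical random draws, so they differ only through
the stability ranges. Per-node overrides pin a class when the user
knows it.

**Noise.** ξ is i.i.d. uniform on [−ε, +ε] (ε default 0.01), applied
after the deterministic part and before clamping — zero-mean, least
structured, uncorrelated with the time span.

**Randomness layout.** Each sweep draws one stability quantile and
one noise term per *original* reachable node, in lexicographic node
order, whether or not the node uses them (sources ignore theirs);
complementary inhibitor nodes never draw. This makes paired-run
guarantees structural rather than statistical: a null inhibition
(complementary activity 0) or a removed perturbation reproduces the
unperturbed run byte for byte under the same seed.
`fixedStability` replaces every R draw by a constant for
deterministic schedule tracing; draws are still consumed so
deterministic and stochastic runs stay aligned.

## Perturbations

Deleting an inhibited node would sever all downstream signal flow,
which inhibitor experiments contradict: some signal still passes
through an inhibited kinase. Inhibition is therefore modeled by a
complementary node `anti_<target>` clamped at a constant activity
(default 1, a saturating small-molecule inhibitor; lower values model
partial inhibition) with a single −1 edge of weight 1 onto the
target. The complementary node is added *after* NSI weighting — the
weights describe the biology, not the intervention — and receives no
source ramp ("constant inhibitory messages"). Gain-of-function
mutations are fixed assignments: the node is clamped at its constant
for every step t ≥ 1, dominating dynamics, noise and the ramp; the
clamp holds during the sweep as well, so same-sweep readers never see
a transient value (this is what makes a clamped mid-chain node fully
decouple its downstream subtree from the stimulus, which the suite
checks by paired runs).

When an inhibited molecule is itself a measured readout its
measurement is unusable, so `maskInhibitedReadouts()` replaces that
row of the *reported* trajectory with the user's report value (often
0) without touching the internal dynamics.

## Validation statistics

`correlateExperiment()` inner-joins a simulation summary with an
experimental table on (condition, node) and reports Pearson r with
the two-sided p from the t transform (n − 2 df). The per-run summary
is the mean of X over iterations 1..T — consistent with pairing
per-iteration values in the Wilcoxon comparison — with a `last-k`
alternative for users who prefer a steady-state window.

`wilcoxonSignedRank()` follows the convention used for
perturbation-response tables: drop zero differences, midranks on
ties, W = the smaller of the positive/negative rank sums, and

$$Z = \frac{W - n'(n'+1)/4}{\sqrt{n'(n'+1)(2n'+1)/24}}$$

reported with its non-positive sign, two-sided p from the normal
approximation with *no continuity correction* — with 100 paired
iterations all moved in the same direction this saturates at
Z = −8.68. Trend calls at α = 0.01: `up` if significant and the
perturbed mean is higher, `down` if lower, `none` otherwise (equal
means make no call). One published five-molecule table prints one row
with Z = −3.14 next to P = 0.016, which is inconsistent with the
normal approximation (2Φ(−3.14) ≈ 0.0017); this package always
computes p from Z and documents the discrepancy rather than
reproducing it.

No multiple-testing correction is applied, matching the tables this
reproduces.

## Synthetic fixtures

The generators in this package are first-class, seeded, and are the
single source of truth for the test suite:

* `nsiMotif()` — the 10-node NSI demonstration motif (NSI = 5/9).
* `cascade(n)` — linear chains with optional inhibitory positions.
* `randomSignedNetwork()` — ligand-rooted sparse digraphs; defaults
  (40 nodes, 7 in-degree-0 ligands, density 0.06, 15% inhibitory
  edges) emulate the shape of a curated hepatocyte
  inflammatory/growth network with seven receptor inputs. Reachability
  from the ligand set is enforced by adding chain edges where sampling
  left a node stranded.
* `syntheticExperimentTable()` — a trajectory summary plus clamped
  Gaussian measurement noise, emulating a normalized micro-ELISA
  panel.

What these fixtures do **not** capture: the specific topology of
curated pathway maps (hand-transcribing published figures is
error-prone, so the random generator emulates shape only, and
`readNetwork()` accepts the real curated files when the user supplies
them), correlated measurement error, and receptor-level kinetics.
Green property tests therefore certify the algorithmic contracts —
boundedness, reachability handling, schedule semantics, paired-run
reproducibility, statistical conventions — not agreement with any
particular biological dataset.

## Numerical and scale choices

* All activity arithmetic is plain double precision; the only
  nonlinearity is the final clamp.
* Ties in the update order are broken by C-locale lexicographic node
  id, making runs locale- and insertion-order-independent.
* Degenerate inputs fail loudly: zero-variance Pearson input,
  all-zero Wilcoxon differences, conflicting duplicate edges, and
  invalid configs (every violation listed in one error).
* Problem sizes used by the shipped tests and the acceptance script —
  networks of 6–82 nodes, T = 5–100, up to a few hundred randomized
  boundedness cases, 30-seed stimulus–response averages — were chosen
  as the smallest sizes at which the asserted properties are not
  statistical accidents; each completes in seconds on a laptop.
* The exact-enumeration check of the signed-rank p compares the
  normal approximation against the exact mid-p for n ≤ 12 away from
  the extreme tails (exact p > 0.05), where the uncorrected
  approximation is within 10%; in the far tails it is crude by
  construction, which is also why saturated table rows print bounds
  like "< 10^-18" rather than exact values.

## Known limitations

* The update rule is a reconstruction constrained by the published
  verbal description (independent binding, retained active fraction,
  additive bounded noise, order independence); other formulas
  satisfying the same constraints exist.
* Activity magnitudes depend on the divisor cap and the stability
  ranges; cross-run *comparisons* (trends, correlations over
  conditions) are the meaningful outputs, not absolute levels.
* BFS layering uses directed out-edges from the sources; feedback
  into a source does not change its layer.
* Single-cell stochasticity is emulated by one noise term per node
  and step, not by molecule-level birth–death processes.
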