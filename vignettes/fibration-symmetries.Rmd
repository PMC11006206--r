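---
title: "Fibration symmetries, building blocks and cluster synchronization: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibration symmetries, building blocks and cluster synchronization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibersync)
```

This vignette records the models, conventions and design choices behind
`fibersync` — the things a maintainer or a careful user needs that the
function reference does not spell out.

## Graphs, input trees and fibers

Networks are integer-weighted directed multigraphs; an undirected
(gap-junction) edge is stored as two opposed directed edges of equal
multiplicity. The input tree of a node is the layered tree of all walks
terminating there: layer 0 is the root, layer $i+1$ expands every entry by
its in-neighbors with multiplicity, and the layer sizes $a_i$ count walks of
length $i$ into the root. Two nodes belong to the same **fiber** exactly
when their input trees are isomorphic; depth $n-1$ suffices to separate all
non-isomorphic trees on an $n$-node graph.

Input-tree isomorphism is decided by canonical colors built bottom-up, not
by explicit bijection search: all nodes start with one color, and each round
recolors by the sorted multiset of in-edge colors (repeated by
multiplicity). Colors after $k$ rounds classify depth-$k$ trees; the fixed
point is the **minimal balanced coloring**. The same refinement run on the
multiplicity-clamped matrix gives the binary-mode coloring; on networks
whose weights are constant per ordered fiber pair (the weighted construction
used throughout), the two agree. Equitability of an arbitrary partition is
checked directly from its definition, returning a witness node pair on
failure, and the quotient (base) graph is only defined — and only
constructed — for balanced partitions. The base of an undirected network is
directed in general, because cells of unequal size collapse asymmetrically.

**Automorphisms** are found by an in-house backtracking search over
candidate images, pruned by a joint refinement on in- *and* out-multisets
(an automorphism must preserve both). Orbits are computed by searching, for
each candidate pair in the same pruning class, for one witness automorphism
mapping the first node onto the second, and closing all witness images under
union–find; the returned `automorphism_set` is that witness collection plus
the identity — a generating set for the orbit structure, not the whole group
(which is exponentially large on symmetric fixtures). The search is capped
at 64 nodes, the intended working scale; pairwise search keeps every orbit
decision exact.

## Fiber building blocks and fiber numbers

Each fiber's **circuit** is its backward-reachable cone in the base; its
**building block** is the subgraph induced by the fiber, its immediate
in-neighbors (regulators), the shortest non-self loop through a fiber node,
and — when those rules leave weak components — the shortest directed paths
bridging them (composite blocks). Ties in the loop and bridge rules include
all shortest witnesses, which makes the construction order-independent.

Fiber numbers $|n, \ell\rangle$ are defined on the block's *base
representation* (the block collapsed under the host partition, minimally
refined where the restriction stops being balanced on the subgraph):

* $n$, the branching ratio, is the limit of $a_{i+1}/a_i$. Raw consecutive
  ratios oscillate, so $n$ is computed as the spectral radius of the
  in-adjacency restricted to the nodes that reach the root, and
  cross-validated against the empirical layer growth. The empirical
  estimator uses the square root of the two-step ratio (damping odd/even
  oscillation) with Richardson extrapolation $2r(d) - r(d/2)$, because trees
  whose dominant eigenvalue is defective grow polynomially times
  geometrically and their plain ratio converges only like $1/d$. Default
  depth 120, tolerance $10^{-3}$; disagreement beyond that raises a
  diagnostic error rather than returning a number.
* $\ell$ counts edge-simple trails terminating at the root, enumerated
  exhaustively on the multiplicity-clamped base **with the root's out-edges
  removed**. The removal is a deliberate convention: the worked enumeration
  for the three-node nested-loop block lists six trails and none pass
  through the root's out-edges, even though the root has them; keeping them
  would inflate the count past the six-trail worked enumeration. It is
  capped (default 24 edges) because trail counting is exponential.

Classification: $n = 0$ is `finite`, integer $n \ge 1$ (relative tolerance
$10^{-6}$) is `n-loop`, anything else is `Fibonacci` (nested loops of
several lengths); blocks assembled through the bridge rule are `composite`.
Multilayer signatures lay the circuit's fibers out by backward BFS distance
from the main fiber, each fiber once at its shallowest layer, rendered with
`⊕` between layers and `+` within one; fibers whose elementary block is
trivial ($|0,0\rangle$ pure sources) appear only as regulators inside other
blocks. Fibonacci blocks collapse onto two-node bases by quotienting under
their own coloring; the collapse asserts that the dominant eigenvalue is
preserved.

## Admissible dynamics

Three admissible models couple through the in-edges of their network, with
$f(V) = -\alpha^{\mathrm{leak}}(V - V_{\mathrm{rest}})$:

* gap junction: $\dot V_i = f(V_i) - \alpha^{\mathrm{gap}} \sum_j \tilde
  A_{ji} (V_i - V_j) + \alpha^{\mathrm{ext}} I_i$;
* Chem I: coupling $\Phi(V_j)(V_i - V_{s,j})$ with the sigmoid
  $\Phi(V) = 1/(1 + e^{-\gamma (V - V^{\mathrm{thr}})})$;
* Chem II: coupling $s_j (V_i - V_{s,j})$ with
  $\dot s_i = a_r \Phi(V_i)(1 - s_i) - a_d s_i$.

Parameters (mV, s, pA): $\alpha^{\mathrm{leak}} = 10$,
$\alpha^{\mathrm{gap}} = \alpha^{\mathrm{chem}} = 100\,\mathrm{s}^{-1}$,
$V_{\mathrm{rest}} = -37$ mV, $a_r = 1$, $a_d = 5\,\mathrm{s}^{-1}$, all
synapses excitatory ($V_s = 0$ mV; $-70$ mV available per presynaptic
neuron), $\gamma = 0.125\,\mathrm{mV}^{-1}$ (125 V$^{-1}$;
`gamma_from_range()` gives the 0.1-to-0.9-over-36-mV value
$2\ln 9/36 \approx 0.122$). $s_{\mathrm{eq}} = a_r/(a_r + 2 a_d) = 1/11$
is the synaptic equilibrium with the sigmoid at $\tfrac12$. The package's
unit convention absorbs the 1 pF capacitance into
$\alpha^{\mathrm{ext}} = 1$ so that 1 pA drives 1 mV/s; this keeps the
stimulus scales (tenths of pA) commensurate with the millivolt kernel
scales used by the synchrony metrics, which is the regime the whole
analysis operates in.

The **threshold voltage** solves the linear steady state obtained by
freezing $\Phi \equiv \tfrac12$ and $s \equiv s_{\mathrm{eq}}$, with the
constant part of the drive on the right-hand side (oscillation and noise
average to zero). The same state is the equilibrium for stability analysis,
and because $\Phi$ is anchored at $V^{\mathrm{thr}}$, plugging the solution
back into the full right-hand side gives a zero residual identically — an
invariant the tests assert to $10^{-10}$.

**Integration** is fixed-step classical RK4 at $dt = 0.1$ ms, compiled
(Rcpp). The smooth stimulus (constant + sinusoids) is evaluated at the RK
stage times, so deterministic runs converge at order 4 (asserted by a
step-halving test). The noise part is a Gaussian random walk with
unit-variance increments, min–max rescaled into $\pm$ its nominal bound over
the run, advanced once per step and held within it — the $\sqrt{dt}$
diffusion scaling of a stochastic RK scheme; the internal stage treatment of
the noise is an implementation choice, documented here, since only the
per-step update scale is contractually fixed. One noise path is drawn per
targeted fiber (sharing preserves the input symmetry; a partial-fiber target
warns). Runs are bit-reproducible per seed, and non-finite states abort with
the offending step.

## Stability

Jacobians at the threshold equilibrium: the gap model gives
$-\alpha^{\mathrm{leak}} I - \alpha^{\mathrm{gap}} L$ (in-Laplacian,
drive-independent, negative spectrum at the default rates); Chem I has
$\Phi = \tfrac12$, $\Phi' = \gamma/4$ diagonals and sigmoid-derivative
off-diagonals; Chem II is the $2n \times 2n$ block matrix over $(V, s)$
whose only drive dependence sits in $\partial \dot V/\partial s$. The
off-diagonal sign follows from differentiating the coupling term (the
derivative of $-\alpha^{\mathrm{chem}}\tilde A_{ji}\Phi(V_j)(V_i - V_{s,j})$
with respect to $V_j$), and every block is unit-tested against central
finite differences of the right-hand side at relative tolerance $10^{-6}$ —
including the Chem II $\partial \dot s$ blocks, which are derived here
rather than quoted. Instability sweeps scan the drive on a grid per sign,
record the leading eigenvalue real part (positive means $> 10^{-9}$), and
bisection-refine the first crossing to 0.01 pA.

On the synthetic fixtures at the default parameters no chemical model
crosses within 0–500 pA — the planted networks are more stable than
repaired biological circuits, whose thresholds depend on the real wiring
and are out of scope here. The crossing machinery is therefore validated on a steep-sigmoid
($\gamma = 1.25\,\mathrm{mV}^{-1}$) mutually excitatory pair whose
antisymmetric mode destabilizes at a closed-form drive: the sweep finds it
to 0.02 pA, simulations 10% below keep the pair synchronous and 10% above
split it, and the mirrored eigenvalue pair coalesces between the crossings
where the equilibrium voltage passes zero.

## Synchrony metrics

$\mathrm{LoS}_{ij}$ is the time-averaged Gaussian kernel of the voltage
difference over the trailing window (default: final 1 s of a 5 s run,
first sample included); $\sigma = 0.1$ mV is the operating point, and the
calibration rule walks a decreasing grid from 10 mV until the mean
cross-fiber LoS falls below $10^{-3}$. The difference score binarizes the
observed matrix at $1 - \varepsilon$ with $\varepsilon = 0.005$ — "round
entries below 1 to 0" is ill-posed in floating point, so the cut is explicit
and configurable — subtracts it from the ideal block matrix of the
partition, and divides the off-diagonal sum by $2(n^2 - n)$: zero is perfect
fiber agreement, negative flags extra cross-fiber synchrony (permitted by
the theory), positive flags missing within-fiber synchrony. PLV uses the
analytic-signal instantaneous phase of each mean-removed trace (one-sided
FFT construction, implemented in the package since no installed dependency
provides it); the phase-extraction method is a package decision, not a
constraint inherited from the metric's definition.

## Synthetic study networks

The real locomotion sub-circuits (manually repaired connectome data) are not
distributable, so the generator plants the structure the analysis assumes
and the fixtures are labelled `*_like` stand-ins, not reconstructions:
directed chemical networks of 22 nodes/4 fibers and 30/10, undirected gap
networks of 20/6 and 29/6, each with left–right interneuron pairs as their
own size-2 fibers that drive the rest — mirroring the finding that such
pairs always form their own balanced color. Base matrices were designed once
with mutually distinct in-color multisets, which makes the base's own
coloring trivial and hence guarantees (input trees lift through fibrations)
that the lift's minimal coloring equals the planted partition; every draw is
still certified before being returned.

Directed lifts sample, for every node of cell $i$ and every in-cell $j$,
$B_{ji}$ distinct tails uniformly from cell $j$. Undirected lifts are
aligned circulants: cells are indexed by $\mathbb{Z}_{s}$ and edges are
unions of orbits of the simultaneous rotation $x \mapsto x + 1$ in every
cell (random orbit offsets, random per-cell relabelling). That rotation is
then itself an automorphism acting transitively inside every cell, so the
undirected draws have orbit partition equal to fiber partition *by
construction* — the property the study's gap networks exhibit — and the
generator audits it anyway. Degree feasibility of a base matrix for this
construction is validated up front. Weight perturbation subtracts seeded
$N(0, \mathrm{std}^2)$ draws from every nonzero weight (once per undirected
edge, mirrored), preserving the support; symmetry analysis always runs on
the unperturbed integer network.

What the generator does *not* emulate: broken or near symmetries needing
repair, inhibitory classes, rectifying gap junctions, anatomical positions,
and the specific wiring of the worm's circuits. Passing tests therefore show
the machinery is correct on networks with exact planted symmetry, not that
any particular biological network has these fibers.

## Simulation experiments and problem sizes

Test 1 runs the chemical models stimulus-free from initial voltages
$N(-35\,\mathrm{mV}, \mathrm{sd})$ over a grid of sd values (the resting-state
default $-37$ mV and the $-35$ mV initial-condition convention are
independent knobs; the drivers use $-35$). Fibers always synchronize;
distinct fibers may merge, which is reported, not failed. Test 2 sweeps the
instability threshold for the interneuron-pair drive, then drives at 90% of
it with a 5% sinusoid (2 Hz interneurons; gap networks add a 1 Hz
motor-fiber channel, without which they synchronize globally). When no
crossing exists in range — the gap model by construction, the synthetic chem
fixtures at default parameters — a 200 pA fallback drive is used: large
enough that the two-frequency forced responses separate fibers at the
0.1 mV kernel scale, chosen once as the gap operating point. Test 3 applies
the stated 0.61 pA-max drive (0.1 constant + 0.5 sinusoid + 0.01 noise; the
builder asserts the nominal maximum) to ten seeded weight-perturbed copies
per std in 0–0.1, averages the LoS, and compares within the binarized
unperturbed blocks; the difference grows with std while within-fiber PLV
stays above cross-fiber PLV.

The analysis drivers use the full 5 s / 0.1 ms / 10-replicate protocol. The
test suite exercises the same code on 2–3 s spans with 0.2 ms steps and 3
replicates — the asserted properties (flow invariance, block structure,
score signs, curve monotonicity) are grid-independent, and the 5 s
invariance runs are kept where the claim is specifically about a 5 s span.

## Known limitations

* Trail enumeration and automorphism search are exponential in the worst
  case; both carry explicit caps with clear errors rather than silent
  truncation.
* `automorphisms()` returns orbit-generating witnesses, not the full group
  or its normal-subgroup structure.
* The branching-ratio cross-check can reject graphs whose dominant
  eigenvalues are complex conjugates of equal modulus (genuinely oscillating
  layer growth); the spectral value alone would be misleading there, so the
  error is intentional.
* Real connectome idiosyncrasies (near-symmetries, inhibition, rectifying
  junctions) are out of scope; apply the partitioners to real data with the
  same caution the repaired-network studies applied.
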