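---
title: "Coarse-graining methods in cgforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-graining methods in cgforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgforge)
```

cgforge derives effective pair potentials between coarse-grained (CG)
beads from a reference particle ensemble.  This vignette is the package's
account of the two optimization methods it implements, the sampling and
analysis machinery underneath them, the numerical choices made where the
methods leave latitude, and what the built-in synthetic reference systems
do and do not demonstrate.

## The coarse-graining problem

A fine-grained (reference) system is mapped onto beads — here one bead per
molecule at its center of mass — and the beads interact through isotropic
pair potentials.  The task is to choose those potentials so that the CG
ensemble reproduces selected properties of the mapped reference ensemble.
cgforge implements two routes:

* **Relative-entropy minimization** over tabulated uniform cubic B-spline
  (CBSPL) potentials.  The relative entropy is the Kullback–Leibler-type
  divergence between the reference configurational distribution and the CG
  model's; in the canonical ensemble its derivatives with respect to the CG
  parameters reduce to differences of ensemble averages, and it is driven
  to a minimum by Newton–Raphson iteration.  For a pair form that is linear
  in its parameters this minimum is unique and, with a finely tabulated
  spline, reproduces the reference pair distributions.
* **Targeted (simplex) optimization** of the six-parameter analytic CKDg
  form, where a downhill-simplex search minimizes a penalty built from the
  radial distribution function (RDF) and optionally the pressure.  Nothing
  in the machinery ties it to structure: any scalar objective computable
  from a CG trajectory can be targeted.

## Potential representations

### CBSPL

A CBSPL potential stores knot values $c_0,\dots,c_m$ on an even grid
$r_i = i\,\Delta r$ with $\Delta r = r_{cut}/(m-2)$; the grid overshoots
the cutoff by two intervals so every $r < r_{cut}$ has four supporting
knots.  On the segment $r_k \le r < r_{k+1}$,
$$u(r) = \begin{bmatrix}1 & t & t^2 & t^3\end{bmatrix}\,
\frac{1}{6}\begin{bmatrix}1&4&1&0\\-3&0&3&0\\3&-6&3&0\\-1&3&-3&1
\end{bmatrix}\begin{bmatrix}c_k\\c_{k+1}\\c_{k+2}\\c_{k+3}\end{bmatrix},
\qquad t = \frac{r-r_k}{\Delta r}.$$
The representation is $C^2$, linear in its knots, and local: each knot
influences four intervals.  Three consequences shape the implementation:

* the four tail knots at $r \ge r_{cut} - \Delta r$ are frozen at zero,
  which forces both $u$ and $f=-u'$ to reach zero smoothly at the cutoff
  ("a couple of knots before and after the cutoff" made precise as the
  four knots of the overhang);
* knots in the core region $r \le r_{min}$ are excluded from optimization
  — separations there are essentially never sampled, so the corresponding
  rows of the Hessian would vanish;
* the parameter derivatives $\partial u(r)/\partial c_j$ are just the
  basis weights of $r$, and second parameter derivatives vanish.

`r_min` defaults to the smallest reference-RDF bin center with $g>0$.

### CKDg

The analytic form is a WCA-split Lennard-Jones repulsion, a
cosine-squared attractive well of depth $\epsilon$ and width $w_c$, and a
Gaussian bump of amplitude $h$, mean $p$ and width $s$, shifted so it
vanishes at its cutoff $r_c$ and clamped to zero beyond (the potential
must be finite-ranged for cell lists).  Six parameters
$(\sigma,\epsilon,w_c,h,p,s)$ are free.

As printed in the source literature the repulsive branch evaluates to $0$
at its split radius while the well branch evaluates to $-\epsilon$ there,
and the split radius is never assigned a value.  cgforge fixes the split
at $r_{c,LJ}=2^{1/6}\sigma$ (the WCA minimum, consistent with the split
radius not being an optimized parameter) and subtracts $\epsilon$ from the
repulsive branch, giving a continuous potential with minimum $-\epsilon$.
`strict = TRUE` reproduces the discontinuous as-printed branch for
comparison.  The ambiguous $\cos^2$ argument is read as
$\pi(r - r_{c,LJ}) / (2 w_c)$, which is the only reading that makes the
well close smoothly at $r_{c,LJ}+w_c$.

## Sampling: Metropolis Monte Carlo, not MD

All observables the optimizers need — RDFs, the virial pressure, ensemble
averages of parameter derivatives — are configurational, so the package
samples with single-molecule Metropolis moves (rigid translations and
rotations for multi-site molecules) rather than integrating dynamics.
This avoids thermostats and integrators entirely; the cost is that no
dynamical information exists in the trajectories, which is irrelevant
here.  External ensembles are accepted through a plain XYZ dialect
(`read_xyz()`), so any engine can stand in for the built-in sampler.

Numerical conventions:

* potentials enter the sampler as uniform tables with linear interpolation
  of $u$ and $f$; the interval is located by direct index arithmetic;
* diverging cores are capped at $10^{10}$ energy units when tabulated —
  the only role of those bins is to reject moves;
* distances use the minimum-image convention in a cubic box;
* the first 25% of each chain is discarded as equilibration by default,
  mirroring the proportions of typical reference protocols;
* the chain consumes R's RNG stream, so a single seed reproduces a run
  bit-for-bit; every driver records the seeds it used.

An internal invariant is checked continuously: every 1000 moves the
incrementally tracked total energy is compared against a full
recomputation, and the worst discrepancy is reported as `drift_max`
(typically $10^{-12}$; the test suite requires $<10^{-8}$).

## Relative-entropy Newton–Raphson

Each iteration: sample a CG ensemble with the current potentials;
accumulate per-frame sums of basis weights over all site pairs (skipping
$r \le r_{min}$) in both the mapped-reference and the CG ensembles; form
the gradient $\beta(\langle d\rangle_{AA} - \langle d\rangle_{CG})$ and,
for the linear CBSPL form, the Hessian
$\beta^2\,\mathrm{Cov}_{CG}(d)$ over the free knots; apply the relaxed
update $\lambda \leftarrow \lambda - \chi H^{-1}\nabla$; refill the core
by extrapolation; evaluate the convergence errors.  The mapped-reference
averages are computed once and reused, since they do not depend on the
CG parameters.

Stability choices, each made once and used everywhere:

* **Relaxation** $\chi$ defaults to 1.  If the total error grows for three
  consecutive iterations, $\chi$ is halved and the iterate reset to the
  best seen; after three halvings the run aborts with a flag.
* **Step cap.** The sampled covariance underestimates curvature along
  knot directions that few pairs visit, and the raw Newton displacement
  along them can be enormous.  The update is rescaled so its largest
  component does not exceed one $k_BT$ (configurable via `step_max`).
  This is a trust-region-style guard, not a change to the update
  direction.
* **Ridge.** A numerically singular Hessian receives
  $\tau I$ with $\tau = 10^{-8}\,\mathrm{tr}(H)/n$ before the solve is
  retried; the event is logged.
* **Core extrapolation.** After each update the frozen core knots are
  refilled with a repulsive exponential $A e^{-Br}$ anchored at the first
  separation whose spline value is determined entirely by free knots;
  the core control points are set to the exponential's values at the knot
  positions, so the variation-diminishing property of B-splines guarantees
  a monotone core with no ringing.  A non-repulsive anchor falls back to a
  linear continuation with a warning.
* **Convergence errors.** $\epsilon_\lambda$ is the sum of squared
  parameter changes, $\epsilon_u$ the sum of squared potential changes on
  a fine grid restricted to the optimized region $(r_{min}, r_{cut}]$
  (the extrapolated core's large absolute values would otherwise swamp
  it), and $\epsilon_{tot} = w_\lambda\epsilon_\lambda + w_u\epsilon_u$.
  Defaults $w_\lambda = 0$, $w_u = 1$: the potential error is what
  matters physically, and the weights are configurable.
* **Reported potentials.** Because the per-iteration CG ensembles are
  stochastic, the iteration settles into a noise plateau rather than a
  point; the reported potentials average the knot vectors of the trailing
  5 iterations (configurable).
* **Initial guess.** The CBSPL form is least-squares fitted to the
  potential of mean force $-k_BT\ln g(r)$ of the reference RDF, with
  bins where $g \le 10^{-10}$ treated as undefined rather than infinite,
  and knots whose support contains fewer than three defined target points
  left to the core extrapolation.

## Targeted simplex optimization

The polytope of $n+1$ vertices is transformed by reflection
($\alpha = 1$), expansion ($\gamma = 2$), contraction ($\rho = 0.5$) and
reduction ($\sigma = 0.5$), with the decision flow: reflect; if the
reflected point beats the best vertex, try the expansion and keep the
better of the two; if it is worse than the worst vertex, contract; if
even the contraction fails to improve on the worst vertex, shrink the
whole simplex toward the best vertex and re-evaluate.  Contraction
triggers on `y_r > y_worst` exactly as stated in the source formulation
(the textbook variant compares against the second-worst vertex); the
printed contraction range "0 > ρ > 1" is unsatisfiable and is implemented
as $0 < \rho < 1$.  Expansion acceptance is not specified in the source;
cgforge keeps the expansion only when it beats the reflection.  The
reduction is applied in the printed summed form $\sigma(p_i + p_1)$,
which at $\sigma = 0.5$ equals the conventional midpoint form; for any
other $\sigma$ the summed form is used and logged.

The penalty is
$y = \sum_{r_i \in [r_{lo}, r_{hi}]} |g_{CG}(r_i) - g_{ref}(r_i)|
+ a\,|p_{CG} - p_{ref}|$, with $a = 0$ switching the pressure term off.
The comparison range is configuration-driven; for the bulk-water analog
in the source it spans the first two coordination shells.

Stochastic-objective choices:

* one penalty evaluation per vertex, with **common random numbers**: all
  vertices within one polytope step share the sampler seed, so ordering
  errors cancel to first order;
* every evaluation starts from one shared configuration, relaxed by a
  short greedy (zero-temperature Metropolis) descent before sampling —
  expansion moves can propose parameters for which the inherited
  configuration is deep inside a repulsive wall;
* $\sigma,\epsilon,w_c,s$ are constrained positive by rejection: a vertex
  outside bounds scores $+\infty$ without sampling;
* evaluator failures likewise score $+\infty$ and are logged, so one
  pathological vertex cannot abort a run.

The optimizer runs either inline (`simplex_minimize()`) or through a
text state file (`simplex_advance()` plus the `cgforge` CLI), where each
communication round proposes at most one trial point for external
evaluation; the two drivers visit identical simplex states.

## Neighbor search and frame-parallel analysis

Pair enumeration is available as a brute-force $O(N^2)$ double loop and
as an $O(N)$ cell list (cell edge at least the cutoff, 26 periodic
neighbor cells); the two return identical pair sets, and boxes narrower
than three cells per edge fall back to the simple search with a message.
RDFs use half-open bins $[k\Delta, (k+1)\Delta)$ — a distance exactly at
`r_max` is excluded — normalized per frame by the ideal-gas shell count
with pair densities $N(N-1)/2/V$ (like pairs) and $N_A N_B/V$ (cross
pairs); the cross-species convention is declared, not inherited from the
source, which does not state one.

Per-frame analyses run through `parallel_map_frames()`, which chunks
frames in order, folds each chunk with the supplied merge rule, and
merges chunks in frame order.  The contract — not the backend — is the
interface: results are bit-identical for integer accumulators and equal
to the serial fold within floating-point associativity otherwise,
independent of the worker count.  Workers are forked processes where the
platform supports them.

## What the synthetic references are, and are not

`generate_reference_fixture()` emulates the role of an external atomistic
reference with toy fluids whose ground-truth potentials are known: a
60-particle single-site fluid interacting through a CKD well
($\sigma = \epsilon = 1$, $w_c = 0.5$, reduced units, $k_B = 1$) at
$T^* = 1.5$ and bead density $\rho^* = 0.5$ — a well-behaved dense-fluid
state point — plus two- and three-site rigid-molecule variants and a
two-species mixture with three pair interactions.  Reference runs use
$2\times10^5$ moves with 200 recorded frames; the per-iteration CG runs
of the relative-entropy driver default to $4\times10^5$ moves with 400
recorded frames, mirroring the 400-frame per-iteration analysis protocol
of the mixture study that motivated this layout.  These sizes keep a full
recovery experiment under a minute on one core.

Self-target experiments on these fixtures demonstrate: the fixed point of
the relative-entropy gradient (sampling the reference's own potential
makes the gradient vanish within Monte-Carlo error), RDF recovery (the
optimized CBSPL reproduces the reference RDF to within a few percent per
bin), positive-semidefiniteness of the Hessian at every iteration, and
CKDg parameter recovery by the simplex from ±20% perturbed starts.

They do **not** demonstrate transferability across state points,
behavior with long-range electrostatics or orientational order (real
water's double-well CG potential emerges from hydrogen-bond structure the
toy fluids lack), multi-body effects, or statistics at realistic system
sizes; passing the suite means the machinery is correct, not that a
particular real system is well coarse-grained.

## Known limitations

* Bonded CG interactions and 3-/N-body potentials are out of scope; the
  rigid-molecule sampler freezes intramolecular degrees of freedom.
* Absolute relative-entropy values are not computed — they require free
  energies and the mapping entropy, both constant in the CG parameters —
  only the derivatives needed for optimization.
* The reweighting shortcut for CG-ensemble averages (avoiding a fresh CG
  run each iteration) is not implemented; each iteration samples anew.
* The CMA evolution-strategy optimizer is not implemented; the state-file
  cycle (`simplex_advance()`'s propose/evaluate contract) is the plug-in
  point where another derivative-free optimizer would attach.
* At desk-scale statistics the Newton iteration settles into a stochastic
  plateau; the trailing-window average is the estimator, and the
  convergence tolerance should be set relative to the plateau's noise
  floor (the workflow driver defaults to `tol = 0.1` for the bundled
  fluid for this reason).
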