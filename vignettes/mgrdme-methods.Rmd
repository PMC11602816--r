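---
title: "Multi-grid compartment models for morphogen gradients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-grid compartment models for morphogen gradients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgrdme)
```

## The model

`mgrdme` simulates two-species reaction-diffusion kinetics on an interval
$[0, L]$ in the compartment-based (lattice) description: the domain is split
into $K$ boxes of width $h = L/K$, diffusion becomes nearest-neighbour jumps
at per-molecule rate $D/h^2$, and reactions fire within boxes with
propensities from mass-action kinetics. The joint copy-number process is a
continuous-time Markov jump process; its master equation is the
reaction-diffusion master equation (RDME).

The package's core generalization is the *multi-grid* RDME: each species
gets its own lattice. Signalling molecules $A$ (fast, $D_A \gg D_B$) live on
a coarse grid of $K_A$ boxes, the morphogen $B$ on a fine grid of $K_B$
boxes, with resolution ratio $\gamma = K_B/K_A = h_A/h_B$. Cross-species
reactions (conversion $A \to B$ or dimerization $A + A \to B$) fire in an
$A$-box and must place their product in some $B$-box: the rate is shared
among target boxes proportionally to interval overlap,
$$ W_{ij} = \frac{|C_i^{(B)} \cap C_j^{(A)}|}{|C_j^{(A)}|}, $$
so every column of $W$ sums to one and the total conversion rate per $A$
molecule is unchanged. For integer $\gamma$ this reduces to sharing the rate
equally over the $\gamma$ sub-boxes; the package implements the general
overlap form throughout, so non-integer ratios work everywhere and the
integer case is just a special case. Compartments are half-open intervals
$[(i-1)h, ih)$ with 1-based indices; interval intersections use a relative
tolerance of $10^{-12}$ to avoid spurious zero-width overlaps at shared
endpoints.

Two networks are built in:

* **first-order**: $\emptyset \to A$ (rate $k_1$, localized in the first
  $A$-box), $A \to B$ (rate $k_2$), $B \to \emptyset$ (rate $k_3$). The
  stationary law is a product of Poisson distributions whose means solve two
  tridiagonal linear systems; `solve_stationary_means()` solves them
  sparsely (residual checked against $10^{-10}\,k_1$). Closed forms pin the
  totals: $\sum \bar A_j = k_1/k_2$, $\sum \bar B_i = k_1/k_3$, and the
  stationary reaction propensity is $3 k_1$.
* **dimerization**: $A + A \to B$ with bimolecular rate constant $k_2$
  (units length/time). No closed form exists; analysis relies on simulation
  (`simulate_ssa()`) and the brute-force generator oracle
  (`truncated_generator()`) for toy systems.

As the macroscopic ground truth for the first-order network, the stationary
concentration profiles with a point source at the origin are
$$ \bar a(x) = \frac{k_1}{\sqrt{D_A k_2}} e^{-\sqrt{k_2/D_A}\,|x|}, \qquad
   \bar b(x) = \frac{k_1\sqrt{k_2 D_A}}{D_A k_3 - D_B k_2}
   e^{-\sqrt{k_2/D_A}\,|x|}
   + \frac{k_1 k_2 \sqrt{D_B}}{(D_B k_2 - D_A k_3)\sqrt{k_3}}
   e^{-\sqrt{k_3/D_B}\,|x|}. $$
The generic $\bar b$ degenerates when $D_A k_3 = D_B k_2$ (equal decay
lengths). The closed confluent limit is
$\bar b(x) = k_1 (1/\alpha + |x|) e^{-\alpha |x|} / (2 D_B)$ with
$\alpha = \sqrt{k_2/D_A}$; the code switches to it when the denominator
drops below $10^{-9}$ times its natural scale. This degenerate case is an
extension beyond the published analysis; the limit was derived by expanding
the two-exponential form in $\beta - \alpha$ and is verified in the tests by
checking it still integrates to $k_1/k_3$.

These unbounded-domain formulas are compared against lattice models on
$[0, L]$; the comparison is meaningful only when mass at the far boundary is
negligible, so `analytic_steady_state()` warns when
$\bar a(L)/\bar a(0) > 10^{-3}$.

## The dimerization propensity: a deliberate convention choice

For the dimerization network the in-box propensity is implemented as
$$ \frac{k_2}{h_A}\,\frac{n(n-1)}{2}, $$
i.e. each of the $n(n-1)/2$ unordered pairs reacts at rate $k_2/h_A$. Two
conventions circulate for lattice dimerization — total propensity
proportional to $n(n-1)$ or to $n(n-1)/2$ — and the choice is load-bearing
because it decides which particle-level dynamics the lattice matches. We
side with the pair-counting form because it is the one consistent with the
microscopic rate bridge. The particle-level (Doi) model lets a pair react at
rate $\lambda$ whenever within distance $\varrho$; a pair uniformly placed
in a box of width $h \gg \varrho$ is within range with probability
$2\varrho/h$, so the lattice per-pair rate matching the Doi dynamics is
$\lambda \cdot 2\varrho/h = k_2/h$ with $k_2 = 2\varrho\lambda$ — the
standard one-dimensional bridging of the bimolecular constant.
Doubling it (by dropping the $1/2$) makes the lattice consume $A$
visibly faster than the particle model: in our experiments the lattice
steady-state $A$ population drops to 8.5 against the particle model's 12.7,
the spatial error at $K_A = 15, K_B = 60$ grows roughly eight-fold, and the
error-minimizing $K_A$ shifts to about 8. With the pair-counting convention
the lattice matches the particle dynamics closely at $K_A = 15$ and the
error minimum sits at $K_A = 15$. The convention is therefore documented
here prominently.

## Stochastic simulation

`simulate_ssa()` is an exact Gillespie direct-method sampler, implemented in
C++ for throughput (millions of events per second). Design choices:

* Direct method with a per-class linear scan (production, $A$-jumps,
  $B$-jumps, reaction, degradation) rather than the next-subvolume method:
  event counts here are at most a few hundred, so the simpler enumeration
  wins, and the class totals are maintained incrementally from integer
  aggregates ($\sum n_j$, $\sum n_j(n_j{-}1)$, boundary terms), which is
  exact and drift-free.
* Time-weighted moments, not event-weighted: SSA states persist for
  exponential holding times, so means and variances are accumulated as
  integrals over time, lazily per compartment (each compartment keeps the
  time of its last change), giving $O(1)$ accumulation per event.
* Monte-Carlo standard errors come from batch means (default 20 batches
  over the post-burn-in window). Batch lengths far exceed the system's
  relaxation times ($1/k_2$, $1/k_3$) in all shipped configurations;
  empirically the batch SEs were within ~15% of the seed-to-seed spread.
* Randomness flows from R's RNG (`set.seed(seed)` per trajectory), so runs
  are reproducible across platforms that ship the same R RNG.
* Initial condition defaults to the empty lattice; for first-order
  steady-state studies `init = "poisson"` draws the stationary product-
  Poisson state, removing the burn-in transient entirely.

The mgRDME with $\gamma = 1$ *is* the standard RDME here — there is one code
path and $W$ is the identity — so the spec-level requirement that the two
coincide distributionally holds by construction and is exercised in tests.

## Brownian dynamics ground truth

`bd_simulate()` integrates the particle model with explicit time steps:
Gaussian displacements (variance $2D\Delta t$) with reflecting boundaries at
$0$ and $L$, Poisson production, and exponential-survival sampling
($1 - e^{-k\Delta t}$, not its Taylor approximation) for first-order events.
Dimerization uses the Doi rule: candidate pairs within $\varrho$ are found
by a sorted sweep each step, processed in random order, each firing with
probability $1 - e^{-\lambda \Delta t}$; a consumed particle invalidates its
remaining pairs. Unspecified microscopic details were fixed once:

* new $A$ particles appear exactly at $x = 0$ (the delta-source convention
  that the analytic profiles assume); a uniform-over-first-compartment
  alternative is available for like-for-like lattice comparisons;
* the product $B$ of a dimerization is placed at the pair midpoint (the
  symmetric choice; either reactant's position is available);
* the default timestep obeys $\sqrt{2 D_A \Delta t} \le \varrho/2$ so
  particles cannot jump across the reaction radius undetected
  ($\Delta t = \varrho^2/(8 D_A) \approx 3.1\times10^{-4}$ for the shipped
  dimerization parameters), and the code warns when $\lambda\Delta t > 0.1$.

Halving $\Delta t$ moved stationary profile estimates by less than their
Monte-Carlo SEs in our checks, and the first-order BD profiles agree with
the closed forms to a few percent in $L^1$ at moderate horizons.

## Error, cost, and the design sweep

The spatial error of a lattice solution is the $L^1$ distance between
concentration profiles,
$\mathrm{err} = \int_0^L |\bar b(x) - \bar B_i/h|\,dx$ — note the
compartment counts are divided by $h$ so both sides are concentrations;
comparing a concentration against raw counts would be dimensionally
inconsistent, and the concentration form is the one the package computes.
Piecewise-vs-piecewise errors are computed exactly on the merged
breakpoint grid; smooth-vs-piecewise errors per compartment with adaptive
quadrature, splitting each panel at sign changes located by scan plus root
bracketing so $|\cdot|$ never kinks inside a panel.

The cost of a design point is the stationary total event rate, which is what
Gillespie iteration counts scale with: for the first-order network the
closed form $3k_1 + 2(D_A/h_A^2)(k_1/k_2) + 2(D_B/h_B^2)(k_1/k_3)$; for
dimerization the analogous expression evaluated at simulation-estimated
population totals, with a global quadratic term
$k_2 \bar A_{tot}(\bar A_{tot}-1)$ — a deliberate coarse summary (no
per-compartment spatial structure, no pair-counting factor): it is a
design-point metric, not a simulated propensity. `pareto_front()` extracts
the non-dominated subset with a $10^{-12}$ tie tolerance, so duplicates and
reorderings cannot change the front.

For the dimerization sweep the reference profile itself is a Monte-Carlo
estimate; `sweep_dimerization()` therefore averages the SSA error over
seeds and reports the between-seed SE. At short horizons the $L^1$ error
has a noise floor (sum over 60 bins of per-bin sampling noise) that
flattens the minimum: at $T \lesssim 5000$ the sample argmin wanders within
$K_A \in [15, 20]$, while by $T \approx 15000$ it settles at
$K_A = 15$ with the error clearly below that of its neighbours. The
acceptance script uses $T = 15000$ with three seeds for this reason.

## What the built-in configurations emulate

The shipped fixtures are the two reference parameter sets of the morphogen
study this package operationalizes: a first-order cascade with
$k_1 = 100, k_2 = 2, k_3 = 1, D_A = 0.16, D_B = 0.01$ on $L = 2$ (so
$K = 40$ gives $h = 0.05$ and jump rates $64$ and $4$), and a dimerization
system with $k_1 = 50, \lambda = 5, \varrho = 0.02, k_3 = 2$ on $L = 1$
(so $k_2 = 0.2$, reference grids $K_A = 15$, $K_B = 60$). They emulate a
localized source feeding a diffusing, decaying morphogen — the standard
pre-patterning gradient scenario. They do **not** emulate features of real
morphogen systems such as advection, growth of the domain, binding kinetics,
2D/3D geometry, or time-dependent readout; a green test establishes
agreement between the three model layers (lattice, particle, analytic) in
this stated world, not biological fidelity beyond it.

## Numerical choices and degenerate inputs

* Linear systems: sparse LU via the Matrix package; explicit post-solve
  residual check at $10^{-10} k_1$.
* Quadrature: `stats::integrate` (adaptive Gauss–Kronrod) at relative
  tolerance $10^{-8}$ for profile integrals.
* `truncated_generator()` caps each compartment's counts and *removes*
  outflow across the cap (reflecting truncation), keeping a proper
  generator; its stationary law solves the null-space problem with the
  normalization row replacing one balance equation. State spaces are limited
  to $10^6$ states. Caps must cover the stationary mass — means plus ~8–10
  standard deviations in the tests.
* Zero-rate models: the SSA fast-forwards to the horizon when the total
  propensity vanishes; the generator oracle returns the point mass at the
  empty state (any point mass is stationary for the zero generator).
* `K_A = K_B = 1` lattices have no diffusion events; the jump-rate terms
  vanish identically rather than erroring.

## Known limitations

* One-dimensional structured grids only; no unstructured meshes, no
  per-region refinement, no 2D/3D Doi spheres (the rate bridge
  $k_2 = \lambda|B_\varrho|$ is implemented for $d = 1$ only).
* No time-dependent analytic solutions or error metrics; all comparisons
  are stationary.
* The dimerization reference is itself simulated, so dimerization error
  values carry reference noise that deterministic first-order errors do
  not.
* No tau-leaping or hybrid acceleration; horizons beyond $T \sim 10^5$
  events-per-unit-time budgets become slow.
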