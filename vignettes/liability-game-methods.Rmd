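---
title: "Methods: replicator dynamics of injury-accident liability rules"
author: "liabgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicator dynamics of injury-accident liability rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liabgame)
```

## The model

School sports injury liability is modelled as an asymmetric two-population
evolutionary game. One population is schools, the other students and their
guardians; each individual either exercises *appropriate caution*
(common-sense prevention effort) or *no caution*. The state of the system is
the pair $(\alpha, \beta) \in [0,1]^2$: the shares of schools and of
students currently playing appropriate caution.

Five scalar parameters drive everything, all in arbitrary currency units
unless noted:

| parameter | meaning | domain | default source |
|---|---|---|---|
| $c_c$ | school prevention cost | $> 0$ | per case study |
| $c_s$ | student/guardian prevention cost | $> 0$ | per case study |
| $p$ | total accident loss | $> 0$ | per case study |
| $a$ | school's loss share when neither side is cautious | $[0,1]$ | swept |
| $b$ | student prevention-cost share reimbursed by the school when only the student is cautious | $[0,1]$ | swept |

An accident (total loss $p$) occurs whenever at least one side is careless.
Under the **proportional (parametric) rule** the loss and prevention costs
are apportioned through $a$ and $b$; the payoff bimatrix
(student, school), with the student as row player, is

|  | school cautious | school careless |
|---|---|---|
| **student cautious** | $(-c_s,\ -c_c)$ | $(-(1-b)c_s,\ -p - b c_s)$ |
| **student careless** | $(-p,\ -c_c)$ | $(-(1-a)p,\ -a p)$ |

Under the **strict rule** the school bears the full loss whenever an
accident occurs, even when only the student was careless: school payoffs
become $-c_c$, $-p - c_s$, $-c_c - p$, $-p$ across the same four cells, and
the student payoff is zero except when paying their own prevention cost.
Note this is *not* the $a = b = 1$ limit of the parametric matrix: the two
differ exactly in the (student careless, school cautious) cell, where the
strict rule moves the loss $p$ from the careless student onto the cautious
school. Because the two readings of "strict" genuinely differ, the package
exposes both (`rule = "parametric"` with $a = b = 1$, and
`rule = "strict_override"`) and asserts neither as the correct one.

## Replicator dynamics

With expected gains $E_a = -c_c$ and
$E_n = -\beta(p + b c_s) - (1-\beta) a p$ for the school (and analogous
$S_a$, $S_n$ for students), the two-population replicator equations are

$$\dot\alpha = \alpha(1-\alpha)\bigl[\beta\bigl((1-a)p + b c_s\bigr) - (c_c - a p)\bigr],$$
$$\dot\beta = \beta(1-\beta)\bigl[\bigl((1-a)p - (1-b)c_s\bigr) - (b c_s - a p)\alpha\bigr].$$

`generic_bimatrix_flow()` implements the textbook replicator directly from
the payoff cells and serves as an independent oracle: the closed forms must
agree with it to $10^{-12}$ on random draws (they do; this is the module's
central correctness test).

Rest points are the four corners plus, when it lies in the open square, the
interior point

$$\alpha^* = \frac{(1-a)p - (1-b)c_s}{b c_s - a p}, \qquad
  \beta^*  = \frac{c_c - a p}{(1-a)p + b c_s}.$$

## Stability classification

Local stability is decided from the Jacobian determinant and trace
(an equilibrium is an ESS iff $\det J > 0$ and $\operatorname{tr} J < 0$;
$\det J < 0$ is a saddle; $\det J > 0,\ \operatorname{tr} J > 0$ is
unstable; a vanishing determinant or trace is non-hyperbolic). Writing the
corner net gains

$$\pi_1 = a p - c_c,\quad \pi_2 = p + b c_s - c_c,\quad
  \pi_3 = p - c_s,\quad \pi_4 = (1-a)p - (1-b)c_s,$$

the corner classifications reduce to sign conditions:
$(0,0)$ is an ESS iff $\pi_1 < 0 \wedge \pi_4 < 0$; $(1,1)$ iff
$\pi_2 > 0 \wedge \pi_3 > 0$; $(0,1)$ iff $\pi_2 < 0 \wedge \pi_4 > 0$;
$(1,0)$ iff $\pi_1 > 0 \wedge \pi_3 < 0$. Since
$\pi_2 - \pi_1 = (1-a)p + b c_s \ge 0$, the pattern
$\pi_1 > 0 \wedge \pi_2 < 0$ is infeasible.

Two derivations here are worth flagging because they are easy to get
wrong:

* **The off-diagonal entry $\partial\dot\beta/\partial\alpha$.** The true
  derivative is $\beta(1-\beta)(a p - b c_s)$. A tempting variant that
  repeats the $\alpha$-independent bracket,
  $\beta(1-\beta)\bigl((1-a)p-(1-b)c_s\bigr)$, circulates for this system
  but is not the derivative of the flow. Corner values are unaffected (the
  off-diagonals vanish at every corner), but interior classification needs
  the true derivative; `game_jacobian()` uses it and exposes the variant as
  an attribute for comparison.
* **The interior point is never an ESS.** At $(\alpha^*, \beta^*)$ both
  diagonal entries vanish, so $\operatorname{tr} J = 0$ exactly: the point
  is a saddle when $a p > b c_s$ (negative determinant) and a
  non-hyperbolic centre when $a p < b c_s$. In the centre case trajectories
  orbit instead of converging, and no corner is attracting.

`classify_scenario()` maps the strict sign pattern of
$(\pi_1,\dots,\pi_4)$ onto the ten tabulated stability scenarios. Two
design points:

* Any $\pi_i$ within $10^{-12}\max(c_c, c_s, p)$ of zero yields
  `"boundary"` rather than a forced sign — non-hyperbolic corners must not
  silently receive an ESS verdict (the fifth case study, with $c_s = p$ and
  hence $\pi_3 = 0$, is exactly this situation).
* The ten tabulated patterns do not exhaust the feasible strict patterns:
  $(+,+,-,-)$ and $(+,+,+,+)$ are reachable and return `"unlisted"`. Their
  equilibria are still fully classified; only the scenario label is outside
  the tabulation.
* The tabulated row for the pattern $(-,+,+,-)$ (scenario 3) is internally
  inconsistent: $\det J$ at $(1,1)$ equals $\pi_2\pi_3 > 0$ with negative
  trace, so $(1,1)$ is a *second* ESS next to $(0,0)$ — the system is
  bistable with an interior saddle, and starts split between the two
  basins. The package follows the determinant/trace rule, reports both ESS
  corners, and the convergence suite accordingly checks membership of the
  ESS set for this pattern rather than unanimity.

## Numerical integration

`integrate_game()` uses an adaptive implicit solver (`deSolve`'s `vode`,
variable-order Adams/BDF) with `rtol = 1e-10`, `atol = 1e-12`,
`t_max = 500` by default. Three numerical choices deserve explanation:

* **Implicit, not explicit.** Trajectories spend most of $[0, t_{\max}]$
  in exponential decay towards an attracting corner, with a decay rate
  proportional to the monetary scale $\max(c_c, c_s, p)$. For the
  largest case study (scale 1000) an explicit Runge-Kutta pair is
  stability-limited to steps of order $10^{-3}$ and needs minutes per
  trajectory; implicit multistep takes the same run in milliseconds. Among
  the implicit options, the Adams/BDF family also resolved every
  pathological start we probed, whereas the implicit Runge-Kutta (Radau)
  error control stalls short of corners once the boundary guard (below)
  introduces a kink in the field.
* **Boundary guard.** The exact field is tangent to $[0,1]^2$, but in
  floating point a share can land infinitesimally outside, where the raw
  polynomial $x(1-x)(\cdot)$ *amplifies* the excursion whenever the bracket
  has the growth sign — near-heteroclinic orbits of the centre case blow up
  catastrophically without protection. The right-hand side therefore
  evaluates flows at the state clipped to the square and adds a linear
  restoring term on the out-of-bounds excess. The field on the square is
  unchanged; the maximum pre-clipping overshoot stays near $10^{-10}$
  (the package's invariance tests bound it by $10^{-9}$). The default
  solver tolerances are set tight precisely to hold that bound.
* **Verdicts.** A run is classified `corner` when the final state is within
  $10^{-3}$ of a corner *and* the flow norm there is below $10^{-8}$;
  `interior` within $10^{-3}$ of a valid interior equilibrium; otherwise
  `undecided` (cycling, stalled boundary case, or horizon too short). The
  thresholds are configurable; the defaults resolve all five case studies
  in well under a second each.

## Case studies and sweeps

`liability_cases()` encodes five canonical parameter sets, all started from
$(0.5, 0.5)$ and swept over $(a, b)$ (case 5 restricts $a \in [0.5, 1]$).
`run_case()` integrates every grid cell (default $21 \times 21$; the tests
use coarser grids for speed), attaches per-cell scenario labels and
verdicts, and compares against the case's expected outcome under the
convention: *strict rule* = the cell nearest $a = b = 1$ (with the
strict-override dynamics run alongside), *proportional rule* = the modal
verdict over interior cells $0.1 \le a, b \le 0.9$. A sweep reports one
summary but never discards cell-level disagreement: `res$disagreements`
persists every cell whose verdict differs from the claim.

Three documented discrepancies are reported rather than resolved:

* **Case 3, proportional claim.** With $p = 12$, $c_c = 8$, $c_s = 4$,
  $\pi_2 = 4 + 4b > 0$ and $\pi_3 = 8 > 0$ for *all* $(a, b)$, so $(1,1)$
  is the unique corner ESS everywhere and the claimed (no caution,
  appropriate caution) outcome is analytically impossible; all interior
  cells appear as disagreements.
* **Case 4, strict sub-range.** Near $a = 1, b = 0$, $\pi_4 < 0$ and the
  sweep converges to $(0,0)$ instead of the claimed $(0,1)$.
* **Case 5 degeneracy.** $c_s = p$ makes $\pi_3 = 0$: every cell is a
  boundary scenario, trajectories stall on the $\alpha = 1$ edge, and no
  outcome is asserted. The case's unexplained annotation
  $\lambda = 1/100$ is carried as metadata only.

Under the strict-override dynamics the student strategies become
payoff-neutral once the school is careless, so the whole $\alpha = 0$ edge
is a continuum of rest points and runs typically end `undecided` at
$(0, \tilde\beta)$ — the qualitative message (the school abandons caution
unless the loss is very high) survives, but no corner verdict is claimed.

`phase_portrait()` samples the flow on a lattice and, when the interior
point is valid, partitions the square into the four rectangles delimited by
$(\alpha^*, \beta^*)$ with the conventional attractor assignment
(upper-left $\to (0,1)$, upper-right $\to (1,1)$, lower-left $\to (0,0)$,
lower-right $\to (1,0)$). When no corner is an ESS the portrait is flagged
`cycling_expected`: the partition is then only the conventional narrative,
since trajectories orbit the interior centre.

## Scenario realization and the convergence suite

`find_scenario_params()` locates parameters realizing each of the ten sign
patterns by a deterministic search over a small catalogue of candidate
values; `check_scenario_convergence()` then integrates a $3\times3$
interior lattice of starts per scenario and checks that every corner
reached is ESS-classified, that unique-ESS scenarios attract all nine
starts, and that the all-saddle scenario reaches no corner at all within
the horizon.

## What the checks do and do not show

All empirical statements in this vignette are recomputed by the test suite
and by `scripts/acceptance.R`; problem sizes there are $1000$ random
parameter draws for the algebraic identities, $10 \times 9$ trajectories
for the convergence suite, and $11\times11$ grids for the sweeps. The
model abstracts away everything a court would actually face — monetary
realism, third-party infringers, more than two liability subjects,
boundedly irrational or moral behaviour — so passing checks demonstrate
internal consistency of the game-theoretic machinery, not predictive
validity for real litigation data. Cycling in the all-saddle configuration
is reported empirically; no Lyapunov-function argument is attempted.
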