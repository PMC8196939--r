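---
title: "Methods: threshold pulse vaccination in an SIS model with saturated treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: threshold pulse vaccination in an SIS model with saturated treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(impulseSIS)
```

## The model and its assumptions

impulseSIS studies an SIS epidemic with three control ingredients: natural
recovery $vI$, hospital treatment at the saturating rate $cI/(b+I)$
(capacity $c$, half-saturation $b$ — the treatment system can only process
so many cases at once), and *state-dependent pulse vaccination*: whenever
the susceptible population reaches a threshold $S_T$, a fraction
$q \in (0,1)$ is vaccinated instantaneously.  The policy is
surveillance-driven rather than calendar-driven, which makes the model a
hybrid (impulsive) dynamical system: smooth flow below the threshold, a
jump on the section $S = S_T$.

Two standing assumptions shape everything:

* **Demographic equilibrium.** The total population obeys
  $dN/dt = A - dN$, so $N \to A/d$.  On that manifold the vaccinated
  compartment can be eliminated and the model reduces to a planar system
  for $(S, I)$ in the invariant triangle
  $D = \{S, I \ge 0,\ S + I \le A/d\}$.  The package implements both the
  planar reduction (`sis_simulate`) and the full three-compartment system
  (`sis_simulate3d`); the exact law
  $N(t) = A/d + (N_0 - A/d)e^{-dt}$, which pulses conserve, is used as a
  correctness check on the event handling.
* **Threshold reachability.** The policy only makes sense if susceptibles
  can regrow to the threshold, which requires $S_T < A/d$; the parameter
  constructor enforces this (and $A,d,\beta,v,c,b > 0$, $\theta \ge 0$,
  $0 < q < 1$).

## Parameters

| symbol | meaning | unit | baseline |
|---|---|---|---|
| $A$ | susceptible recruitment | indiv·time⁻¹ | 7 |
| $d$ | natural death rate | time⁻¹ | 0.7 |
| $\beta$ | transmission coefficient | indiv⁻¹·time⁻¹ | 1 (or 0.8) |
| $v$ | natural recovery rate | time⁻¹ | 4 |
| $\theta$ | vaccine waning rate | time⁻¹ | 0.1 |
| $c$ | maximal treatment rate | indiv·time⁻¹ | 2.5 |
| $b$ | treatment half-saturation | indiv | 1 |
| $q$ | pulse vaccination fraction | — | 0.22 |
| $S_T$ | susceptible threshold | indiv | 8 (or 6.3) |

The three presets bundle these baselines: `fig1`
($\beta = 1$, $S_T = 8$; the disease-free cycle is marginally unstable,
$\mu_2 \approx 1.0095$), `fig2a` ($\beta = 0.8$, $S_T = 6.3$; globally
disease-free), and `fig2b` ($\beta = 0.8$, $S_T = 8$; bistable).  They are
reference configurations for a fast, strongly-controlled infection, not
fits to data; each sits deliberately close to a different side of the
$\mu_2 = 1$ boundary so that the full qualitative repertoire of the model
is exercised.

## The ODE core

Equilibria lie on the line $S + I = A/d$ (sum the two planar equations:
the residual is $(d+\theta)(A/d - S - I)$).  Endemic infective levels are
therefore roots of the quadratic $I^2 + a_1 I + a_2 = 0$ with
$a_1 = b + (d+v)/\beta - A/d$ and $a_2 = (c + b(d+v))/\beta - bA/d$.  The
case structure in $R_0 = Ab\beta/(d(c + b(d+v)))$, the subthreshold
$\hat R_0$ and the recruitment bound $A_1 = bd + d(d+v)/\beta$ produces a
backward bifurcation: for $A > A_1$ and $\hat R_0 < R_0 < 1$ two endemic
equilibria coexist, so pushing $R_0$ below one does not by itself clear
the infection.  `sis_equilibria` reports all of this; inputs numerically
on a case boundary ($|R_0 - 1|$ or the discriminant within $10^{-9}$
relative) are labelled `"boundary"` rather than forced into a branch.

**Stability index.** At an endemic state the Jacobian trace equals
$-(\theta + d + \beta I - cI/(b+I)^2)$, so the package's $H(I)$ is defined
as exactly that bracket: $H > 0$ means a stable node or focus.  A variant
of $H$ with an extra $+q$ appears when the continuous-vaccination term of
the three-compartment model is carried into the reduced system; since the
planar system contains no $q$, the default omits it, and
`paper_literal = TRUE` exposes the variant for comparison.  The stability
*label* additionally uses the determinant (saddle detection) and the
discriminant of the Jacobian (node/focus), which the trace alone cannot
decide.

## Hybrid simulation

The simulator integrates with `deSolve::lsodar`, whose root-finding stops
the integration exactly on $S - S_T = 0$; the root time is refined
internally by the solver, and the state at an impulse time is stored with
the left-continuous convention (pre-pulse value; the post-pulse value is
recorded separately and equals the pulse map of the pre-pulse state
*exactly*, by construction).  Because $q > 0$, the post-pulse state
$(1-q)S_T$ is strictly below the threshold, so no immediate retrigger is
possible.

Default tolerances are `rtol = 1e-10`, `atol = 1e-12` — far tighter than
trajectory plotting needs, because the Poincaré-map derivative estimates
difference nearby orbits and inherit the integration error.  Two further
numerical choices matter:

* **No-return timeout.** An orbit captured by an interior attractor never
  reaches the threshold; the map evaluator gives up after
  $50/(d+\theta)$ time units and raises a typed condition
  (`"sis_no_return"`) rather than looping.  `maxsteps` is raised well
  above the solver default, since that window is integrated as a single
  output interval.
* **Convergence detection.** The long-horizon simulator watches the
  running maximum of $S$ over windows of length $10/(d+\theta)$ (several
  relaxation times of the $S$-dynamics); if it stops increasing while
  staying below $S_T$, the orbit is declared converged to an interior
  attractor instead of integrating to the horizon.

Initial states with $S > S_T$ are rejected: the policy does not define an
orbit there, and silently applying an immediate pulse would invent
behaviour the model does not specify.

## The disease-free cycle and its multiplier

On $I = 0$ the flow is one-dimensional and solvable:
$\xi(t) = A/d - (A/d - (1-q)S_T)e^{-(d+\theta)t}$, period
$T = \ln(\Delta_1)/(d+\theta)$ with
$\Delta_1 = (A - d(1-q)S_T)/(A - dS_T) > 1$.  The transversal Floquet
multiplier has the closed form
$$\mu_2 = \Delta_1^{\frac{-d-v-c/b+\beta A/d}{d+\theta}}
  \exp\!\Big(-\frac{\beta q S_T}{d+\theta}\Big),$$
and the exponent numerator factors as $(d+v+c/b)(R_0-1)$, which is why
$R_0 < 1$ forces $\mu_2 < 1$.  The package keeps **three independent
routes** to $\mu_2$ and tests them against each other:

1. the closed form (`sis_mu2`),
2. the jump-factor-times-quadrature decomposition
   (`sis_mu2(route = "decomposed")`), agreeing to $10^{-12}$,
3. the finite-difference slope of the Poincaré map at the origin
   (`sis_dP1(0, p, order = 1)`), agreeing to $10^{-4}$.

The limits $q \to 0$ and $S_T \to 0$ both give $\mu_2 = 1$ (no pulse, or
a pulse applied at zero susceptibles, leaves the multiplier neutral).
These boundary values are outside the constructor's invariants and are
reachable only through `sis_mu2_limit`, the explicit limit-evaluation
entry point.

## Poincaré map numerics

`sis_map_P1` evaluates the return map by time-domain event integration,
reusing the simulator machinery.  The alternative formulation — integrate
$dI/dS = F_2/F_1$ in the phase plane — is singular wherever $F_1 = 0$
(exactly the tangency heights that bound the map's domain), so it is used
only as the *linearised* quadrature along $I = 0$, where $F_1 > 0$
throughout.

**Derivatives.** Central (interior) or one-sided (at the origin, where
the map is only defined for $I_0 \ge 0$ and $P_1(0) = 0$ is known
analytically) finite differences with two-level Richardson extrapolation.
Two refinements proved necessary:

* the order-1 slope at the origin is a *growth factor*, so the logarithm
  of $P_1(h)/h$ is extrapolated rather than the ratio itself — across
  parameter space the multiplier spans many orders of magnitude and the
  log-expansion stays tame;
* the probe step is chosen adaptively from a pilot evaluation so the
  probe image stays $\sim 10^{-4}$ (linear regime), and the integrator's
  absolute tolerance on $I$ is scaled to the starting level so tiny-$I$
  orbits are tracked with relative accuracy.

**g″(0) two ways.** The second derivative at the origin is computed both
by finite differences and by the quadrature
$g''(0) = \mu_2 \int_{(1-q)S_T}^{S_T} m(s)\, \partial I(s,0)/\partial I_0\, ds$,
where $m(s)$ is the second $I$-derivative of the phase-plane slope field
at $I = 0$ (re-derived here by series expansion of $F_2/F_1$:
$m = (2cF_{10}/b^2 - 2\varphi_0\psi_0)/F_{10}^2$ with
$F_{10} = (d+\theta)(A/d - s)$, $\varphi_0 = \beta s - d - v - c/b$,
$\psi_0 = -\beta s + v - \theta + c/b$) and the linearisation
$\partial I(s,0)/\partial I_0$ has a closed form.  The third derivative
is finite-difference only: the corresponding quadrature kernel involves
nested integrals and is error-prone to transcribe, while the FD estimate
is cheap and cross-checkable.

**Fixed points.** A sign scan of $P_1(I) - I$ on a grid over
$(0, I_{\max})$ with `uniroot` refinement.  Near the upper domain
boundary transit times diverge (the orbit shaves past the endemic
equilibrium), so a sign change can hide between the last returning grid
point and the first no-return point; the search therefore also bisects on
*validity* to close that gap.  The domain bound $I_{\max}$ comes from the
tangency geometry: the positive root of
$BI^2 + (D + Bb + c)I + Db = 0$ on the relevant section (when the leading
coefficient is negative), continued forward or backward to the other
section.  For the two regimes where return is not guaranteed by the case
analysis (C3, C4) the bound is reported as unknown and the map is still
evaluable pointwise, errors surfaced rather than clipped.

## Bifurcation analysis

The critical values solve $\mu_2(\alpha) = 1$ for
$\alpha \in \{q, S_T, A\}$, each bracketed by monotonicity arguments
derived from the closed-form derivative and refined by bisection to
$|\mu_2 - 1| < 10^{-8}$:

* in $q$: $\mu_2$ rises to a maximum at
  $\tilde q = 1 - (b(d+v)+c)/(b\beta S_T)$ and then falls; a root exists
  in $(\tilde q, 1)$ iff $\tilde q > 0$ and $\mu_2(1) < 1$.  The
  $b(d+v)+c$ grouping is forced by the sign factor
  $\beta(1-q)S_T - d - v - c/b$ of $\partial\mu_2/\partial q$; a variant
  with $b(b+v)+c$ is exposed behind `paper_literal` for comparison.
* in $S_T$: the turning points solve
  $\beta d(1-q)\bar S_T^2 + \beta A(q-2)\bar S_T + A(d+v+c/b) = 0$, whose
  discriminant is positive whenever $R_0 > 1$ because
  $K(q) = 4(1-q)/(q-2)^2 < 1 = K(0)$ on $(0,1)$; the roots straddle
  $A/d$, and $\mu_2$ runs from $1$ at $S_T = 0^+$ through a minimum to
  $+\infty$ at $A/d$, giving a unique crossing.
* in $A$: $\mu_2 \to \infty$ as $A \downarrow dS_T$ and
  $\mu_2 \to e^{-\beta q S_T/(d+\theta)} < 1$ as $A \to \infty$, so a
  doubling bracket always closes.  The derivative diagnostic
  $B_1(A)$ is implemented as
  $\ln(\Delta_1)/d - (A/d - (d+v+c/b)/\beta)\,dqS_T/((A-d(1-q)S_T)(A-dS_T))$;
  the $1/d$ on the log term is required for
  $\partial\mu_2/\partial A = \beta\mu_2 B_1/(d+\theta)$ to match the
  finite difference of the closed form (verified to $10^{-9}$ relative),
  and a literal variant without it is kept behind `paper_literal`.  The
  second-order diagnostic is a numerical derivative of $B_1$ rather than
  a transcribed polynomial whose printed leading coefficient is
  dimensionally inconsistent.

**Classification.** At a critical point the map family satisfies
$P_1(0,\alpha) = 0$ and $\partial P_1/\partial I_0 = 1$; the bifurcation
type follows from $g''(0)$ (transcritical when
$|g''| > 10^{-4}$, i.e. $10^{-4}\mu_2$ at the critical point) and
otherwise from $g'''(0)$ (pitchfork), with `"inconclusive"` returned when
both sit below the combined quadrature/finite-difference noise floor —
below that floor a sign is not evidence.  The cross derivative
$\partial^2 P_1/\partial I_0\,\partial\alpha$ equals
$\partial\mu_2/\partial\alpha$ and is reported with its sign (negative at
$q_1^*$ and $A^*$, positive at $S_T^*$).  For the baseline family all
three critical points classify as transcritical ($g''(0) > 0$); whether
$g''(0) > 0$ holds in general is not asserted — the package reports the
computed value.

## A note on "decreasing" in the disease-free regime

In the globally disease-free case C1 the return map is sometimes
described as monotonically decreasing.  As a *function* it is not: its
slope at the origin is $\mu_2 > 0$, and numerically $P_1$ is increasing
on its domain for C1 parameter sets (e.g. the baseline with
$\beta = 0.1$).  The property that actually holds — and that delivers
global attraction of the disease-free cycle — is *contraction*:
$P_1(I) < I$ for every $I > 0$, so the sequence of crossing heights
decreases monotonically to zero.  The test suite asserts the contraction
form.

## What the presets do and do not establish

The presets and the randomised parameter grids used in the tests exercise
deterministic, well-mixed, demographically closed dynamics with exact
threshold detection.  Passing tests therefore establish the internal
consistency of the analysis (closed forms against simulation against
quadrature) under those idealisations — not robustness to demographic
noise, reporting delays in detecting $S = S_T$, imperfect vaccine uptake,
or seasonal forcing, none of which are modelled.  Fixed-point detection
is limited to order-1 orbits; order-$k$ cycles of the map are out of
scope, as is a rigorous domain characterisation for cases C3/C4.

## Problem sizes

All computations are desk-scale: single ODE integrations over tens of
time units at tight tolerance.  The test suite runs
20-point random parameter grids for the property checks, 10 initial
conditions for the basin check of the globally disease-free preset
(horizon 25, up to 200 pulses each), and 100–140-point parameter scans;
the whole suite completes in a few seconds on one core.
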