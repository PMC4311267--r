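---
title: "Speed-coefficient model reduction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-coefficient model reduction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Mechanistic models of signalling networks routinely carry ten to thirty
dynamic variables, most of which relax much faster than the features of
interest. `speedred` implements a systematic way to find and exploit that
time-scale separation: rank the variables of an ODE system

$$\frac{\mathrm{d}x_i}{\mathrm{d}t} = f_i(x_1,\dots,x_N)$$

by their *speed coefficients*

$$\lambda_i(t) = \left|\frac{\partial f_i}{\partial x_i}\right|
  \Big|_{x = x(t)},$$

the absolute diagonal Jacobian entries evaluated along one representative
numerical solution. A large $\lambda_i$ means variable $i$ relaxes quickly
toward its momentary steady state, making it a candidate for a
quasi-steady-state approximation (QSSA). Because $\lambda_i$ varies along
the solution, the ranking uses the *fastest at its slowest* rule: for each
variable take the minimum of $\lambda_i$ over the analysed window, then
eliminate the variable whose minimum is largest.

When the equation of the chosen variable $x_j$ is affine in $x_j$,

$$\frac{\mathrm{d}x_j}{\mathrm{d}t} = \alpha_j(t) - \beta_j(t)\,x_j,$$

the zeroth-order QSSA replaces the ODE by
$\bar{x}_j^{0} = \alpha_j/\beta_j$, and the first-order refinement adds the
correction

$$\bar{x}_j^{1} = \frac{\alpha_j}{\beta_j}
  + \frac{\alpha_j\dot\beta_j - \beta_j\dot\alpha_j}{\beta_j^{3}},$$

with the dots expanded by the chain rule through the reduced dynamics.
The procedure iterates — simulate, rank, eliminate, re-simulate — and
every step is validated by direct comparison of the reduced and parent
solutions (period, amplitude, waveform error), the numerical counterpart
of letting the artificial Tikhonov parameter go from one to zero. The
mathematical backing is classical fast–slow asymptotics: under
stability assumptions on the fast subsystem, solutions (and periodic
orbits with their periods) of the full system converge to those of the
reduced one as the separation grows. The package encodes that guarantee
as an executable property: on a linear fast–slow toy pair with a
closed-form slow manifold (`build_toy_tikhonov()`), the reduced-model
error scales as $\varepsilon$ at order 0 and $\varepsilon^2$ at order 1,
and the test suite fits those slopes.

## The packaged model family

The showcase is a two-feedback model of the NF-κB signalling network.
Nuclear NF-κB (`r`) drives transcription of its inhibitor IκBα (mRNA `u`,
cytoplasmic protein `q`, nuclear protein `s`) and of A20 (mRNA `x`,
protein `y`); IκBα sequesters NF-κB in the cytoplasm (`p` free
cytoplasmic NF-κB, `z` the phosphorylated complex), while A20 shuts down
the kinase module that degrades IκBα (neutral IKK `v`, active IKK `w`).
The TNFα stimulus is the binary input `k24`. `build_sm()` returns this
10-variable system with the published rate constants (seconds and µM
throughout); under continuous stimulation it sustains relaxation-type
oscillations of nuclear NF-κB with a period near 100 minutes.

Two experimentally motivated stimulation protocols are packaged: constant
saturating TNFα (`k24 ≡ 1`) and a pulse train (5-minute pulses every
100 minutes). They define different representative solutions and, as the
test suite verifies, genuinely different reductions: the continuous
solution eliminates `z, p, y, v, s, w` in that order, while the pulsed
solution eliminates `z, p, y, w` — active IKK goes, neutral IKK stays,
because `v` only decays quickly while the stimulus is on. The two
6-variable models that result behave differently under pulsing (period
doubling versus 1:1 entrainment), which is the central scientific point:
a reduction is a statement *about a class of solutions*, not about the
network alone.

## Numerical and design choices

**Representative solutions.** Simulations start from the published
initial-condition column (the rest state of the original 14-variable
parent model) and run 3000 minutes for the continuous protocol
(1000 minutes discarded as transient) and ten stimulus periods for the
pulsed protocol (two discarded), reported on a 10 s grid. These horizons
give at least 19 full cycles for metrics at the ~100-minute period.

**The rest state of the simplified model is degenerate.** In the
10-variable model the constitutive complex-dissociation reactions of the
parent model have been pruned, so with the stimulus off the only exact
equilibrium is the drained one: all free NF-κB/IκBα forms at zero and the
IKK pool neutral. One can see this structurally: the free-NF-κB total
`p + z + r/k1` obeys
$\mathrm{d}/\mathrm{d}t(p + z + r/k_1) = -k_4qp - k_4sr/k_1 \le 0$ when
`w = 0`, so any equilibrium needs `qp = 0` and `sr = 0`, which cascades to
the trivial state. That state is also non-hyperbolic (the leak is
quadratic), which is why equilibrium scans seed Newton iteration from an
integration-based relaxation *at the first scanned stimulus value* rather
than from the rest state. It also means the published initial-condition
column is *not* an equilibrium of the simplified model — the
corresponding rest-state comparison in the acceptance tests documents
this mismatch rather than hiding it.

**Transient exclusion in the ranking.** The minimum of $\lambda_i$ is
taken over the post-transient window by default
(`speed_transient = transient` in `reduce_iteratively()`). The onset
transient probes a far deeper trough of nuclear NF-κB than the attractor
ever visits; ranking on the full interval drags the nuclear-IκBα speed
minimum below the constant active-IKK rate `k23` and swaps the fifth and
sixth eliminations relative to the attractor's own ordering. The choice
is exposed as an argument (`transient = 0` ranks over everything).

**First-order corrections and the zeroth-order skeleton.** The affine
pair $(\alpha_j, \beta_j)$ and the time derivatives
$\dot\alpha_j, \dot\beta_j$ are always derived from the chain in which
earlier eliminations enter at zeroth order (the "skeleton"), while the
correction refines what is substituted. The difference against expanding
through first-order-corrected expressions is of second asymptotic order,
and the convention keeps later equations affine in their own variable —
with several first-order substitutions in a chain, corrections otherwise
feed back and make a later elimination non-affine. When at most the final
substitution is first-order (the published minimal continuous model),
the convention coincides with the direct derivation, and it reproduces
the published structure of the active-IKK closed form: a rational
function of the A20 transcript plus a correction proportional to the
transcript balance $\mathrm{d}x/\mathrm{d}t$.

**A finding on the all-first-order variant.** Applying first-order
corrections to every eliminated variable (the `z0p1y1v1s1w1` label)
does *not* yield an oscillating model under this derivation: the
nuclear-IκBα correction alone (`s1`) stabilises the equilibrium at the
saturating dose, moving the Hopf point above `k24 = 1`, even though the
corrected substitution tracks the eliminated variable to within 15%
along the parent solution. The correction's denominator $\beta_s^3$
amplifies its feedback in the nuclear-NF-κB troughs where
$\beta_s = k_4 r + k_8 + k_{14}k_1$ is smallest. The published period for
that variant is therefore not reproduced here; the corresponding test is
left failing by design and says so. This mirrors the published
observation that correction-order choices relocate the Hopf point (the
zeroth-order active-IKK model moves it to `k24 ≈ 3.1`).

**Oscillation metrics.** Peaks are strict local maxima filtered by a
prominence of 5% of the post-transient range (robust to the flat troughs
of these relaxation oscillations, where zero-crossing methods misfire),
with quadratic sub-grid refinement of peak times. The period is the mean
peak-to-peak interval; a readout is called oscillatory when at least
three peaks exist and the interval coefficient of variation is below
10%. The waveform (shape) mean squared error extracts one full cycle per
model, rescales it to unit period, aligns at the peak and compares on a
common 1000-point grid, so period differences do not contribute. The
readout defaults to nuclear NF-κB (`r`), the variable whose dynamics the
oscillation literature reports; amplitude is its max − min over the
analysed window. Comparative waveform errors here use the 10-variable
model as baseline (its 14-variable parent is not part of the package),
so they are roughly two orders of magnitude smaller than numbers quoted
against the parent.

**Quasi-steady-state residual.** For every zeroth-order elimination the
package reports `max_t |x_j^1| / max_t |\bar{x}_j^0|` along the reduced
model's own solution — the relative size of the neglected first-order
term, the standard a-posteriori accuracy estimate for a leading-order
asymptotic. Values stay below 0.09 for the first four continuous-protocol
eliminations and reach 0.12 for nuclear IκBα, consistent with that
elimination being the marginal one.

**Symbolic layer.** Expressions are plain R language objects restricted
to rational arithmetic and powers — exactly what mass-action and Hill
kinetics need — differentiated with `stats::D()` and tidied by constant
folding only. Algebraic identity (e.g. "the derived substitution equals
the printed closed form") is decided by evaluation at 24 deterministic
low-discrepancy points with a magnitude-aware tolerance; there is no
symbolic cancellation engine, and "is zero" compares against the size of
the expression's own terms to stay meaningful under floating-point
cancellation. Reduced systems keep three synchronized right-hand-side
forms: flattened (for differentiation), the zeroth-order skeleton (for
decompositions), and the unsubstituted form plus substitution chain,
which the integrator evaluates in reverse elimination order so each
substitution is computed once per step — the difference between seconds
and minutes for deeply reduced models.

**Stiff integration and protocols.** `deSolve::lsoda` with
`rtol = 1e-8`, `atol = 1e-10`; the solver is stopped and restarted at
every pulse edge so each segment is smooth, and halving the tolerances
moves reported periods by less than 0.1%. Piecewise-constant inputs are
treated as constants inside segments (their time derivative does not
enter first-order corrections); substitutions re-evaluate across edges
through the integrator restart.

**Bifurcation analysis.** Equilibria are tracked by damped Newton with
the symbolic Jacobian (residual below 1e-12), continued across a
parameter grid with each solution seeding the next, optionally ramping
the parameter in halved steps when a jump fails. Hopf points are sign
changes of the maximal real eigenvalue part refined by bisection to
1e-4 in the parameter, and are only classified as Hopf when the crossing
pair is complex (|Im| > 1e-6 s⁻¹). Limit cycles are characterised by
direct long integration from a perturbed equilibrium, not collocation —
sufficient here because the documented ranges contain no folds; a
continuation package would be the tool for fold or period-doubling
tracking, which is out of scope.

## What the fixtures do and do not show

The toy fast–slow pair isolates the asymptotic convergence orders under
ideal conditions: linear dynamics, exact slow manifold, no feedback from
the eliminated variable's error. The NF-κB family adds stiff nonlinear
feedback but is still a deterministic, well-mixed, single-compartment
ODE model with published point parameters. Passing tests therefore
demonstrate correctness of the reduction machinery and reproduction of
the published dynamical landmarks; they say nothing about cell-to-cell
variability, stochastic transcription, delays or spatial effects, none
of which the method itself addresses. Two printed-form details are kept
as explicit variants rather than silently corrected: the literal
published active-IKK closed form (`build_minimal_continuous(as_printed =
TRUE)`, whose constants do not match direct derivation) and the pulsed
model's nuclear-IκBα equation
(`build_minimal_pulsed(fix_typo = FALSE)`), so both discrepancies remain
testable.

## Reproducing the study-scale numbers

```{r example}
library(speedred)

sm <- build_sm()
lineage <- reduce_iteratively(sm, protocol_constant("k24", 1),
                              n_steps = 6, order_policy = list(w = 1))
lineage$table

hopf_scan(sm, "k24", c(0.05, 1.2), n_grid = 40)
```

Problem sizes used throughout the package (3000-minute horizons, 40-point
bifurcation grids, 24-point identity samples) keep every documented run
in the seconds-to-a-couple-of-minutes range on one core while leaving
the reported digits stable under refinement.
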