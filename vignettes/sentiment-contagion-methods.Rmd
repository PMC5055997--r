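---
title: "Modelling sentiment contagion with interacting optimists and pessimists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sentiment contagion with interacting optimists and pessimists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sosaspsa)
```

## The model

Sentiment spreading through a crowd behaves much like an infectious process:
people catch moods from the people they meet, and they also develop them
spontaneously. `sosaspsa` implements a three-compartment model of this
process. A closed, well-mixed population of size $N$ is split into
susceptible ($S$), optimistic ($O$) and pessimistic ($P$) individuals.

Each sentiment channel on its own is a SISa process — the
susceptible–infected–susceptible model augmented with spontaneous
("automatic") infection. Susceptibles adopt a sentiment by contact
(transmission rates $\beta_O$, $\beta_P$), or out of nowhere at constant
rates ($\alpha_O$, $\alpha_P$), and sentiment holders relax back to
susceptibility at recovery rates ($g_O$, $g_P$). Stacking the two channels
on a shared susceptible pool gives the two-channel SOSa–SPSa model, in which
optimists and pessimists never meet.

The extension implemented here lets them meet. When an optimist contacts a
pessimist, the optimist either reverts to susceptible (rate $l_1$) or flips
to pessimism (rate $l_2$); symmetrically, a pessimist meeting an optimist
reverts to susceptible (rate $m_1$) or flips to optimism (rate $m_2$). The
outcome budgets are constrained: $l_1 + l_2 \le 1$ and $m_1 + m_2 \le 1$.
With contact factor $c$ the dynamics are

$$
\begin{aligned}
\frac{dS}{dt} &= g_O O + g_P P - (\alpha_O + \alpha_P) S
  - c\,(\beta_O O + \beta_P P)\,S + c\,(l_1 + m_1)\,O P,\\
\frac{dO}{dt} &= -g_O O + \alpha_O S + c\,\beta_O O S
  - c\,(l_1 + l_2 - m_2)\,O P,\\
\frac{dP}{dt} &= -g_P P + \alpha_P S + c\,\beta_P P S
  - c\,(m_1 + m_2 - l_2)\,O P,
\end{aligned}
$$

with $S + O + P = N$ at all times. Note that the deterministic flow feels
the interaction rates only through the two combinations $l_1 + l_2 - m_2$
and $m_1 + m_2 - l_2$; distinct $(l_2, m_2)$ pairs with equal differences
produce identical trajectories, though not identical stochastic event mixes.

### Contact scaling

The bilinear terms can be read two ways. With **frequency-dependent**
transmission ($c = 1/N$) an individual's infection pressure depends on the
*composition* of the crowd; with **density-dependent** transmission
($c = 1$) it depends on absolute counts, and rates like $\beta_O = 0.02$
would imply hundreds of conversions per person per unit time in a crowd of
1880. The baseline rate estimates (drawn from Hill et al.'s 2010 analysis of
Framingham Heart Study sentiment data) are per-contact quantities and
reproduce the expected long-run composition only under frequency scaling,
so `contact_scaling = "frequency"` is the default. The `"density"`
convention is kept available on the parameter object for completeness, since
the bilinear form is often written on raw counts.

### Baseline conditions

The packaged configuration `hill2010_fhs.json` carries the ten baseline
rates ($\alpha_O = 0.18$, $\beta_O = 0.02$, $g_O = 0.088$,
$\alpha_P = 0.04$, $\beta_P = 0.04$, $g_P = 0.13$, $l_1 = 0.13$,
$l_2 = 0.009$, $m_1 = 0.09$, $m_2 = 0.07$) and the canonical initial crowd:
$O = 626$, $P = 626$, $S = 628$, $N = 1880$. Time units are abstract; no
calendar interpretation is attached.

```{r baseline}
fx <- fhs_parameters()
res <- integrate_to_equilibrium(fx$params, fx$initial, fx$N)
round(100 * state_fractions(res$state, fx$N), 2)
```

From an even three-way split, optimism rises, pessimism falls, and the
susceptible pool bulges briefly before draining; the system settles near
64% optimists, 6% pessimists and 30% susceptibles. States are real-valued
throughout the deterministic machinery — the continuum approximation — and
are only integerized in the stochastic simulator.

## Numerical choices

**Integration.** Trajectories use `deSolve`'s `lsoda` with relative
tolerance $10^{-10}$ and absolute tolerance $10^{-12} N$. The system is
small and non-stiff at these parameter scales; the tight tolerances are
chosen so that conservation of $S + O + P$ is a meaningful invariant
(verified to $10^{-8} N$ along every trajectory) rather than an accident of
solver slack. The susceptible derivative is computed as $-(dO/dt + dP/dt)$,
which is algebraically the printed form and closes the population by
construction. Negative overshoot is never clipped silently: components are
allowed a band of $-10^{-9} N$ and anything beyond is a hard failure.

**Equilibrium by integration.** A run is accepted as converged when the
largest derivative component drops below $10^{-10} N$ at the horizon
(default $t = 2000$, one doubling retry). Under the baseline conditions the
flow reaches that criterion well before $t = 2000$.

**Equilibrium by root finding.** `find_equilibrium()` works in the reduced
$(O, P)$ space with $S = N - O - P$ substituted, so conservation is exact by
construction and the Jacobian is $2 \times 2$. A Broyden-type solve
(`pracma::fsolve`) is followed by Newton polishing with the analytic
Jacobian until the residual meets tolerance; roots with materially negative
components are rejected with a diagnostic rather than repaired. At an
interior equilibrium the two channels must price the susceptible pool
identically,

$$
\frac{g_P P + c\,O P (m_1 + m_2 - l_2)}{\alpha_P + c\,\beta_P P}
= \frac{g_O O + c\,O P (l_1 + l_2 - m_2)}{\alpha_O + c\,\beta_O O} = S,
$$

and `eq2_residual()` reports the mismatch of that identity (defined only
when both denominators are nonzero). The identity residual at any converged
root sits at the $10^{-12}$ level; the two independent routes — long-run
integration and algebraic solving — agree on the baseline to better than
$10^{-10} N$.

**Stability.** A full analytic stability treatment of the twelve-parameter
system is out of scope; `assess_stability()` instead evaluates the reduced
Jacobian by central finite differences (step $10^{-6} N$), checked in the
test suite against the hand-derived analytic Jacobian, and flags an
equilibrium stable when both eigenvalue real parts are negative. The
baseline equilibrium is stable, with real negative eigenvalues. A
multi-start helper probes the simplex from a grid of 16 starting
compositions and deduplicates roots closer than $10^{-6} N$; it probes, but
cannot prove, that the attractor is unique.

## The stochastic counterpart

`gillespie_run()` is an exact event-driven realisation of the same
transition scheme on an integer population: the ten propensities are the
ten right-hand-side terms evaluated at the current state (frequency
scaling), waiting times are exponential in the total propensity, and the
direct method picks one transition per event, with ties on the cumulative
bounds resolved to the lower-indexed event. Every event moves exactly one
individual, so conservation is integer-exact. Ensembles derive run $i$'s
seed as `seed + i`, making the whole ensemble reproducible from one
integer. Rescaling the canonical initial state to another $N$ uses
proportional scaling with largest-remainder rounding so the total is
preserved exactly.

The stochastic model serves as an independent oracle for the deterministic
one: at $N = 10^4$ a 200-run ensemble mean stays within three standard
errors of the ODE solution at every saved time point over the transient
window $t \in [0, 40]$ (the window in which the flow does essentially all
of its travelling), and the pure-recovery special case reproduces the
closed-form decay $N e^{-g t}$. Exact simulation is entirely adequate at
these population sizes; no tau-leaping or hybrid acceleration is provided.

## Parameter-response experiments

Three sweep experiments map how the equilibrium composition responds to the
rates that matter most for the pessimist compartment. Each grid point is an
independent equilibrium solve, warm-started from its neighbour for
continuity, and every stored cell is reproducible by calling
`find_equilibrium()` directly.

- **`sweep_gP()`** (default grid $0.05$ to $0.50$ by $0.05$, bracketing the
  baseline $0.13$): the equilibrium pessimist share falls monotonically as
  pessimist recovery speeds up, with shrinking decrements — recovery is a
  strong but saturating lever.
- **`sweep_l2_vs_l1()`** (default $l_2$ from $0$ to $0.3$ by $0.03$): the
  pessimist share rises monotonically in $l_2$. When conversion dominates
  reversion ($l_2 > l_1$) pessimism is self-reinforcing, and the share
  exceeds that of the mirrored configuration with the two rates swapped.
- **`sweep_alphaP_by_lm()`** (default $\alpha_P \in \{0.01, 0.04, 0.07,
  0.1\}$): the pessimist share is nondecreasing in spontaneous pessimism
  and saturates — the increment from $\alpha_P = 0.07$ to $0.1$ is smaller
  than from $0.01$ to $0.04$.

The $(l_2, m_2)$ pairs crossed with the $\alpha_P$ grid are a genuinely
open design choice: no canonical pair values exist for this experiment, and
because the deterministic flow sees only $l_2 - m_2$ differences,
near-symmetric pairs make the $\alpha_P$ response almost exactly linear.
The defaults — $(0.009, 0.07)$, $(0.15, 0.07)$, $(0.2, 0.05)$ — therefore
run from the baseline pair into the conversion-dominant regime, where the
self-reinforcing interaction makes the saturation pronounced. The grids are
chosen to bracket the baseline values, not to reproduce any particular
published curve.

## What the generator emulates, and what it does not

The study conditions are fully synthetic in the sense that no external data
enter anywhere: the baseline rate set and initial split *are* the
conditions, shipped as a fixture, and all other inputs are generated in
code. The model assumes a closed, homogeneous, well-mixed crowd of
indistinguishable individuals: no contact network, no household or
community structure, no heterogeneity in susceptibility, no leaders,
rescuers or media influence, and no time-varying rates. Passing tests
therefore demonstrate internal consistency of the mean-field model and its
stochastic counterpart under these idealisations — not that real crowds
follow these curves. Parameter estimation from longitudinal cohort data is
likewise out of scope; the baseline rates are taken as given.

One modelling asymmetry is worth stating explicitly: the transition
structure contains no route by which susceptibles become optimistic through
contact with pessimists. Narratively such a "small possibility" is
sometimes entertained; the flow implemented here follows the differential
equations, which carry no such term.

## Known limitations

- Stability is assessed numerically at solved equilibria; no global or
  analytic stability result is claimed, and the multi-start probe cannot
  rule out additional roots outside its grid.
- The deterministic identifiability caveat above: $(l_2, m_2)$ pairs with
  equal differences are indistinguishable from trajectories alone.
- Rate-parameter validation enforces nonnegativity and the two probability
  budgets, but rates well above 1 per unit time, while admissible, strain
  the per-contact interpretation.
- The test suite exercises problem sizes chosen for a desk-scale machine:
  ensembles of 200 runs at $N = 10^4$ and 1000 runs at $N = 500$, and
  50-point random-parameter sweeps; these sizes are stated in the tests and
  can be scaled up freely.
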