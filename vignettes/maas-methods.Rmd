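---
title: "Attention-switching choice models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-switching choice models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maas)
```

## The model

`maas` models a binary decision between alternatives A and B whose options
carry several attributes.  Evidence is accumulated by a single process
$X(t)$, but its dynamics change as attention moves between attributes:
while attribute $k$ is attended,

$$dX(t) = (\delta_k - \gamma_k X(t))\,dt + \sigma\,dW(t),$$

an Ornstein–Uhlenbeck process with attribute-specific drift $\delta_k$
(positive values favour A) and decay $\gamma_k$; $\gamma_k = 0$ recovers a
Wiener process with drift, so everything below applies to drift-diffusion
models unchanged.  The decision falls the first time $X$ reaches
$+\theta_A$ (choose A) or $-\theta_B$ (choose B).  If the available time
runs out first, no decision is made; the model therefore predicts a triple
$(p_A, p_B, p_0)$ together with mean decision times $ET_A$, $ET_B$
conditional on each choice.  No non-decision (encoding/motor) component is
added: the outputs are decision times only, and users who need response
times must add their own residual-time model on top.

Attention follows a *time-and-order schedule* of $L$ stages.  The attribute
order can be fixed or generated by a Markov chain with switching matrices
$D^{(l)}$ (entry $(k', k)$: probability that the $l$-th switch goes from
attribute $k'$ to $k$; diagonals should be zero, since staying put is not a
switch — `validate_schedule()` warns otherwise).  Stage durations, measured
in chain steps, can be fixed integers or draws from a discrete
attention-time distribution, independent across stages.  The final stage
may instead be open-ended (`horizon = "infinite"`), in which case $p_0 = 0$.

## Discretization

The continuous process is approximated by an absorbing birth–death chain on
the grid $-m_B\Delta, \ldots, m_A\Delta$ with $\Delta = \sigma\sqrt{\tau}$
for time step $\tau$.  This square-root coupling keeps the per-step
variance at $\sigma^2\tau$, which is what makes the chain converge to the
diffusion as $\tau \to 0$; the test suite checks the constant-drift
absorption probability against the continuous two-boundary formula at
$\tau = 1/64$ (relative error under 1%).  From an interior state $x$ the
chain moves one step up with probability
$\tfrac12\bigl(1 + (\delta_k - \gamma_k x)\sqrt{\tau}/\sigma\bigr)$, one
step down otherwise — a pure birth–death chain with no staying
probability.

Two practical consequences:

* **Stability.**  The up-probability must stay in $[0,1]$, i.e.
  $|\delta_k - \gamma_k x|\sqrt{\tau}/\sigma \le 1$ at every interior
  state.  Violations are an *error*, never a silent clip: clipping would
  quietly change the approximated process.  Decrease $\tau$ or the
  drift/decay magnitudes to restore stability.
* **Thresholds off the grid** are rounded to the nearest grid index with a
  warning reporting the effective thresholds $m_A\Delta$, $-m_B\Delta$
  actually used.

The default configuration throughout the documentation and tests is
$\theta_A = \theta_B = 10$, $\sigma = 1$, $\tau = 1/16$, giving
$\Delta = 1/4$ and an 81-state space, with the process started as a point
mass at evidence 0 (biased starts are supported through
`initial_state()`).  This resolution is fine enough that discretization
error is far below the behavioural effects under study, while every solve
in the package completes in well under a second.

## Attention-time distributions

Stage durations live on the positive integers $\{1, 2, \ldots\}$ — a
zero-length attention episode is meaningless.  Five families are provided
(`attention_time()`): deterministic $n_0$; geometric
$P(T = n) = (1-r)^{n-1}r$ (mean $1/r$, variance $(1-r)/r^2$) — the
memoryless, highest-variance case; uniform on $\{N-M, \ldots, N+M\}$
(mean $N$, variance $M(M+1)/3$), which interpolates between the
deterministic and high-variance regimes as $M$ grows; and Poisson and
binomial counts *shifted up by one step* so their support starts at 1
(means $\lambda + 1$ and $np + 1$).  The shift is a deliberate convention:
it avoids zero-duration stages while preserving the ability to match means
across families, which is how the sweep code parameterizes them
(`mean =` gives $n_0 = \text{mean}$, $r = 1/\text{mean}$,
$\lambda = \text{mean} - 1$, and for the binomial $p = 1/2$,
$n = 2(\text{mean} - 1)$).  At a matched mean of 300 steps the variances
order geometric (89,700) > uniform $M = N{-}1$ (29,900) > uniform
$M = N/2$ (7,550) > Poisson (299) > binomial (149.5), which is the lever
behind the variance-effect results below.

## Exact solution

For a *fixed* schedule, `solve_deterministic()` advances the defective
(sub-probability) state distribution step by step, accumulating the mass
absorbed at each boundary and, weighted by the global step index, the
response-time sums; conditional means are $ET_X = \tau\,et_X/p_X$
(reported `NA` when $p_X = 0$, not 0).  An open-ended final stage uses
linear solves against the fundamental matrix,
$V = (I-Q)^{-1}R$ and $W = (I-Q)^{-2}R$, instead of stepping.

For *random* schedules, `schedule_operators()` precomputes per attribute
the episode operators

$$V_k = \Bigl[\sum_{i\ge 0}(1-f_i)Q_k^i\Bigr]R_k,\quad
  W_k = \Bigl[\sum_{i\ge 0}(1-f_i)(i{+}1)Q_k^i\Bigr]R_k,\quad
  B_k = \sum_{n\ge 1}p_nQ_k^n,\quad
  C_k = \sum_{n\ge 1}p_n n Q_k^n,$$

and `solve_random()` folds them backwards through the schedule:

$$G_l(k') = V_{k'} + B_{k'}\sum_k d^{(l)}_{k'k} G_{l+1}(k), \qquad
  H_l(k') = W_{k'} + C_{k'}\sum_k d^{(l)}_{k'k} G_{l+1}(k)
            + B_{k'}\sum_k d^{(l)}_{k'k} H_{l+1}(k),$$

with $G_L = V$, $H_L = W$.  Then $Z'G_1(k_1)$ and $Z'H_1(k_1)$ give the
choice probabilities and time sums per initial attribute.  The nesting
matters: a flat product of per-stage factors
$(\mathbf I + \mathbf B D^{(1)})\cdots(\mathbf I + \mathbf B D^{(L-1)})$
over-counts, because its expansion contains cross terms (such as
$\mathbf B D^{(2)} \mathbf V$ with no stage-1 survival factor) that
correspond to no realizable path; the nested recursion is the correct
law-of-total-probability expansion, and the test suite pins it against
exhaustive trajectory enumeration on small chains and against the
stage-stepping solver on fixed schedules (agreement to $10^{-12}$).

$p_0$ is computed as $1 - p_A - p_B$, which is exact for the finite
horizon; for infinite horizons it is zero up to the series truncation
tolerance.

### Numerical evaluation of the operators

* The four series are accumulated **jointly**, with a single matrix
  product per term ($X \leftarrow XQ$); high powers of $Q$ are never
  formed by repeated squaring, and the cost is one $(m{-}2)^2$
  matrix-matrix multiply per retained term.
* Series are truncated at `at_truncation_bound(dist, tol)`, the smallest
  $N$ with $1 - F(N) \le$ `tol`; the default `tol = 1e-12` keeps
  truncation error orders of magnitude below every tolerance asserted in
  the tests, at negligible cost for the distributions used here.
* For the geometric distribution the series have closed forms —
  $V = (I-(1-r)Q)^{-1}R$, $W = (I-(1-r)Q)^{-2}R$, $B = rQ(I-(1-r)Q)^{-1}$,
  $C = rQ(I-(1-r)Q)^{-2}$ — evaluated by linear solves (`method = "auto"`
  dispatches there; `method = "series"` remains available and the two
  routes agree to $10^{-10}$ in the tests, which is the practical check
  on both).
* Operators are cached per (attribute, distribution) pair within a solve;
  per-stage overrides (`stage_overrides`) force recomputation for that
  stage only.
* Fixed integer durations inside `solve_random()` are treated as
  point-mass attention times, which is what makes the random-schedule
  solver reduce *exactly* to the deterministic one — a reduction asserted
  at $10^{-12}$ across all standard configurations.

## Units and the sweep axis

All durations inside the engine are chain steps; one step is $\tau$ time
units.  `run_sweep()` sweeps the *expected* attention time and accepts the
grid either in steps (`grid_units = "steps"`, the default, matching the
distributions' own parameterization) or in time units
(`grid_units = "time"`, converted by $\tau$) — the latter is the natural
axis when plotting against physical time, and some qualitative effects are
only visible on it: with $\tau = 1/16$, a grid of 10–500 *time units*
spans 160–8000 steps, an order of magnitude beyond the same numbers read
as steps.  The preference-reversal demonstration below is a case in point.

## What the numerical experiments show

With the standard 81-state configuration the package reproduces the
model's characteristic predictions, each of which is asserted in the test
suite:

* **Variance effect.**  At matched mean attention time, kinds with small
  variance (Poisson, binomial) are numerically indistinguishable from
  deterministic timing (differences in $p_A$ below $10^{-3}$), the
  geometric kind differs most, and the uniform kinds sit in between,
  moving from the deterministic toward the geometric end as $M$ grows.
  Small timing uncertainty therefore does not affect observable choice
  frequencies; large (memoryless) uncertainty does.  Note the uniform
  with $M = N{-}1$ genuinely belongs to the *intermediate* group: at mean
  300 steps its $p_A$ deviates from deterministic timing by up to about
  0.012 depending on the configuration, an order of magnitude more than
  Poisson/binomial.
* **Preference reversal.**  With a B-favouring attribute ($\delta_1 =
  -0.1$) attended first and a strongly A-favouring one ($\delta_2 = 0.2$,
  $\gamma_2 = 0.03$) attended indefinitely after, $p_A$ falls
  monotonically in the first stage's duration and crosses $0.5$ near
  $t_1 \approx 65$ time units: which alternative is favoured flips with
  attention allocation alone.
* **Fast errors.**  When the evidence for A strengthens across the
  attended sequence ($0 < \delta_1 < \delta_2$), A is the more frequent
  *and slower* choice ($ET_B < ET_A$) — fast errors; with the order
  reversed, the frequent choice is also the fast one.  Both patterns hold
  across the sweep grid for deterministic and geometric timing alike.

## The Monte Carlo simulator

`simulate_trials()` simulates the *discrete chain itself*, not a separate
discretization of the stochastic differential equation, so solver and
simulator target the identical process and their agreement (within
binomial/sample standard errors) is a genuine cross-validation of the
matrix algebra.  Per trial the realized schedule is drawn first (order,
then durations), then the walk is stepped; all draws come from R's RNG in
a documented order, so `seed` fixes the full result bit-for-bit.  The
stepping loop is compiled (Rcpp): $2\times 10^5$ trials of the standard
two-stage configurations run in roughly ten seconds.  Open-ended final
stages carry a $10^7$-step safety cap per trial; capped trials are scored
as no-decision and reported via `truncated` with a warning (none occur in
the configurations shipped with the package).  The test suite runs the
solver-vs-simulator comparison at $2\times 10^5$ trials per
configuration, where the standard errors are small enough (about $10^{-3}$
on probabilities) to detect real discrepancies while keeping the full
suite around a minute.

The simulator is also the package's synthetic-data source.  What it
emulates is exactly the model's own data-generating process — schedules,
attention times, and the birth–death walk.  What it does *not* emulate is
everything a real data set adds on top: non-decision time, trial-to-trial
parameter drift, lapses, and recording noise.  Agreement between solver
and simulator therefore validates the implementation, not the model's fit
to any empirical data; fitting is out of scope altogether.

## Limitations

* Mean response times only; full RT distributions are available from the
  simulator's samples but not analytically.
* The stage count $L$ is always finite and explicit; closed-form
  $L \to \infty$ solutions are not provided.
* Attention times are independent across stages and keyed by attribute
  (with per-stage overrides); trajectory-dependent switching is out of
  scope.
* One discretization is shared by all attributes; per-attribute $\sigma_k$
  is accepted in the dynamics, but the grid spacing uses the shared
  $\sigma$ supplied to `build_discretization()`.
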