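---
title: "Methods: logit dynamics, cluster variation, and transition analysis for the composite Ising+Potts game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logit dynamics, cluster variation, and transition analysis for the composite Ising+Potts game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticegame)
```

## The model

`latticegame` simulates and solves multi-strategy coordination games on the
`L x L` periodic square lattice. One player sits at every site, plays the
same two-player matrix game against its four nearest neighbors, and collects
the income

$$\tilde u_x(s_x) = \sum_{\delta} s_x \cdot A\, s_{x+\delta},$$

where $A$ is the $n \times n$ payoff matrix and $s_x$ the (unit-vector
encoded) strategy at site $x$. The canonical game, built by
`ising_potts_game(alpha)`, is a five-strategy *pure coordination-type* game
(every row and column of $A$ sums to zero) that couples two independent
subgames: strategies 1–2 form an Ising pair with unit coordination payoff,
and strategies 3–5 form a three-state Potts triple whose strength is the
single parameter $\alpha \ge 0$ — diagonal $\alpha$, off-diagonal
$-\alpha/2$, and zero payoff between the two families. Because $A$ is
symmetric the game is a potential game with potential matrix $V = A$, and a
whole strategy configuration $s$ has the configuration potential

$$U(s) = \tfrac12 \sum_{x,\delta} s_x \cdot V s_{x+\delta},$$

a sum of pair potentials over the $2N$ lattice edges. One immediate exact
identity, used as an invariant throughout the test suite: since every edge
pays both of its endpoints but enters $U$ once, the average payoff per
player equals exactly twice the average potential per player, for *any*
configuration.

Strategy revision follows the logit (Glauber heat-bath) rule: a randomly
chosen player replaces its strategy by $s'$ with probability proportional to
$\exp(\tilde u_x(s')/K)$, the current strategy competing in the
normalization. $K > 0$ is the noise level and plays the role of temperature.
For potential games this rule satisfies detailed balance with respect to the
Boltzmann distribution $p(s) \propto e^{U(s)/K}$, which is what lets the
machinery of equilibrium statistical physics — phase transitions, critical
exponents, free-energy comparisons — be applied verbatim. `mc_step()`
performs $N$ single-site updates at independently drawn sites per Monte
Carlo step (MCS), so every player revises once on average per MCS;
random-site updating (rather than sweeping) is used because sequential
sweeps bias the dynamics. `detailed_balance_check()` verifies the balance
identity flip by flip, and `boltzmann_exact()` provides the brute-force
stationary distribution on lattices tiny enough to enumerate (guarded at
$10^7$ configurations), which is the oracle the Monte Carlo engine is tested
against.

Low-noise behavior: the five ordered phases (two Ising, three Potts) are
degenerate in payoff at $\alpha = 1$. The package's central scientific
content is how that degeneracy is resolved — by entropy. The Ising phase
keeps its four minority strategies in a 3 (neutral Potts defects) + 1
(opposing Ising strategy, payoff $-4$) structure, while the Potts phase
splits them 2 + 2; the Ising phase is therefore less ordered, has higher
entropy at equal $K$, and its thermodynamic potential $\Phi = U + KS$
overtakes the Potts phase even when $\alpha$ slightly exceeds 1 — a social
dilemma in which the population settles in the *lower-payoff* phase.

## Cluster-variation solvers

Two truncations of $\Phi$ are implemented.

**Mean field (one-site).** `mf_phi()` evaluates
$\Phi^{(1)}/N = 2\rho^\top A \rho + K S(\rho)$ with
$S = -\sum_i \rho_i \ln \rho_i$. Stationarity on the simplex is equivalent
to the self-consistency map $\rho_i \propto \exp(4 (A\rho)_i / K)$ (the
coefficient is the lattice coordination number $z = 4$; the module accepts
general even $z$). `mf_stationary()` iterates this map, damped by 0.5, from
a standard start set — each near-pure vertex, the barycenter, and mixed
Ising/Potts starts — to residual $10^{-12}$, deduplicates, and classifies
stability by the projected Hessian $zA - K\,\mathrm{diag}(1/\rho)$ on the
simplex tangent space (negative definite = locally stable = attracting for
the map). The barycenter is always a stationary point; it is unstable at low
noise and becomes the unique stable state at high noise.

The map was chosen over generic constrained optimization because it
preserves the simplex exactly, converges linearly away from criticality,
and its Jacobian delivers the stability classification for free. Branches
are tracked in $K$ by continuation (each solution seeds the next $K$), which
keeps metastable branches alive past the free-energy crossing — necessary
for locating first-order transitions. `mf_branch_endpoint()` bisects on
branch existence; for the composite game at any $\alpha$ the Ising branch
reduces on its symmetric subspace to
$m = 2\sinh(4m/K) / (2\cosh(4m/K) + 3)$, whose nontrivial solution
disappears continuously at $K = 8/5$ — the solver recovers this numerically
rather than assuming it. The two-strategy reduction likewise satisfies
$m = \tanh(4m/K)$, ordered below $K = 4$, which the unit tests check to
$10^{-10}$.

`mf_potts_ising_crossing()` locates the first-order Potts–Ising transition
as the $K$ where the two branches' $\Phi$ values cross (coarse scan, then
bisection to $10^{-4}$; $\Phi$ differences below $10^{-10}$ are treated as
ties, since at $\alpha = 1$ the low-$K$ gap decays like $e^{-c/K}$ and falls
below solver resolution). The $\Phi$ gap decreases monotonically up to the
Ising endpoint, where the Ising branch merges into the disordered state;
`mf_alpha_c()` exploits this and bisects on the sign of
$\Phi_{\rm Potts}(K_I) - K_I \ln 5$, the gap at the endpoint, to find the
$\alpha$ at which the stable Ising window closes. The mean-field Potts
branch carries a first-order discontinuity in $\rho(K)$ that neither the
pair approximation nor the simulation shows; a regression test asserts the
discontinuity exists, since it is a known qualitative artifact of the
one-site truncation.

**Pair approximation (two-site).** `pair_phi()` evaluates the Bethe form
$\Phi^{(2)}/N = 2\sum p_2 A - 2K \sum p_2 \ln p_2 + 3K \sum p_1 \ln p_1$
with the marginal $p_1$ given by the compatibility conditions
$p_1(i) = \sum_j p_2(i,j)$. For an independent $p_2 = p_1 \otimes p_1$ this
collapses exactly to $\Phi^{(1)}$ (Bethe entropy identity — a unit test).
Rather than solving the constrained stationarity system directly, the
package integrates the *dynamical* pair-approximation equations of motion,
which give much easier access to metastable branches: a focal site in
strategy $i$ sees four neighbors drawn independently from the conditional
$p_2(\cdot|i)$, flips to $k$ with the logit probability of that
neighborhood, and each flip rewrites the focal site's four edges. Summing
over all $n^4$ neighbor configurations gives a closed flow
$\dot p_2 = (G + G^\top)/4 - 2 p_2$ that conserves symmetry and
normalization identically. Integration is explicit Euler with an adaptive
step (start 0.2, halved whenever a probability would leave $[0,1]$,
regrown 5% per accepted step, capped at 0.4) to residual
$\max |\dot p_2| < 10^{-10}$.

Two consistency checks connect the dynamical and variational routes: every
converged fixed point is verified to make the constrained $\Phi^{(2)}$
gradient constant on its support (residual below $10^{-8}$), and dynamical
stability is classified from the numerically estimated Jacobian of the flow
on the symmetric, normalization-preserving tangent space. The two-strategy
reduction orders below $K = 2/\ln 2 \approx 2.885$, the classical Bethe
value for $z = 4$, which the acceptance suite recovers by bisection to
$\pm 0.005$. For the composite game the pair approximation reproduces the
qualitative corrections the simulation shows and mean field misses: a
correlated disordered state in which the Ising strategies are slightly more
frequent than the Potts strategies (with the Potts share of that branch
dying out as $K \to 0$), and a far more accurate first-order point —
$K_{PI}(\alpha = 1.01) \approx 0.971$ against the simulation's
$0.970$, versus mean field's $1.03$.

## Transition analysis

**Order parameters.** For the composite game, `order_parameters()` returns
the Ising magnetization $\rho_1 - \rho_2$ and the Potts order parameter
$\rho_3 - (\rho_4 + \rho_5)/2$, after relabeling each run so the dominant
Ising strategy is 1 and the dominant Potts strategy is 3 (the ground states
are degenerate, so labels are a per-run convention, applied post hoc by
`relabel_frequencies()`).

**Continuous transitions.** `fit_power_law()` fits
$m(K) = B\,((K_c - K)/K_c)^\beta$ jointly in $(K_c, \beta, B)$ with
`minpack.lm`, because the reported quantities of interest carry
uncertainties in both $K_c$ and $\beta$. The fit window policy — the open
methodological choice here — starts from the points closest to the
transition and widens outward while the residual standard error stays
within 1.5 times the best value seen; uncertainties come from a
200-resample residual bootstrap. The suite validates the fitter three ways:
parameter recovery on its own model across
$\beta \in \{1/8, 1/9, 0.075\}$, a fit to the exact closed-form
square-lattice magnetization curve (`onsager_magnetization()`) recovering
$\beta = 1/8 \pm 0.005$, and a scaled-down lattice run (below).

**Binder cumulants.** `binder_cumulant()` computes
$U_L = 1 - \langle m^4\rangle / 3\langle m^2\rangle^2$;
`binder_crossing()` locates the crossing of two sizes from the pointwise
difference curve using isotonic regression, because the difference is
monotone in $K$ up to Monte Carlo noise but its shape varies drastically —
nearly linear for the Ising restriction, strongly kinked for the
three-state Potts restriction, where polynomial smoothing was found to bias
the crossing left by roughly 0.02. With $L \in \{16, 32\}$ and
$4\times10^4$–$10^5$ samples per point this resolves the two exactly known
restrictions, $K_c = 2/\ln(1+\sqrt2) \approx 2.269$ (Ising pair) and
$K_c = (3/2)/\ln(1+\sqrt3) \approx 1.4925$ (Potts triple at $\alpha = 1$;
the coupling $3/2$ is the diagonal-minus-off-diagonal gap of the zero-sum
Potts block), to about $\pm 0.01$.

**First-order transition.** `locate_first_order_mc()` bisects on the noise
level at which the winner of the ordered-phase domain competition switches
from Potts to Ising, with a majority vote over seeded replicates. A run
counts as conquered when one family holds over 75% of the lattice, its
leading strategy over 55%, and no opposing strategy over 10%. These
thresholds are set by the equilibrium structure of the phases themselves:
near $K = 1$ the Ising phase keeps only ~83% aggregate share (its three
Potts minorities sit near 5% each), so near-unanimity criteria never
trigger, while a single opposing strategy above 10% signals a surviving
macroscopic domain — a still-contested lattice — rather than equilibrium
point defects.

Two initial conditions are available, and the choice matters at desk scale.
From a *random* initial state the early dynamics generically feeds the
entropy-rich Ising pair on both sides of the transition, and on a
$128 \times 128$ lattice that kinetic head start lets an Ising domain
percolate before the Potts payoff advantage ($1\%$ at $\alpha = 1.01$) can
assert itself: measured winner votes stay Ising-majority down to
$K \approx 0.92$, several percent below the thermodynamic transition. The
published protocol overcomes this with lattices of linear size 1600–3000,
which is beyond a desk run. The default here is therefore a prepared
two-domain *slab* state (half Ising-ordered, half Potts-ordered): the
invasion direction of a macroscopic interface — the same growth-and-
shrinking mechanism that decides the random-init competition at large sizes
— determines the winner without any nucleation stage. At $L = 128$ the slab
switch point lands near $K \approx 0.956(9)$ — within about 1.5% of the
large-lattice value $0.970$ that the pair approximation of this same model
also gives ($0.971$), but still visibly shifted: even the interface route
carries a residual finite-size bias toward the Ising side (Ising still
invades at $K = 0.965$ at $L = 128$ and $192$), far smaller than the
several-percent bias of the random-init route yet not negligible at the
$\pm 0.01$ level. Sharpening the last digit genuinely needs the published
lattice sizes. Undecided slab replicates (interfaces that
have not finished crossing within the step budget) vote by their final
family share, which is meaningful precisely because the slab starts at a
50/50 split. The random-init route remains available (`init = "random"`)
with its bias documented.

**Entropy diagnostics.** `entropy_payoff_curves()` prepares each ordered
phase, measures stationary frequencies, and reports the per-player payoff
alongside $K\,S$ with the one-site entropy formula
$S = -\sum_i \rho_i \ln \rho_i$ applied to the measured frequencies. Runs
that escape their metastable basin (the prepared family loses its aggregate
majority or its leader) are flagged and excluded from comparisons.

## Problem sizes and what the tests show

The test and acceptance runs use deliberately modest sizes chosen as the
package's desk-scale defaults: exact-enumeration comparisons on
$3 \times 3$ lattices ($2^9$ and $3^9$ states), Binder crossings at
$L \in \{16, 32\}$, first-order location and the scaled-down exponent fit
at $L = 128$ with $10^3$–$10^5$ MCS. At these sizes the order-disorder
exponent fit lands within $\pm 0.03$ of the Ising value $1/8$ and $K_c$
within $\pm 0.01$ of 1.0666; the published multi-digit exponent estimates
($\beta_I = 0.135(10)$ at $K_c = 1.06665(10)$, and the Potts-side values)
required $L = 400$–$3000$ and up to $10^6$ MCS and are explicitly outside
desk scale — the package computes the same estimators, so those runs are a
matter of budget, not code.

What passing tests do *not* show: real noisy social or biological systems
are not square lattices with homogeneous degree; the logit-Boltzmann
correspondence breaks on non-potential (asymmetric) games, which the
simulator accepts but the thermodynamic solvers deliberately refuse; and
the pair-approximation equations of motion are one standard closure —
variants differing in side-edge bookkeeping exist, which is why the pair
module's acceptance rests on property-based checks (conservation,
$\Phi^{(2)}$-stationarity of fixed points, the Bethe limit) plus agreement
with the simulation's branch structure rather than on digit-matching any
single published curve.

## Numerical choices worth knowing

- Logit probabilities are computed with max-shifted exponentials; $K$ as
  small as $10^{-3}$ cannot overflow. Below $K \approx 0.05$ mixing is so
  slow that prepared ordered initial states (`uniform:i`) are recommended.
- The Monte Carlo inner loop tabulates the cumulative logit distribution
  over all $n^4$ neighbor configurations once per $(A, K)$, making a site
  update one table gather plus one uniform draw; for $n$ beyond table range
  it falls back to on-the-fly evaluation.
- Reproducibility runs through R's own RNG (`set.seed()`; the C++ kernel
  draws from the same stream). Replicate seeds inside
  `locate_first_order_mc()` are derived deterministically from the master
  seed, the noise level, and the replicate index.
- All probability-vector invariants (simplex membership, $p_2$ symmetry and
  normalization) are enforced to $10^{-12}$–$10^{-14}$ per step, not merely
  at the end.
- Near-degenerate stability eigenvalues (within $10^{-8}$ of zero) are
  reported as `"marginal"` rather than silently classified.
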