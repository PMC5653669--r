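---
title: "Multi-ensemble Markov models: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-ensemble Markov models: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical model, the
choices made where the design was genuinely open, and what a green test
does and does not establish. Every empirical number quoted here is computed
by the test suite or the README example; nothing is asserted that the code
does not itself reproduce.

## 1. The estimation problem

Simulation data for a tightly binding protein–ligand system come in two
statistically different flavors:

* **time-correlated data** — unbiased trajectories, typically too short to
  sample unbinding, but carrying genuine kinetic information through their
  lag-$\tau$ transition counts $c_{ij}^k$;
* **equilibrium data** — Hamiltonian replica-exchange samples at several
  bias strengths. Rapid exchanges destroy contiguous-time kinetics, but
  after an equilibration discard each replica may be treated as drawn from
  its ensemble's equilibrium distribution.

Every configuration $x$ carries unit-less bias energies
$b^k(x) = (U^k(x) - U^0(x))/k_BT$ in all $K$ ensembles ($b^0 \equiv 0$).
The joint maximum-likelihood problem is

$$L \;=\; \underbrace{\prod_{k,i,j}\big(p_{ij}^k\big)^{c_{ij}^k}
\prod_{x \in X^k_{\mathrm{time}} \cap S_i} \mu(x)\, e^{f_i^k - b^k(x)}}_{\text{transition-based part}}
\;\times\;
\underbrace{\prod_k \prod_{x \in X^k_{\mathrm{eq}}} \mu(x)\, e^{f^k - b^k(x)}}_{\text{equilibrium part}}$$

over point weights $\mu(x) \ge 0$, joint state–ensemble free energies
$f_i^k$ and per-ensemble transition matrices $p^k$, subject to

* $p^k$ row-stochastic and reversible w.r.t. $e^{-f_i^k}$ (detailed
  balance),
* local normalization $\sum_{x \in S_i} \mu(x)\, e^{f_i^k - b^k(x)} = 1$
  for every sampled $(i,k)$,
* the coupling $e^{-f^k} = \sum_i e^{-f_i^k}$, which ties the equilibrium
  part to the state-resolved free energies.

With an empty equilibrium set the problem is exactly the transition-based
reweighting (TRAM) problem; with no transition data it collapses to MBAR.
Both limits are verified to $10^{-8}$ in the acceptance suite.

**Solver.** The stationarity conditions of the Lagrangian give a
self-consistent fixed point, iterated in log space: one pass of the
row-normalization multipliers $\nu_i^k$, normalization multipliers
$\gamma_i^k = R_i^k + M^k e^{f^k - f_i^k}$ (where $R_i^k$ collects count and
sample terms and $M^k$ is the equilibrium sample count of ensemble $k$),
then $\mu(x) = 1/\sum_k \gamma_{s(x)}^k e^{f_{s(x)}^k - b^k(x)}$ and
$e^{-f_i^k} = \sum_{x\in S_i} \mu(x) e^{-b^k(x)}$. The gauge is fixed each
iteration to $f^0 = 0$, which simultaneously normalizes
$\sum_x \mu(x) = 1$. Because the equilibrium-data multiplier term
$M^k e^{f^k - f_i^k}$ follows from the same Lagrangian, no separate update
schedule is needed; equilibrium samples also enter the per-state sums (see
§5 on the aggregation flag).

**Convergence** is declared when the sup-norm change of all $f_i^k$ falls
below `tol` (default $10^{-10}$) *and* the log-likelihood is stable to
$10^{-8}$; `max_iter` defaults to $10^5$. Workbench fits use `tol = 1e-6`,
which changes the benchmark observables by far less than their statistical
error. The optional fixed-point acceleration mentioned in early designs was
not needed and is not implemented; the plain iteration converges in a few
hundred iterations on all shipped problems.

**The likelihood trace.** The objective is evaluated at an exactly feasible
point each iteration: the per-state normalization holds by construction of
the $f$ update, and the transition part is evaluated at the
Metropolis projection of the current estimate against $e^{-f}$, which is
reversible and row-stochastic at every iterate and coincides with the raw
estimate at convergence. The fixed point is not formally an ascent method:
on adversarial count patterns without self-transitions a transient dip of
order $10^{-2}$ can occur before convergence (it does not affect the
converged optimum, which the probe oracle checks). On chain-sampled data
the trace is non-decreasing to evaluation precision, and the tests assert
this with a slack of $10^{-9}$ relative to the likelihood magnitude.

**Numerics.** All reductions are log-sum-exp; bias energies up to several
hundred $k_BT$ are safe (tested at 500). States with counts in some
ensembles only get transition matrices on their sampled subsets; rows of
ensembles without counts are `NA` by design.

## 2. The benchmark landscape (what the generator emulates)

The 2D landscape emulates the statistical structure of a long
protein–peptide binding data set at desk scale: a deep bound well
(11.5 $k_BT$, $\sigma=0.35$) at the end of a narrow channel through a hard
protein slab, a pre-bound well (4 $k_BT$) near the channel mouth, two
shallow non-native surface wells (3.5 and 3 $k_BT$ — metastable traps), and
a flat dissociated plateau in a $9 \times 8$ box. Energies are in $k_BT$
($k_BT \equiv 1$), lengths dimensionless. Hard excluded volume is wrapped
in a soft quadratic repulsive skin (width 0.2, strength 8 $k_BT$) so the
accessible-region energy is finite everywhere and walls are never
flattened by the bias.

* **Sampler**: Metropolis Monte Carlo with isotropic Gaussian proposals,
  default `step_size = 0.12` (unbiased acceptance ≈ 0.55 inside the bound
  well, ≈ 0.65 overall — near the standard 1/2 efficiency heuristic).
  Each trajectory owns a counter-based RNG stream derived from its seed;
  replica-exchange swap decisions use a separate stream, so trajectory
  content is reproducible independent of exchange bookkeeping.
* **Bias ladder**: ensemble $k$ scales all well depths by
  $(1-\lambda_k\alpha)$, default $\lambda = 0, .25, .5, .75, 1$ with
  $\alpha = 1$; only the attractive part is flattened, so
  $b^k(x) \ge 0$ everywhere. Neighbor swaps every 10 steps (acceptance
  ≈ 0.7).
* **Hardness calibration**: the bound-well depth was set once, before any
  acceptance test existed, so that the mean bound→dissociated first-passage
  time (~$10^6$ steps, measured by direct simulation) exceeds the 5000-step
  unbiased trajectories by more than two orders of magnitude — the regime
  in which unbiased-only estimation must struggle. It was not revisited.
* **Discretization**: a uniform 0.5 × 0.5 grid plus two explicit
  dissociated distance shells (beyond distance 3 from the channel mouth).
  The dissociated state is discretized explicitly because it has low
  metastability; every frame beyond the threshold maps into the shells
  regardless of its grid cell. Count lag 20 steps, chosen where the
  implied timescales of the discretized process plateau (they change by
  <10% from lag 20 to 40) and diffusion per lag roughly matches the cell
  size.

What the generator does **not** emulate: configurational-entropy scales of
a 3D solvated complex (the dissociated volume here is tiny), rugged
high-dimensional discretization error, force-field error, or exchange
bottlenecks in a 14-replica ladder. A green benchmark establishes estimator
correctness and the qualitative data-efficiency separation, not performance
on molecular systems.

## 3. Kinetics

* **Transition-matrix MFPTs** solve $(I - T_{\mathrm{rest}})\,m = \tau\,1$;
  the source average uses the stationary distribution restricted to the
  source set (equilibrium-start convention of residence-time reporting).
* **Rate matrices.** Residence times from $T(\tau)$ overestimate when a
  state's lifetime is below the lag, hence two continuous-time estimators:
  the discrete-observation maximum-likelihood generator (off-diagonal rates
  optimized in log space; zero-count pairs pinned at zero; initialized from
  the projected real matrix logarithm), and a spectral least-squares fit
  whose objective matches $Q r_i = \mu_i r_i$ and $l_i^T Q = \mu_i l_i^T$
  for all real positive eigenpairs of $T$, $\mu_i = \log(\lambda_i)/\tau$,
  with unit weights (the open weighting choice; documented here because the
  published description leaves it free). On exactly embeddable $T$ both
  agree with the matrix logarithm to $10^{-6}$; on non-embeddable input the
  projection to the generator cone (clip negatives, restore row sums) is
  deterministic and the LSQ optimum stays in the cone by construction.
  The ML estimator uses numerical gradients and is meant for coarse models
  (tens of states), e.g. after spectral coarse-graining.
* **Coarse-graining** is the inner-simplex spectral construction on the
  top eigenvectors with clipping and row renormalization; crisp states by
  argmax.

## 4. Transition path theory

Committors from the boundary-value linear system; gross flux
$f_{ij} = \pi_i(1-q^+_i)T_{ij}q^+_j$; net flux, total flux and
$k_{AB} = F/(\tau\sum_i \pi_i(1-q^+_i))$ in inverse physical time.
Pathways are extracted by maximum-bottleneck (widest-path) search on the
net-flux graph with **lexicographic tie-breaking on state indices** (the
documented deterministic choice), subtracting each bottleneck until the
requested coverage. Numerically induced edges against the committor
ordering are pruned with a warning. Both the microstate network and the
coarse-grained network are valid inputs; total flux is invariant under any
valid partition (asserted to $10^{-12}$).

## 5. Open design points and how they were decided

* **Equilibrium samples in the stationary aggregation.** Whether
  equilibrium samples should enter the per-state weight aggregation (and
  hence $\pi$) or only the ensemble-level $f^k$ is not determined by the
  likelihood alone. Default: they enter (uses all information); the
  TRAM-set-only aggregation is available via
  `unbiased_stationary(fit, "samples-tram")`. At convergence the default
  coincides with $\pi_i \propto e^{-f_i^0}$ to numerical precision; the
  TRAM-only route differs at the level of that data split's statistical
  noise, which is how the flag's effect is reported.
* **Connectivity rule.** States are linked by counts in either direction in
  any ensemble, or by *equilibrium* samples sharing an ensemble. Counting
  time-correlated samples as equilibrium evidence
  (`eq_roles = "mbar+tram"`) is offered but off by default: with a single
  unbiased ensemble it would merge count-disconnected blocks whose relative
  weights the likelihood cannot actually determine.
* **Count mode.** Sliding-window counting is the default; `"sample"` mode
  (stride = lag) supports independence checks. Totals differ exactly by
  the documented pair-count arithmetic.
* **Equilibration handling.** Replica data enter after discarding an
  initial 5% and striding by 10 frames (the protocol shape of the emulated
  study: 50 ns discard, 0.1 ns subsampling, ~40 ns correlation time).
  Statistical-independence testing beyond the stride is left to the
  diagnostics (implied timescales, Chapman–Kolmogorov).

## 6. Known limitations

* The benchmark's conventional-MSM baseline is *less wrong* here than in
  high-dimensional practice: on a small 2D grid at diffusive lag, binding
  trajectories leave locally reversible counts along the whole funnel, so
  the reversible MLE partially reconstructs unbinding through detailed
  balance. Its rate estimates scatter around a systematic ~3x
  underestimate, landing within the factor-2 success window in roughly a
  quarter to a third of seeds rather than almost never. The acceptance
  suite asserts the strict "≈ 0" clause anyway and documents its failure;
  the qualitative separation (MEMM ≈ 0.8–0.9 success at a budget where the
  MSM sits at ≈ 0.3 with systematic bias) is asserted and holds.
* The likelihood trace is a diagnostic, not a proof of ascent (§1).
* The ML rate-matrix estimator does not scale past tens of states.
* Replica-exchange equilibrium data are assumed equilibrated after the
  discard; at very small budgets (≲ $10^5$ steps) this is visibly violated
  and the MEMM inherits a bias toward the initial (bound) configuration —
  the main failure mode of the small-budget benchmark points.
* Uncertainty is bootstrap-only (whole trajectories resampled); no
  asymptotic covariance formulas are provided.
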