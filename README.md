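# memmtools

Multi-ensemble Markov models (MEMMs) for binding thermodynamics and
kinetics in R.

## The problem

Estimating the kinetics of a tightly binding ligand from simulation is hard
because unbinding is rare: unbiased trajectories that are long enough to
sample binding are usually far too short to ever dissociate. Biased
(Hamiltonian replica-exchange) simulations on a flattened interaction
potential sample dissociation reversibly, but their dynamics are wrong.
MEMM estimators resolve the dilemma by a joint maximum-likelihood fit over
all ensembles: the biased data pin down the thermodynamics, detailed balance
converts the observed *binding* transitions into *unbinding* rates of the
unbiased ensemble.

`memmtools` implements the three estimators of this family plus the
downstream kinetic analysis:

* **MBAR** — equilibrium free-energy differences between K ensembles from
  equilibrium samples;
* **TRAM** — transition-based reweighting: per-ensemble reversible
  transition matrices `p_ij^k`, state–ensemble free energies `f_i^k` and
  unbiased point weights `mu(x)` from time-correlated data with transition
  counts `c_ij^k`;
* **TRAMMBAR** — the hybrid whose likelihood is the product
  `L = L_TRAM * L_MBAR`, coupling equilibrium replica-exchange samples to
  the state level through `exp(-f^k) = sum_i exp(-f_i^k)`. It reduces
  exactly to TRAM when the equilibrium set is empty and to MBAR when the
  time-correlated set is empty.

Downstream: implied timescales, Chapman–Kolmogorov tests, continuous-time
rate matrices (maximum-likelihood and spectral least-squares), mean
first-passage times, dissociation constants (`Kd`), bimolecular association
rates, perturbative free-energy differences, and transition path theory
(committors, reactive fluxes, pathway decomposition, coarse-graining).

The package ships a fully controlled benchmark system: a 2D protein–ligand
landscape (deep bound pocket at the end of a channel, a pre-bound site, two
non-native surface sites, a dissociated plateau) with Metropolis Monte
Carlo and Hamiltonian replica-exchange samplers, grid discretization, exact
quadrature references and an MSM-vs-MEMM benchmark harness.

## Worked example

Half a million MC steps of mixed data — 60% short unbiased binding
trajectories started in the dissociated region, 40% replica exchange over a
five-rung flattening ladder — versus the exact reference:

```r
library(memmtools)

surface  <- build_default_landscape()
schedule <- bias_schedule()                  # lambda = 0, .25, .5, .75, 1
disc     <- grid_discretizer(surface)

trajs <- generate_dataset(surface, schedule, disc, budget = 5e5, seed = 1)
cm    <- apply_connectivity(count_transitions(trajs, lag = 20,
                                              n_states = disc$n_states,
                                              n_ensembles = 5))
fit   <- trammbar_estimate(cm, tol = 1e-6, trace = FALSE)
print(fit)
#> MEMM: 78 states, 5 ensembles, lag 20
#>   converged: TRUE after 465 iterations (increment 1.75e-08)
#>   ensemble free energies: 0, 2.449, 4.188, 4.783, 4.923
```

The ensemble free energies `f^k` are the unit-less free-energy costs of
switching the whole system from the unbiased to each flattened ensemble.
Binding free energy and residence time follow from the stationary
distribution and the unbiased transition matrix:

```r
ref     <- reference_solution(surface, disc, seed = 99)
regions <- ref$cell_region
pi_full <- numeric(disc$n_states)
pi_full[cm$active] <- fit$unbiased_stationary
dG <- -log(sum(pi_full[regions == "bound"])) +
       log(sum(pi_full[regions == "dissociated"]))

tmat <- extract_transition_matrix(fit)
orig <- cm$active[tmat$states]
mfpt <- mfpt_tmatrix(tmat,
                     which(orig %in% which(regions == "bound")),
                     which(orig %in% which(regions == "dissociated")))
#> MEMM:      dG = -5.27 kBT, residence time = 9.72e+05 steps
#> reference: dG = -5.44 kBT, residence time = 9.38e+05 steps
```

The MEMM reproduces the binding free energy within 0.2 kBT and the mean
dissociation time within 4% — from data in which *no unbiased trajectory
ever dissociates* (the reference residence time is ~2000x one trajectory).
A conventional MSM built from the same total amount of unbiased-only data
misses the rate by factors of 3–10 (see `run_benchmark()`).

Mechanism, via transition path theory coarse-grained onto the five regions:

```r
fn <- reactive_flux(tmat,
                    A = which(orig %in% which(regions == "dissociated")),
                    B = which(orig %in% which(regions == "bound")))
macro <- split(seq_along(orig), regions[orig])
fn_macro <- coarse_grain_flux(fn, unname(macro[lengths(macro) > 0]))
pathway_decomposition(fn_macro, coverage = 0.95)
#> pathway decomposition: 3 pathway(s), 95.1% of total flux
#>    47.8%  2 -> 6 -> 5 -> 1
#>    24.5%  2 -> 3 -> 6 -> 5 -> 1
#>    22.8%  2 -> 4 -> 6 -> 5 -> 1
```

(Macrostates in order: 1 bound, 2 dissociated, 3 misbound1, 4 misbound2,
5 prebound, 6 transit.) Half of the association flux goes directly
dissociated → transit → pre-bound → bound; the rest detours through one of
the two non-native surface sites.

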