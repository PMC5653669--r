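test_that("MBAR solves trivial and enumerable systems", {
  # K = 1: f = 0, uniform weights
  r1 <- mbar_estimate(list(matrix(0, 50, 1)))
  expect_equal(r1$f, 0)
  expect_equal(r1$weights, rep(1 / 50, 50))
  # identical bias columns: f^1 = f^0 = 0 by symmetry
  b <- cbind(rnorm(40), 0, 0)[, c(2, 3)]
  r2 <- mbar_estimate(list(b[1:20, ], b[21:40, ]))
  expect_equal(r2$f, c(0, 0), tolerance = 1e-10)
  # exact enumeration oracle: discrete system, bias +c on a subset,
  # samples replicated proportionally to exact unbiased weights
  w <- c(4, 3, 2, 1)            # unbiased multiplicities of 4 microstates
  bstate <- c(1.3, 1.3, 0, 0)   # bias +1.3 on microstates 1, 2 in ensemble 2
  reps <- rep(1:4, times = w)
  bias <- cbind(0, bstate[reps])
  # all samples drawn from the unbiased ensemble
  r3 <- mbar_estimate(bias, sample_counts = c(length(reps), 0))
  f1_exact <- -log(sum(w * exp(-bstate)) / sum(w))
  expect_equal(r3$f[2], f1_exact, tolerance = 1e-10)
})

test_that("MBAR is overflow-safe and warns on poor overlap", {
  # bias energies up to 500 kBT must not overflow
  b <- cbind(0, c(rep(0, 10), rep(500, 10)))
  w <- testthat::capture_warnings(
    r <- mbar_estimate(list(b[1:10, ], b[11:20, ]), max_iter = 2000))
  expect_true(any(grepl("overlap", w)))
  expect_true(all(is.finite(r$f)))
  expect_true(all(is.finite(r$log_weights)))
})

test_that("TRAM matches the exhaustive 2-state grid-search oracle", {
  # symmetric counts: closed form p = 1/2, pi = 1/2
  cm <- mk_cm(array(matrix(5, 2, 2), c(2, 2, 1)),
              list(mk_traj(rep(c(1, 2), 10), bias = matrix(0, 20, 1))))
  fit <- tram_estimate(cm)
  expect_equal(fit$transition_matrices[[1]],
               matrix(0.5, 2, 2), tolerance = 1e-8)
  expect_equal(fit$unbiased_stationary, c(0.5, 0.5), tolerance = 1e-8)
  # asymmetric counts against the grid-search maximizer
  C <- matrix(c(14, 6, 4, 26), 2, byrow = TRUE)
  cm2 <- mk_cm(array(C, c(2, 2, 1)),
               list(mk_traj(rep(c(1, 2, 2), 10), bias = matrix(0, 30, 1))))
  fit2 <- tram_estimate(cm2)
  oracle <- grid_search_2state(C, n_grid = 301)
  expect_equal(fit2$unbiased_stationary, oracle$pi, tolerance = 0.01)
  expect_equal(fit2$transition_matrices[[1]], oracle$P, tolerance = 0.01)
  # and the solution's likelihood is at least the oracle's grid optimum
  ll_fit <- sum(C * log(fit2$transition_matrices[[1]]))
  expect_gte(ll_fit, oracle$ll - 1e-8)
})

test_that("identical data in all ensembles gives ensemble-symmetric f", {
  s <- rep(c(1, 2, 3, 2), 25)
  C1 <- matrix(0, 3, 3)
  for (t in seq_len(length(s) - 1)) C1[s[t], s[t + 1]] <- C1[s[t], s[t + 1]] + 1
  counts <- array(0, c(3, 3, 2))
  counts[, , 1] <- C1; counts[, , 2] <- C1
  trs <- list(mk_traj(s, 0L, bias = matrix(0, length(s), 2)),
              mk_traj(s, 1L, bias = matrix(0, length(s), 2)))
  fit <- trammbar_estimate(mk_cm(counts, trs))
  f <- fit$state_ensemble_free_energies
  expect_equal(f[, 1], f[, 2], tolerance = 1e-8)
})

test_that("MEMM result invariants hold on a mixed TRAM+MBAR fit", {
  set.seed(1)
  bstate <- c(0, 1.5, 3)
  s0 <- c(1, rep(c(1, 2, 3, 2), 50))
  counts <- array(0, c(3, 3, 2))
  for (t in seq_len(length(s0) - 1))
    counts[s0[t], s0[t + 1], 1] <- counts[s0[t], s0[t + 1], 1] + 1
  w2 <- exp(-bstate) * c(0.5, 0.3, 0.2); w2 <- w2 / sum(w2)
  s2 <- sample(1:3, 300, TRUE, prob = w2)
  trs <- list(mk_traj(s0, 0L, bias = cbind(0, bstate[s0])),
              mk_traj(s2, 1L, role = "mbar", bias = cbind(0, bstate[s2])))
  cm <- mk_cm(counts, trs)
  fit <- trammbar_estimate(cm)
  f <- fit$state_ensemble_free_energies
  p <- fit$transition_matrices[[1]]
  # rows sum to 1 within 1e-10
  expect_lt(max(abs(rowSums(p) - 1)), 1e-10)
  # detailed balance within 1e-8 relative
  flux <- exp(-f[, 1]) * p
  expect_lt(max(abs(flux - t(flux)) / pmax(flux, 1e-300)), 1e-8)
  # e^{-f^k} = sum_i e^{-f_i^k} within 1e-10
  fk <- vapply(1:2, function(k) -memmtools:::logsumexp(-f[, k]), numeric(1))
  expect_equal(fk, fit$ensemble_free_energies, tolerance = 1e-10)
  # gauge: f^0 = 0 and sum of point weights = 1
  expect_equal(fit$ensemble_free_energies[1], 0, tolerance = 1e-12)
  mu <- exp(c(fit$point_weights$log_mu_tram, fit$point_weights$log_mu_mbar))
  expect_equal(sum(mu), 1, tolerance = 1e-10)
  # TRAM normalization: sum_{x in S_i} mu e^{f_i^k - b^k} = 1 per (i,k)
  st <- c(s0, s2)
  bias <- rbind(cbind(0, bstate[s0]), cbind(0, bstate[s2]))
  lm <- log(mu)
  for (i in 1:3) for (k in 1:2) {
    v <- sum(exp(lm[st == i] + f[i, k] - bias[st == i, k]))
    expect_equal(v, 1, tolerance = 1e-8)
  }
  # stationary aggregation routes agree at convergence
  expect_equal(unbiased_stationary(fit, "free-energies"),
               unbiased_stationary(fit, "samples-all"), tolerance = 1e-6)
})

test_that("log-likelihood trace is non-decreasing on chain-sampled data", {
  # realistic sliding-window counts (diagonal-dominant) from a simulated
  # reversible chain; the adversarial no-self-count pattern can show a small
  # transient dip (see the methods vignette), chain data does not
  rr <- random_reversible(3, seed = 8)
  s0 <- simulate_chain(rr$T, 400, seed = 9)
  counts <- array(0, c(3, 3, 2))
  for (t in seq_len(length(s0) - 1))
    counts[s0[t], s0[t + 1], 1] <- counts[s0[t], s0[t + 1], 1] + 1
  bst <- c(0, 1, 2)
  set.seed(10)
  s2 <- sample(1:3, 150, TRUE)
  cm <- mk_cm(counts,
              list(mk_traj(s0, 0L, bias = cbind(0, bst[s0])),
                   mk_traj(s2, 1L, role = "mbar", bias = cbind(0, bst[s2]))))
  fit <- trammbar_estimate(cm)
  tr <- fit$convergence$log_likelihood_trace
  # slack relative to the likelihood magnitude (evaluation precision)
  expect_true(all(diff(tr) > -1e-9 * max(1, abs(tr[length(tr)]))))
})

test_that("TRAMMBAR limit equivalences (also exercised in acceptance)", {
  set.seed(3)
  s0 <- rep(c(1, 2, 1, 3), 30)
  counts <- array(0, c(3, 3, 2))
  for (t in seq_len(length(s0) - 1))
    counts[s0[t], s0[t + 1], 1] <- counts[s0[t], s0[t + 1], 1] + 1
  bst <- c(0, 2, 1)
  tr0 <- mk_traj(s0, 0L, bias = cbind(0, bst[s0]))
  cm <- mk_cm(counts, list(tr0))
  a <- tram_estimate(cm)
  b <- trammbar_estimate(cm)   # no equilibrium data present
  expect_equal(a$state_ensemble_free_energies,
               b$state_ensemble_free_energies, tolerance = 1e-8)
})

test_that("solution log-likelihood beats random feasible probes", {
  set.seed(5)
  bstate <- c(0, 1, 2)
  s0 <- rep(c(1, 2, 3, 2, 1, 3), 20)
  counts <- array(0, c(3, 3, 2))
  for (t in seq_len(length(s0) - 1))
    counts[s0[t], s0[t + 1], 1] <- counts[s0[t], s0[t + 1], 1] + 1
  s2 <- sample(1:3, 100, TRUE)
  cm <- mk_cm(counts,
              list(mk_traj(s0, 0L, bias = cbind(0, bstate[s0])),
                   mk_traj(s2, 1L, role = "mbar", bias = cbind(0, bstate[s2]))))
  fit <- trammbar_estimate(cm)
  ll_fit <- trammbar_loglik(cm,
                            fit$state_ensemble_free_energies,
                            fit$transition_matrices,
                            c(fit$point_weights$log_mu_tram,
                              fit$point_weights$log_mu_mbar))
  for (probe in 1:50) {
    pp <- random_feasible_params(cm, seed = probe)
    ll_p <- trammbar_loglik(cm, pp$f_ik, pp$p, pp$log_mu)
    expect_gte(ll_fit, ll_p - 1e-9)
  }
})

test_that("kd_from_populations converts correctly", {
  # C_box for the 7.62 nm box: ~3.75e-3 mol/L
  v <- 7.62^3
  expect_equal(kd_from_populations(0.5, 0.5, v), 3.753e-3, tolerance = 1e-3)
  # monotone to zero with vanishing unbound population
  k1 <- kd_from_populations(0.5, 0.1, v)
  k2 <- kd_from_populations(0.5, 0.01, v)
  expect_gt(k1, k2)
  expect_equal(kd_from_populations(0.5, 0, v), 0)
  expect_error(kd_from_populations(0, 0.5, v), "positive")
})

test_that("perturbative ddG has the exact closed forms", {
  set.seed(2)
  s0 <- rep(c(1, 2, 1, 2), 30)
  counts <- array(0, c(2, 2, 1))
  for (t in seq_len(length(s0) - 1))
    counts[s0[t], s0[t + 1], 1] <- counts[s0[t], s0[t + 1], 1] + 1
  cm <- mk_cm(counts, list(mk_traj(s0, bias = matrix(0, length(s0), 1))))
  fit <- tram_estimate(cm)
  n <- length(s0)
  # du = 0 -> 0; constant du cancels
  expect_equal(perturbative_ddg(fit, rep(0, n), 1, 2), 0)
  expect_equal(perturbative_ddg(fit, rep(2.7, n), 1, 2), 0, tolerance = 1e-12)
  # du = c on set A only -> ddG = c
  cval <- 0.8
  du <- ifelse(s0 == 1, cval, 0)
  expect_equal(perturbative_ddg(fit, du, 1, 2), cval, tolerance = 1e-12)
  expect_error(perturbative_ddg(fit, du, integer(0), 2), "non-empty")
})

test_that("TRAM recovers the stationary law of the toy landscape", {
  # pi over regions from a modest MEMM vs a 4x longer unbiased reference run
  surf <- fast_landscape()
  disc <- grid_discretizer(surf)
  sch <- bias_schedule(c(0, 0.5, 1))
  reg <- memmtools:::discretizer_regions(surf, disc)
  trajs <- generate_dataset(surf, sch, disc, budget = 1.2e5, seed = 5,
                            traj_len = 3000L)
  cm <- apply_connectivity(count_transitions(trajs, lag = 10,
                                             n_states = disc$n_states,
                                             n_ensembles = 3))
  fit <- trammbar_estimate(cm, tol = 1e-7, trace = FALSE)
  pi_full <- numeric(disc$n_states)
  pi_full[cm$active] <- fit$unbiased_stationary
  # exact Boltzmann oracle by dense quadrature over the same region masks
  ref <- reference_solution(surf, disc, n_events = 0)
  for (r in c("bound", "prebound", "dissociated")) {
    p_hat <- sum(pi_full[reg == r])
    p_exact <- sum(ref$pi_exact[reg == r])
    expect_lt(abs(p_hat - p_exact), 0.05)
  }
})
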