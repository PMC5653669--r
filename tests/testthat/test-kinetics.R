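test_that("reversible MSM MLE agrees with the TRAM core on one ensemble", {
  # two independent implementations of the same maximum-likelihood problem
  set.seed(3)
  rr <- random_reversible(4, seed = 4)
  s <- simulate_chain(rr$T, 3000, seed = 5)
  C <- matrix(0, 4, 4)
  for (t in seq_len(length(s) - 1)) C[s[t], s[t + 1]] <- C[s[t], s[t + 1]] + 1
  tm <- msm_estimate(C, lag = 1)
  cm <- mk_cm(array(C, c(4, 4, 1)),
              list(mk_traj(s, bias = matrix(0, length(s), 1))))
  fit <- tram_estimate(cm, tol = 1e-12)
  expect_equal(tm$matrix, fit$transition_matrices[[1]], tolerance = 1e-6)
  expect_equal(tm$stationary, fit$unbiased_stationary, tolerance = 1e-6)
})

test_that("implied timescales recover the chain relaxation time", {
  # 2-state chain with lambda2 = 0.8: t2 = -1/ln(0.8) = 4.4814
  T2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  s <- simulate_chain(T2, 2e5, seed = 6)
  its <- implied_timescales(list(mk_traj(s)), lags = c(1, 2, 5),
                            n_states = 2, m = 1)
  expect_equal(its$timescales[1, 1], -1 / log(0.8), tolerance = 0.1)
  # Markovian data: t2(tau) constant across lags within sampling error
  expect_lt(diff(range(its$timescales[, 1])) / its$timescales[1, 1], 0.15)
  # lambda2 -> 1: timescale grows without bound
  tstiff <- vapply(c(0.99, 0.999), function(l) -1 / log(l), numeric(1))
  expect_true(all(diff(tstiff) > 0))
})

test_that("Chapman-Kolmogorov test separates Markovian from hidden dynamics", {
  # Markovian chain: m = 1 predicted == estimated exactly; m > 1 within bands
  rr <- random_reversible(3, seed = 7)
  s <- simulate_chain(rr$T, 3e4, seed = 8)
  ck <- ck_test(list(mk_traj(s)), lag = 1, multiples = c(1, 3),
                macro_sets = list(a = 1, b = 2:3), n_states = 3,
                n_boot = 15, seed = 1)
  m1 <- ck[ck$multiple == 1, ]
  expect_equal(m1$predicted, m1$estimated, tolerance = 1e-12)
  m3 <- ck[ck$multiple == 3 & is.finite(ck$predicted), ]
  width <- pmax(m3$upper - m3$lower, 0.02)
  expect_true(all(abs(m3$predicted - m3$estimated) < 3 * width))

  # hidden-state (lumped) chain: strong metastability inside the lump makes
  # the observed process non-Markovian at short lag
  Th <- matrix(c(0.98, 0.02, 0.00,
                 0.02, 0.97, 0.01,
                 0.00, 0.02, 0.98), 3, byrow = TRUE)
  Th <- Th / rowSums(Th)
  sh <- simulate_chain(Th, 1e5, seed = 9)
  obs <- ifelse(sh <= 2, 1L, 2L)  # lump hidden states 1, 2
  ckh <- ck_test(list(mk_traj(obs)), lag = 1, multiples = c(1, 20),
                 macro_sets = list(a = 1, b = 2), n_states = 2,
                 n_boot = 15, seed = 2)
  m20 <- ckh[ckh$multiple == 20 & ckh$set_from == "a" & ckh$set_to == "b", ]
  expect_gt(abs(m20$predicted - m20$estimated),
            (m20$upper - m20$lower) / 2)
})

test_that("ML rate matrix: closed forms and parameter recovery", {
  # T = I: Q = 0
  q0 <- estimate_rate_matrix_ml(diag(c(100, 100)), lag = 1)
  expect_equal(q0$generator, matrix(0, 2, 2))
  # 2-state symmetric closed form: a = -ln(0.8)/2
  Tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  C <- 1e4 * diag(c(0.5, 0.5)) %*% Tm
  qml <- estimate_rate_matrix_ml(C, lag = 1)
  expect_equal(qml$generator[1, 2], -log(0.8) / 2, tolerance = 1e-6)
  expect_equal(qml$generator[2, 1], -log(0.8) / 2, tolerance = 1e-6)
  # generator contract
  expect_true(all(qml$generator[row(qml$generator) != col(qml$generator)] >= 0))
  expect_lt(max(abs(rowSums(qml$generator))), 1e-10)
  # exp(Q tau) reproduces the count MLE within likelihood tolerance
  expect_lt(abs(attr(qml, "loglik_gap")), 1e-6)
  # recovery from multinomial counts: Q = [[-0.1, 0.1], [0.2, -0.2]]
  Q <- matrix(c(-0.1, 0.1, 0.2, -0.2), 2, byrow = TRUE)
  P <- as.matrix(Matrix::expm(Q))
  set.seed(11)
  n_obs <- c(6.7e5, 3.3e5)
  Cs <- rbind(rmultinom(1, n_obs[1], P[1, ])[, 1],
              rmultinom(1, n_obs[2], P[2, ])[, 1])
  qrec <- estimate_rate_matrix_ml(Cs, lag = 1)
  # binomial standard errors on the off-diagonal rates
  se12 <- sqrt(P[1, 2] / n_obs[1]) / 1  # dP ~ dq at tau = 1, first order
  se21 <- sqrt(P[2, 1] / n_obs[2])
  expect_lt(abs(qrec$generator[1, 2] - 0.1), 3 * se12 + 0.002)
  expect_lt(abs(qrec$generator[2, 1] - 0.2), 3 * se21 + 0.002)
})

test_that("LSQ rate matrix agrees with the matrix logarithm when embeddable", {
  Tm <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  qlsq <- estimate_rate_matrix_lsq(transition_matrix(Tm, lag = 1))
  expect_equal(qlsq$generator[1, 2], -log(0.8) / 2, tolerance = 1e-6)
  # 3-state embeddable: matrix exponential of a random reversible generator
  # (real spectrum, per the method's precondition)
  set.seed(12)
  Q <- matrix(runif(9, 0.05, 0.3), 3); Q <- (Q + t(Q)) / 2
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  P <- as.matrix(Matrix::expm(Q * 0.7))
  qe <- estimate_rate_matrix_lsq(transition_matrix(P, lag = 0.7))
  expect_equal(qe$generator, Q, tolerance = 1e-5)
  qm <- estimate_rate_matrix_ml(1e6 * diag(3) %*% P, lag = 0.7)
  expect_equal(qm$generator, Q, tolerance = 1e-5)
  # perturbed non-embeddable input still yields a valid generator
  Pp <- P; Pp[1, 2] <- Pp[1, 2] + 0.05
  Pp <- Pp / rowSums(Pp)
  qp <- estimate_rate_matrix_lsq(transition_matrix(Pp, lag = 0.7))
  off <- qp$generator[row(qp$generator) != col(qp$generator)]
  expect_true(all(off >= -1e-12))
  expect_lt(max(abs(rowSums(qp$generator))), 1e-10)
})

test_that("mean first-passage times solve the right linear systems", {
  # 2-state symmetric rates k: MFPT = 1/k
  k <- 0.37
  Q <- matrix(c(-k, k, k, -k), 2, byrow = TRUE)
  expect_equal(mfpt_rate(Q, c(0.5, 0.5), 1, 2), 1 / k, tolerance = 1e-12)
  # 3-state linear chain, all rates k: MFPT(1 -> 3) = 3/k
  Q3 <- matrix(c(-k, k, 0, k, -2 * k, k, 0, k, -k), 3, byrow = TRUE)
  expect_equal(mfpt_rate(Q3, rep(1 / 3, 3), 1, 3), 3 / k, tolerance = 1e-12)
  # discrete time: absorbing 2-state with p_leave = 0.5, tau = 1: MFPT = 2
  T2 <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, byrow = TRUE)
  expect_equal(mfpt_tmatrix(transition_matrix(T2, lag = 1), 1, 2), 2)
  # discrete vs continuous: bias shrinks with the lag
  Qd <- matrix(c(-0.2, 0.2, 0.05, -0.05), 2, byrow = TRUE)
  errs <- vapply(c(1, 0.25), function(tau) {
    P <- as.matrix(Matrix::expm(Qd * tau))
    tm <- transition_matrix(P, lag = tau)
    abs(mfpt_tmatrix(tm, 1, 2) - mfpt_rate(Qd, tm$stationary, 1, 2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # errors
  expect_error(mfpt_rate(Q, c(0.5, 0.5), 1, 1), "disjoint")
  expect_error(mfpt_tmatrix(transition_matrix(T2, lag = 1),
                            integer(0), 2), "non-empty")
})

test_that("bimolecular association rate conversion", {
  # C_box = 1 M: rate equals 1/mfpt
  v1 <- 1 / (6.02214076e23 * 1e-24)  # volume with C_box = 1 mol/L
  expect_equal(bimolecular_on_rate(1, v1), 1, tolerance = 1e-12)
  # doubling the volume doubles k_on at fixed mfpt
  expect_equal(bimolecular_on_rate(1, 2 * v1) / bimolecular_on_rate(1, v1), 2)
  # the worked example: V = 442.45 nm^3, mfpt = 1e-6 s -> ~2.66e8 /M/s
  expect_equal(bimolecular_on_rate(1e-6, 7.62^3), 2.665e8, tolerance = 1e-3)
})

test_that("metastable coarse-graining recovers block structure", {
  Tb <- matrix(c(0.88, 0.10, 0.01, 0.01,
                 0.10, 0.88, 0.01, 0.01,
                 0.01, 0.01, 0.88, 0.10,
                 0.01, 0.01, 0.10, 0.88), 4, byrow = TRUE)
  tm <- transition_matrix(Tb, lag = 1)
  mc <- metastable_coarse_grain(tm, 2)
  expect_equal(mc$assignment[1], mc$assignment[2])
  expect_equal(mc$assignment[3], mc$assignment[4])
  expect_false(mc$assignment[1] == mc$assignment[3])
  # membership contract
  expect_true(all(mc$memberships >= 0 & mc$memberships <= 1))
  expect_equal(rowSums(mc$memberships), rep(1, 4))
  # n_macro = n_states: identity partition
  mcid <- metastable_coarse_grain(tm, 4)
  expect_equal(mcid$memberships, diag(4))
})
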