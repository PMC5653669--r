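test_that("default landscape has the designed five-region topology", {
  surf <- build_default_landscape()
  w <- surf$wells
  e_centers <- potential_energy(surf, w[, 1:2])
  # bound well is the global minimum among wells
  expect_true(all(e_centers[1] < e_centers[-1]))
  # far from wells and walls: plateau energy
  expect_equal(potential_energy(surf, c(4.5, 0)), surf$plateau,
               tolerance = 1e-6)
  # excluded region is excluded
  expect_true(is.infinite(potential_energy(surf, c(-2.5, 2))))
  # all five regions are represented by the region classifier
  pts <- rbind(w[, 1:2], c(5, 3), c(1.5, 0))
  reg <- region_of(surf, pts)
  expect_setequal(as.character(reg),
                  c("bound", "prebound", "misbound1", "misbound2",
                    "dissociated", "transit"))
})

test_that("well centers are local minima (gradient ~ 0)", {
  surf <- build_default_landscape()
  h <- 1e-4
  for (i in seq_len(nrow(surf$wells))) {
    c0 <- surf$wells[i, 1:2]
    gx <- (potential_energy(surf, c0 + c(h, 0)) -
             potential_energy(surf, c0 - c(h, 0))) / (2 * h)
    gy <- (potential_energy(surf, c0 + c(0, h)) -
             potential_energy(surf, c0 - c(0, h))) / (2 * h)
    # tails of neighboring wells pull on the center (up to ~0.12 kBT/length
    # for the prebound well next to the deep bound well); the center must
    # still be a local minimum within the probe-grid resolution
    expect_lt(max(abs(c(gx, gy))), 0.2)
    dd <- expand.grid(dx = seq(-0.25, 0.25, by = 0.05),
                      dy = seq(-0.25, 0.25, by = 0.05))
    e <- potential_energy(surf, cbind(c0[1] + dd$dx, c0[2] + dd$dy))
    bm <- which.min(e)
    expect_lt(max(abs(c(dd$dx[bm], dd$dy[bm]))), 0.051)
  }
})

test_that("invalid landscape overrides are rejected with diagnostics", {
  w <- build_default_landscape()$wells
  w[1, 3] <- 2.0  # bound shallower than misbound1
  expect_error(build_default_landscape(list(wells = w)),
               "strictly deeper")
  expect_error(build_default_landscape(list(nonsense = 1)),
               "unknown landscape parameter")
})

test_that("bias_surface flattens wells only, monotonically in lambda", {
  surf <- build_default_landscape()
  expect_error(bias_surface(surf, 1.2), "0, 1")
  expect_error(bias_surface(surf, -0.1), "0, 1")
  set.seed(1)
  pts <- cbind(runif(200, 0, 5.5), runif(200, -3.5, 3.5))
  pts <- pts[!memmtools:::.toy_excluded_cpp(unclass(surf), pts), , drop = FALSE]
  u0 <- potential_energy(surf, pts)
  # lambda = 0: identity
  expect_equal(potential_energy(bias_surface(surf, 0), pts), u0)
  # lambda = 1, alpha = 1: bound-well center energy equals plateau
  # (wall skin does not reach the well center)
  expect_equal(
    potential_energy(bias_surface(surf, 1), surf$wells[1, 1:2]),
    surf$plateau, tolerance = 1e-6)
  # b >= 0 everywhere and non-decreasing in lambda at well centers
  lambdas <- c(0.25, 0.5, 0.75, 1)
  prev <- rep(0, nrow(surf$wells))
  for (l in lambdas) {
    b <- potential_energy(bias_surface(surf, l), pts) - u0
    expect_true(all(b >= -1e-12))
    bc <- potential_energy(bias_surface(surf, l), surf$wells[, 1:2]) -
      potential_energy(surf, surf$wells[, 1:2])
    expect_true(all(bc >= prev - 1e-12))
    prev <- bc
  }
})

test_that("metropolis sampling: acceptance, determinism, start validation", {
  # essentially flat surface in a huge box: every proposal accepted
  flat <- build_default_landscape(list(
    wells = rbind(bound = c(0, 0, 1e-12, 0.3),
                  prebound = c(1, 0, 0, 0.3),
                  misbound1 = c(2, 0, 0, 0.3),
                  misbound2 = c(3, 0, 0, 0.3)),
    box = c(-1e6, 1e6, -1e6, 1e6), slab_xhi = -1e6 + 1,
    channel = c(-1e6, 0.1)))
  tr <- metropolis_sample(flat, c(100, 100), n_steps = 5000, seed = 3)
  expect_equal(tr$acceptance_fraction, 1.0)
  # determinism
  surf <- fast_landscape()
  t1 <- metropolis_sample(surf, c(3, 0), 2000, seed = 11)
  t2 <- metropolis_sample(surf, c(3, 0), 2000, seed = 11)
  expect_identical(t1$positions, t2$positions)
  t3 <- metropolis_sample(surf, c(3, 0), 2000, seed = 12)
  expect_false(identical(t1$positions, t3$positions))
  # frame count contract (thin = 1): n_steps + 1 frames
  expect_equal(nrow(t1$positions), 2001L)
  # start inside the protein slab
  expect_error(metropolis_sample(surf, c(-1, 2), 100), "excluded")
  # every visited position is accessible
  expect_false(any(memmtools:::.toy_excluded_cpp(unclass(surf), t1$positions)))
})

test_that("metropolis sampling reproduces the Boltzmann variance of a well", {
  # deep isotropic Gaussian well ~ harmonic with kappa = depth / sigma^2;
  # positional variance per coordinate = sigma^2 / depth
  depth <- 40; sig <- 0.3
  surf <- build_default_landscape(list(
    wells = rbind(bound = c(2.5, 0, depth, sig),
                  prebound = c(-0.4, 0, 1, 0.3),
                  misbound1 = c(0.45, 2, 1, 0.3),
                  misbound2 = c(0.45, -2, 1, 0.3))))
  tr <- metropolis_sample(surf, c(2.5, 0), n_steps = 1e5, step_size = 0.03,
                          seed = 5)
  x <- tr$positions[-(1:2000), 1] - 2.5
  v_hat <- var(x)
  v_exact <- sig^2 / depth
  # standard error of the variance from batch means
  nb <- 40
  bm <- tapply(x, rep(seq_len(nb), length.out = length(x)), var)
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(v_hat - v_exact), 3 * se + 0.03 * v_exact)
})

test_that("replica exchange: trivial swaps, determinism, labels", {
  surf <- fast_landscape()
  # two identical ensembles: every swap accepted
  sch0 <- structure(list(n_ensembles = 2L, scaling = c(0, 0),
                         temperature = 1), class = "bias_schedule")
  re <- replica_exchange_sample(surf, sch0, n_steps = 500,
                                exchange_interval = 5, seed = 2)
  expect_equal(attr(re, "swap_acceptance"), 1.0)
  # determinism and fixed ensemble labels
  sch <- bias_schedule(c(0, 0.5, 1))
  r1 <- replica_exchange_sample(surf, sch, 400, seed = 9)
  r2 <- replica_exchange_sample(surf, sch, 400, seed = 9)
  for (k in 1:3) {
    expect_identical(r1[[k]]$positions, r2[[k]]$positions)
    expect_equal(unique(r1[[k]]$ensemble_labels), k - 1L)
  }
})

test_that("replica exchange preserves per-ensemble marginals", {
  # region occupancies of the replica-exchange marginal match long direct
  # Metropolis sampling of the same ensemble (z-test, Bonferroni alpha=0.01)
  surf <- fast_landscape()
  sch <- bias_schedule(c(0, 0.6))
  n <- 6e4
  re <- replica_exchange_sample(surf, sch, n_steps = n,
                                exchange_interval = 10, seed = 31,
                                start = matrix(c(3, 3, 0, 0), 2))
  for (k in 1:2) {
    direct <- metropolis_sample(bias_surface(surf, sch$scaling[k]),
                                c(3, 0), n_steps = n, seed = 77 + k)
    block <- 2000  # compare block-averaged occupancies
    occ <- function(tr) {
      reg <- region_of(surf, tr$positions) == "dissociated"
      tapply(reg, rep(seq_len(length(reg) %/% block + 1),
                      each = block)[seq_along(reg)], mean)
    }
    o1 <- occ(re[[k]]); o2 <- occ(direct)
    z <- (mean(o1) - mean(o2)) /
      sqrt(var(o1) / length(o1) + var(o2) / length(o2))
    expect_lt(abs(z), qnorm(1 - 0.005 / 2))  # Bonferroni over 2 ensembles
  }
})

test_that("compute_bias_matrix matches direct evaluation", {
  surf <- build_default_landscape()
  sch <- bias_schedule(c(0, 0.4, 0.8))
  tr <- metropolis_sample(surf, c(1, 1), 500, seed = 8)
  b <- compute_bias_matrix(tr, sch, surf)
  expect_equal(dim(b), c(501L, 3L))
  # unbiased column identically zero
  expect_true(all(b[, 1] == 0))
  # a frame far out on the plateau: whole row ~ 0
  far <- which(tr$positions[, 1] > 4.5 & abs(tr$positions[, 2]) > 2.5)
  if (length(far))
    expect_lt(max(abs(b[far[1], ])), 1e-6)
  # spot check against independent re-evaluation
  set.seed(4)
  for (t in sample(nrow(b), 5)) for (k in 2:3) {
    u0 <- potential_energy(surf, tr$positions[t, ])
    uk <- potential_energy(bias_surface(surf, sch$scaling[k]),
                           tr$positions[t, ])
    expect_equal(b[t, k], uk - u0, tolerance = 1e-12)
  }
  # non-negative when flattening only removes attraction
  expect_true(all(b >= -1e-12))
})

test_that("long-run Metropolis occupancies agree with dense quadrature", {
  # Boltzmann consistency on a softened landscape where mixing is fast
  surf <- fast_landscape()
  disc <- grid_discretizer(surf)
  ref <- reference_solution(surf, disc, n_events = 0)
  tr <- metropolis_sample(surf, c(3, 0), n_steps = 4e5, seed = 17)
  dt <- discretize(tr, disc)
  reg <- ref$cell_region
  p_sim <- vapply(c("bound", "dissociated"), function(r)
    mean(dt$states %in% which(reg == r)), numeric(1))
  p_exact <- vapply(c("bound", "dissociated"), function(r)
    sum(ref$pi_exact[reg == r]), numeric(1))
  # block-based Monte Carlo error
  for (i in 1:2) {
    inr <- dt$states %in% which(reg == c("bound", "dissociated")[i])
    blocks <- tapply(inr, rep(seq_len(80), each = length(inr) %/% 80 + 1)[
      seq_along(inr)], mean)
    se <- sd(blocks) / sqrt(length(blocks))
    expect_lt(abs(p_sim[i] - p_exact[i]), 4 * se + 0.01)
  }
})

test_that("trajectory containers round-trip through files", {
  surf <- fast_landscape()
  sch <- bias_schedule(c(0, 1))
  tr <- metropolis_sample(surf, c(2, 0), 50, seed = 1)
  disc <- grid_discretizer(surf)
  dtr <- discretize(tr, disc, bias = compute_bias_matrix(tr, sch, surf))
  f <- tempfile(fileext = ".rds")
  write_trajectory_set(list(tr, dtr), f, metadata = list(seed = 1))
  back <- read_trajectory_set(f)
  expect_equal(back[[1]]$positions, tr$positions)
  expect_equal(back[[2]]$states, dtr$states)
  expect_equal(attr(back, "metadata")$seed, 1)
  f2 <- tempfile(fileext = ".tsv")
  export_trajectories_csv(list(dtr), f2)
  tab <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), length(dtr$states))
  expect_error(export_trajectories_csv(list(tr, dtr), f2), "mix")
  unlink(c(f, f2))
})
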