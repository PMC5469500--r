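# The LAD fitting program, lambda selection and alternative-optima sampling.

test_that("data reachable inside the cone is fitted exactly", {
  m <- chain3()
  sol <- regrex_lad(m, reaction_data(m, c(R1 = 3)), lambda = 0)
  expect_equal(sol$error_norm, 0, tolerance = 1e-7)
  expect_equal(unname(sol$v_opt), rep(3, 3), tolerance = 1e-7)
})

test_that("conflicting data yields the 1-D scan optimum", {
  m <- chain3()
  d <- chain37_data(m)
  # independent 1-D oracle: v1 = v2 = v3 = v, error |v-3| + |v-7|
  verr <- function(v) abs(v - 3) + abs(v - 7)
  grid <- seq(0, 10, by = 0.001)
  expect_equal(min(vapply(grid, verr, 0)), 4)
  sol <- regrex_lad(m, d, lambda = 0)
  expect_equal(sol$error_norm, 4, tolerance = 1e-7)
  v <- unname(sol$v_opt)
  expect_equal(v[1], v[2], tolerance = 1e-7)
  expect_true(v[1] >= 3 - 1e-7 && v[1] <= 7 + 1e-7)
})

test_that("full regularization with max-scaled data shrinks all fluxes to zero", {
  fx <- make_fixture("random", n_reactions = 9, n_metabolites = 5,
                     reversible_fraction = 0.25, seed = 21)
  sol <- regrex_lad(fx$model, fx$data, lambda = 1)
  expect_lt(sol$l1_norm, 1e-6)
  expect_equal(sol$error_norm, sum(fx$data$d, na.rm = TRUE), tolerance = 1e-6)
})

test_that("the l1 norm of the optimum is non-increasing in lambda", {
  for (sd in c(2, 31)) {
    fx <- make_fixture("random", n_reactions = 8, n_metabolites = 4,
                       reversible_fraction = 0.25, seed = sd)
    l1 <- vapply(c(0, 0.1, 0.3, 0.5, 1), function(l)
      regrex_lad(fx$model, fx$data, lambda = l)$l1_norm, 0)
    expect_true(all(diff(l1) <= 1e-6))
  }
})

test_that("lambda selection maximizes the data-flux correlation", {
  fx <- make_fixture("random", n_reactions = 8, n_metabolites = 4,
                     reversible_fraction = 0.25, seed = 2)
  # singleton grid
  expect_equal(select_lambda(fx$model, fx$data, 0)$lambda, 0)
  # lambda = 1 zeroes all fluxes -> correlation undefined, scored -Inf
  sel <- suppressMessages(select_lambda(fx$model, fx$data, c(0, 1)))
  expect_equal(sel$lambda, 0)
  expect_identical(sel$scores$correlation[2], -Inf)
  # argmax contract on a wider grid
  sel2 <- suppressMessages(select_lambda(fx$model, fx$data, c(0, 0.1, 0.3)))
  best <- sel2$scores$correlation[sel2$scores$lambda == sel2$lambda]
  expect_true(all(best >= sel2$scores$correlation))
})

test_that("the solved optimum satisfies its own optimality structure", {
  fx <- make_fixture("random", n_reactions = 9, n_metabolites = 5,
                     reversible_fraction = 0.3, seed = 7)
  sol <- regrex_lad(fx$model, fx$data, lambda = 0.1)
  # complementary error components at the optimum
  expect_lt(max(sol$eps_plus * sol$eps_minus), 1e-10)
  # the split flux satisfies the extended balance
  sp <- split_reversible(fx$model)
  expect_lt(max(abs(as.matrix(sp$S_ext) %*% sol$v_split)), 1e-6)
  # l1 norm of the split equals the l1 norm of the recombined fluxes
  expect_equal(sol$l1_norm, sum(abs(sol$v_opt)), tolerance = 1e-6)
})

test_that("a zero-distance random point returns the optimum itself", {
  m <- chain3()
  d <- chain37_data(m)
  sol <- regrex_lad(m, d, lambda = 0)
  v <- ambiflux:::aos_one(m, d, sol$w, unname(sol$v_opt),
                          sol$weighted_error, sol$l1_norm,
                          solver_spec(mip_gap = 0.01))
  expect_equal(unname(v), unname(sol$v_opt), tolerance = 1e-6)
})

test_that("AOS samples preserve both norms and respect the oracle span", {
  m <- chain3()
  d <- chain37_data(m)
  sol <- regrex_lad(m, d, lambda = 0)
  ex <- brute_force_aos_extrema(m, d, sol)
  s <- regrex_aos(m, d, sol, n = 25, seed = 5)
  for (i in 1:3) {
    expect_true(all(s$V[, i] >= ex$lo[i] - 1e-5))
    expect_true(all(s$V[, i] <= ex$hi[i] + 1e-5))
  }
  errs <- apply(s$V, 1, function(v) sum(abs(d$d[1:2] - abs(v[1:2]))))
  expect_true(all(abs(errs - sol$error_norm) < 1e-5))
  l1s <- rowSums(abs(s$V))
  expect_true(all(abs(l1s - sol$l1_norm) < 1e-5))
})

test_that("data-orphan parallel routes vary across the alternative optima", {
  m <- orphan_pair_toy()
  d <- reaction_data(m, c(R1 = 5, R4 = 5))
  sol <- regrex_lad(m, d, lambda = 0)
  expect_equal(sol$error_norm, 0, tolerance = 1e-7)
  ex <- brute_force_aos_extrema(m, d, sol)
  # the two orphan routes trade flux: each spans [0, 5]
  expect_equal(ex$lo[2:3], c(0, 0), tolerance = 1e-6)
  expect_equal(ex$hi[2:3], c(5, 5), tolerance = 1e-6)
  s <- regrex_aos(m, d, sol, n = 60, seed = 2)
  # data-bounded coordinates pinned, orphans genuinely varying
  expect_lt(diff(range(s$V[, "R1"])), 1e-5)
  expect_gt(diff(range(s$V[, "R2"])), 0.8 * 5)
  expect_gt(diff(range(s$V[, "R3"])), 0.8 * 5)
  # reproducibility of the sampler
  s2 <- regrex_aos(m, d, sol, n = 10, seed = 8)
  s3 <- regrex_aos(m, d, sol, n = 10, seed = 8)
  expect_identical(s2$V, s3$V)
})

test_that("reversible orphans keep their magnitude and may flip sign", {
  fx <- make_fixture("fig1_toy")
  m <- fx$model; d <- fx$data
  sol <- regrex_lad(m, d, lambda = 0)
  expect_equal(sol$error_norm, 0, tolerance = 1e-7)
  s <- regrex_aos(m, d, sol, n = 40, seed = 6)
  # v1, v2 pinned by the (consistent) data
  expect_lt(diff(range(s$V[, "v1"])), 1e-5)
  expect_lt(diff(range(s$V[, "v2"])), 1e-5)
  # |v3| is pinned by l1 preservation; only its sign is free
  mag <- abs(s$V[, "v3"])
  expect_lt(diff(range(mag)), 1e-5)
  ex <- brute_force_aos_extrema(m, d, sol)
  expect_true(all(s$V[, "v3"] >= ex$lo[3] - 1e-5 &
                  s$V[, "v3"] <= ex$hi[3] + 1e-5))
})
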