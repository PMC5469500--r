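# Network extraction, maximally-different alternatives and enumeration.

test_that("extraction finds the minimal completion of the detour toy", {
  m <- detour_toy()
  core <- core_set(m, "R1")
  net <- corex(m, core)
  expect_equal(unname(net$Z), 2)
  expect_identical(names(which(net$x == 1)), c("R2", "R5"))
  # exhaustive oracle agrees
  bf <- brute_force_min_subnetwork(m, 1)
  expect_equal(bf$Z, 2)
  expect_equal(length(bf$subsets), 1)
  expect_identical(m$reaction_ids[bf$subsets[[1]]], c("R2", "R5"))
  # witness flux keeps every included reaction active, excluded ones silent
  wf <- net$witness_flux
  expect_true(all(abs(wf[net$include]) >= net$epsilon - 1e-9))
  expect_true(all(abs(wf[!net$include]) <= 1e-9))
})

test_that("a cardinality floor forces the longer detour network", {
  m <- detour_toy()
  net <- corex(m, core_set(m, "R1"), Z_lb = 3)
  expect_equal(unname(net$Z), 3)
  expect_true(all(net$include[c("R3", "R4", "R5")]))
  # oracle over all subsets of size 3: the detour completion is feasible
  feas3 <- Filter(function(s)
    ambiflux:::subnetwork_feasible(m, c(1, s), 1e-4, tspec()),
    utils::combn(2:5, 3, simplify = FALSE))
  expect_true(list(c(3L, 4L, 5L)) %in% feas3)
})

test_that("core covering the whole consistent model needs no additions", {
  m <- chain3()
  net <- corex(m, core_set(m, 1:3))
  expect_equal(unname(net$Z), 0)
  expect_true(all(net$include))
  bf <- brute_force_min_subnetwork(m, 1:3)
  expect_equal(bf$Z, 0)
  expect_identical(bf$subsets, list(integer(0)))
})

test_that("an inconsistent core is reported with the blocked reactions", {
  # R4: C -> D can never carry flux (C unproduced)
  S <- matrix(0, 4, 4,
              dimnames = list(c("A", "B", "C", "D"), paste0("R", 1:4)))
  S["A", 1] <- 1; S["A", 2] <- -1; S["B", 2] <- 1; S["B", 3] <- -1
  S["C", 4] <- -1; S["D", 4] <- 1
  m <- metabolic_model(colnames(S), rownames(S), S, rep(0, 4), rep(10, 4))
  expect_error(corex(m, core_set(m, "R4")), "R4",
               class = "ambiflux_solver_error")
  bf <- brute_force_min_subnetwork(m, 4)
  expect_false(bf$feasible)
})

test_that("the alternative-network step finds the symmetric twin", {
  m <- make_fixture("parallel_paths", n_paths = 2)$model
  core <- core_set(m, "R1")
  net <- corex(m, core)
  st <- altnet_step(m, core, net)
  expect_equal(st$mismatches, 2L)
  expect_equal(sum(st$x), sum(net$x))       # cardinality conserved
  expect_false(all(st$x == net$x))
  # the mismatch indicators are never both set: mismatches = hamming distance
  expect_equal(st$mismatches, hamming(st$x, net$x))
})

test_that("a unique optimum yields zero mismatches and a singleton ensemble", {
  m <- chain3()
  core <- core_set(m, 1)
  net <- corex(m, core)
  st <- altnet_step(m, core, net)
  expect_equal(st$mismatches, 0L)
  expect_identical(st$x, net$x)
  ens <- altnet_enumerate(m, core, net, max_iter = 10, seed = 1)
  expect_equal(length(ens$networks), 1)
})

test_that("enumeration recovers all symmetric optima", {
  key <- function(idx) paste(sort(idx), collapse = ",")
  oracle_vs_altnet <- function(n_paths, seeds) {
    m <- make_fixture("parallel_paths", n_paths = n_paths)$model
    bf <- brute_force_min_subnetwork(m, 1)
    found <- character(0)
    for (sd in seeds) {
      ens <- altnet_enumerate(m, core_set(m, "R1"), max_iter = 50, seed = sd)
      for (net in ens$networks)
        found <- union(found, key(which(net$include) [-1]))
    }
    expect_equal(length(bf$subsets), n_paths)
    expect_setequal(found, vapply(bf$subsets, key, ""))
  }
  oracle_vs_altnet(2, seeds = 1)
  oracle_vs_altnet(4, seeds = 1:5)
})

test_that("every ensemble member keeps the core active (independent LP)", {
  fx <- make_fixture("random", n_reactions = 9, n_metabolites = 5,
                     reversible_fraction = 0.25, seed = 13)
  m <- fx$model
  core <- core_set(m, fx$core)
  ens <- altnet_enumerate(m, core, max_iter = 25, seed = 2)
  for (net in ens$networks) {
    expect_true(ambiflux:::subnetwork_feasible(m, which(net$include),
                                               net$epsilon, tspec()))
    expect_equal(sum(net$x), sum(ens$networks[[1]]$x))
  }
})

test_that("confidence-group mode conserves per-group cardinalities", {
  m <- make_fixture("parallel_paths", n_paths = 3)$model  # R1..R5
  core <- core_set(m, "R1", mode = "corda",
                   groups = list(MC = c("R2", "R3"), NC = "R4", OT = "R5"))
  net <- corex(m, core)
  st <- altnet_step(m, core, net)
  for (g in c("MC", "NC", "OT")) {
    grp <- core$group_of[core$P]
    expect_equal(sum(st$x[grp == g]), sum(net$x[grp == g]))
  }
  # with the MC-only swap available, the twin differs inside MC
  expect_equal(st$mismatches, 2L)
  expect_setequal(names(which(st$x != net$x)), c("R2", "R3"))
  # group validation
  expect_error(core_set(m, "R1", mode = "corda",
                        groups = list(MC = "R2", NC = "R4", OT = "R5")),
               "partition", class = "ambiflux_validation_error")
})

test_that("external networks round-trip through the audit", {
  m <- detour_toy()
  core <- core_set(m, "R1")
  net <- corex(m, core)
  a <- audit_external_network(m, core, which(net$include))
  expect_equal(a$x_opt, net$x)
  expect_equal(unname(a$Z), unname(net$Z))
  # a consistent superset is accepted with a larger cardinality
  a2 <- audit_external_network(m, core, 1:5)
  expect_equal(unname(a2$Z), 4)
  st <- altnet_step(m, core, a2$x_opt, Z = a2$Z)
  expect_equal(sum(st$x), 4)
  # missing core reaction and infeasible networks are rejected
  expect_error(audit_external_network(m, core, c("R2", "R5")),
               "core", class = "ambiflux_validation_error")
  expect_error(audit_external_network(m, core, c("R1", "R5")),
               class = "ambiflux_validation_error")
})
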