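# Model containers, JSON/SBML reading, validation and the reversible split.

test_that("JSON round-trip preserves every model field", {
  m <- detour_toy()
  m$gpr[2] <- "g1 and (g2 or g3)"
  tf <- withr::local_tempfile(fileext = ".json")
  write_model(m, tf)
  m2 <- read_model(tf)
  expect_identical(m2$reaction_ids, m$reaction_ids)
  expect_identical(m2$metabolite_ids, m$metabolite_ids)
  expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
  expect_equal(m2$lb, m$lb)
  expect_equal(m2$ub, m$ub)
  expect_identical(m2$gpr, m$gpr)
  expect_identical(m2$subsystem, m$subsystem)
})

test_that("SBML L3/FBC models read correctly", {
  path <- system.file("extdata", "toy_chain.xml", package = "ambiflux")
  m <- read_model(path)
  expect_equal(length(m$reaction_ids), 3)
  # the boundary species is excluded from mass balance
  expect_identical(m$metabolite_ids, c("M_A", "M_B"))
  expect_equal(m$lb, c(0, -10, 0))
  expect_true(m$reversible[2])
  expect_identical(m$gpr, c("g1", "(g2 and g3)", ""))
  # three columns, two internal metabolites, chain topology
  expect_equal(unname(as.matrix(m$S)),
               rbind(c(1, -1, 0), c(0, 1, -1)))
})

test_that("bound violations are rejected as validation errors", {
  path <- system.file("extdata", "toy_chain.xml", package = "ambiflux")
  txt <- readLines(path)
  txt <- sub('id="ub_ten" value="10"', 'id="ub_ten" value="-20"', txt)
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines(txt, bad)
  expect_error(read_model(bad), "lb > ub",
               class = "ambiflux_validation_error")
  expect_error(metabolic_model("R1", "A", matrix(1), lb = 5, ub = 1),
               class = "ambiflux_validation_error")
})

test_that("malformed files raise format errors naming the problem", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not json", tf)
  expect_error(read_model(tf), "parse", class = "ambiflux_validation_error")
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(id = "x"), tf2, auto_unbox = TRUE)
  expect_error(read_model(tf2), "metabolites",
               class = "ambiflux_validation_error")
  expect_error(read_model("/nonexistent/model.json"),
               class = "ambiflux_validation_error")
})

test_that("reversibility follows the bounds, and ids must be unique", {
  expect_error(metabolic_model(c("R1", "R1"), "A", matrix(c(1, -1), 1),
                               lb = c(0, 0), ub = c(1, 1)),
               "duplicated", class = "ambiflux_validation_error")
  m <- metabolic_model(c("R1", "R2"), "A", matrix(c(1, -1), 1),
                       lb = c(-5, 0), ub = c(5, 5))
  expect_identical(m$reversible, c(TRUE, FALSE))
})

test_that("splitting reversible reactions builds the extended model", {
  m <- metabolic_model(paste0("R", 1:3), c("A", "B"),
                       rbind(c(1, -1, 0), c(0, 1, -1)),
                       lb = c(0, -4, 0), ub = c(10, 8, 10))
  sp <- split_reversible(m)
  expect_equal(ncol(sp$S_ext), 4)    # 2 irreversible + 2 x 1 reversible
  expect_true(all(sp$lb_ext >= 0))
  # forward column = original, backward = negated, bounds [0, ub] / [0, -lb]
  expect_equal(sp$ub_ext, c(10, 10, 8, 4))
  expect_equal(as.numeric(sp$S_ext[, 4]), -as.numeric(m$S[, 2]))

  # all-irreversible model splits to itself
  ch <- chain3()
  sp2 <- split_reversible(ch)
  expect_equal(as.matrix(sp2$S_ext), as.matrix(ch$S), ignore_attr = TRUE)
})

test_that("recombined feasible split fluxes satisfy the original balance", {
  fx <- make_fixture("random", n_reactions = 9, n_metabolites = 5,
                     reversible_fraction = 0.3, seed = 11)
  m <- fx$model
  sp <- split_reversible(m)
  rng <- fva(m)
  withr::with_seed(5, {
    for (k in 1:10) {
      v <- ambiflux:::af_qp_project(as.matrix(m$S), m$lb, m$ub,
                                    stats::runif(ncol(m$S), rng$vmin, rng$vmax))
      v_ext <- c(v[sp$irr], pmax(v[sp$rev], 0), pmax(-v[sp$rev], 0))
      expect_lt(max(abs(as.matrix(sp$S_ext) %*% v_ext)), 1e-7)
      expect_equal(unname(recombine_fluxes(sp, v_ext)), v, tolerance = 1e-9)
    }
  })
})
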