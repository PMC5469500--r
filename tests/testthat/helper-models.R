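# Shared fixture builders for the test suite. Everything is constructed in
# code; no binary fixtures.

# 3-reaction irreversible chain ->A->B-> with bounds [0, 10].
chain3 <- function() make_fixture("chain", n_reactions = 3)$model

# The chain with data d1 = 3 on R1 and d2 = 7 on R2 (R3 data-orphan):
# mass balance forces v1 = v2 = v3, so the fitted error is
# min_v |v - 3| + |v - 7| = 4, attained on v in [3, 7].
chain37_data <- function(model) reaction_data(model, c(R1 = 3, R2 = 7))

# Detour toy from the extraction examples: ->A (R1, core); A->B directly
# (R2) or via C (R3: A->C, R4: C->B); B-> (R5). Minimal completion of core
# {R1} is {R2, R5} with Z = 2; at Z = 3 the detour {R3, R4, R5} is optimal.
detour_toy <- function() {
  S <- matrix(0, 3, 5,
              dimnames = list(c("A", "B", "C"), paste0("R", 1:5)))
  S["A", "R1"] <- 1
  S["A", "R2"] <- -1; S["B", "R2"] <- 1
  S["A", "R3"] <- -1; S["C", "R3"] <- 1
  S["C", "R4"] <- -1; S["B", "R4"] <- 1
  S["B", "R5"] <- -1
  metabolic_model(colnames(S), rownames(S), S, lb = rep(0, 5),
                  ub = rep(10, 5), id = "detour_toy",
                  subsystem = c("uptake", "direct", "detour", "detour", "sink"))
}

# A model with two parallel fully data-orphan routes between A and B; the
# alternative optima of a fit with data on the boundary reactions trade flux
# between the two routes, giving genuinely varying coordinates.
orphan_pair_toy <- function() {
  S <- matrix(0, 2, 4, dimnames = list(c("A", "B"), paste0("R", 1:4)))
  S["A", "R1"] <- 1
  S["A", "R2"] <- -1; S["B", "R2"] <- 1
  S["A", "R3"] <- -1; S["B", "R3"] <- 1
  S["B", "R4"] <- -1
  metabolic_model(colnames(S), rownames(S), S, lb = rep(0, 4),
                  ub = rep(10, 4), id = "orphan_pair")
}

# Default solver spec used across tests.
tspec <- function(...) solver_spec(...)
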