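# Synthetic test fixtures: small consistent models with planted cores and
# reaction data, plus brute-force oracles (independent code paths from the
# MILP builders) for the network-extraction and alternative-optima programs.

#' Generate a synthetic fixture model
#'
#' All topologies are consistent by construction (every reaction can carry
#' steady-state flux), so [reduce_model()] leaves them unchanged.
#'
#' * `chain`: a linear pathway uptake -> M1 -> ... -> sink.
#' * `parallel_paths`: uptake -> A, `n_paths` parallel conversions A -> B,
#'   sink B ->; with the uptake as core there are `n_paths` optimal
#'   single-reaction completions, a known set of alternative optima.
#' * `fig1_toy`: three reactions, data on the first two only; an uptake/sink
#'   pair through one metabolite (pinned by the data) plus a reversible
#'   inter-pool transport that touches no balanced metabolite, hence is free
#'   to vary across the alternative optima.
#' * `random`: a linear backbone through `n_metabolites` internal metabolites
#'   plus random forward shortcut reactions between backbone metabolites; a
#'   random subset is made reversible.
#'
#' @param topology One of `"chain"`, `"parallel_paths"`, `"fig1_toy"`,
#'   `"random"`.
#' @param n_reactions Number of reactions (`chain`, `random`).
#' @param n_metabolites Number of internal metabolites (`random`).
#' @param n_paths Number of parallel routes (`parallel_paths`).
#' @param reversible_fraction Fraction of reactions made reversible
#'   (`random`).
#' @param data_coverage Fraction of reactions given data values (uniform on
#'   [0, 1]).
#' @param core_fraction Fraction of data-bounded reactions planted as core:
#'   those with the largest data values (the upper quantile construction).
#' @param seed Integer seed.
#' @param bound Flux bound magnitude.
#' @return List with elements `model` ([metabolic_model()]), `data`
#'   ([reaction_data()]) and `core` (integer indices of the planted core).
#' @export
make_fixture <- function(topology = c("chain", "parallel_paths", "fig1_toy",
                                      "random"),
                         n_reactions = 6, n_metabolites = 4, n_paths = 2,
                         reversible_fraction = 0.2, data_coverage = 0.6,
                         core_fraction = 0.3, seed = 1L, bound = 10) {
  topology <- match.arg(topology)
  if (n_reactions < 1) stop_validation("fixture must have at least 1 reaction")
  for (f in c(reversible_fraction, data_coverage, core_fraction))
    if (f < 0 || f > 1) stop_validation("fractions must lie in [0, 1]")
  model <- switch(topology,
    chain = fixture_chain(n_reactions, bound),
    parallel_paths = fixture_parallel(n_paths, bound),
    fig1_toy = fixture_fig1(bound),
    random = fixture_random(n_reactions, n_metabolites, reversible_fraction,
                            seed, bound))
  n <- length(model$reaction_ids)
  withr::with_seed(seed + 1L, {
    if (topology == "fig1_toy") {
      d <- c(0.7, 0.7, NA)   # data on the first two reactions only
    } else {
      nD <- max(1L, round(data_coverage * n))
      idx <- sample.int(n, nD)
      d <- rep(NA_real_, n)
      d[idx] <- stats::runif(nD)
    }
  })
  model$gpr[!is.na(d)] <- paste0("g", which(!is.na(d)))
  data <- reaction_data(model, d)
  db <- data$data_bounded
  n_core <- max(1L, round(core_fraction * length(db)))
  core <- db[order(d[db], decreasing = TRUE)][seq_len(n_core)]
  list(model = model, data = data, core = sort(core))
}

fixture_chain <- function(n, bound) {
  if (n < 2) stop_validation("chain needs >= 2 reactions")
  m <- n - 1
  S <- matrix(0, m, n)
  for (i in seq_len(m)) { S[i, i] <- 1; S[i, i + 1] <- -1 }
  metabolic_model(paste0("R", seq_len(n)), paste0("M", seq_len(m)), S,
                  lb = rep(0, n), ub = rep(bound, n), id = "chain",
                  subsystem = rep("linear_pathway", n))
}

fixture_parallel <- function(n_paths, bound) {
  n <- n_paths + 2
  S <- matrix(0, 2, n)
  S[1, 1] <- 1                       # R1: -> A
  for (p in seq_len(n_paths)) {      # A -> B, n_paths parallel copies
    S[1, 1 + p] <- -1; S[2, 1 + p] <- 1
  }
  S[2, n] <- -1                      # last: B ->
  metabolic_model(paste0("R", seq_len(n)), c("A", "B"), S,
                  lb = rep(0, n), ub = rep(bound, n), id = "parallel_paths",
                  subsystem = c("uptake", rep("conversion", n_paths), "sink"))
}

fixture_fig1 <- function(bound) {
  S <- matrix(0, 1, 3)
  S[1, 1] <- 1; S[1, 2] <- -1        # v1: -> A, v2: A ->; v3 touches no
  metabolic_model(c("v1", "v2", "v3"), "A", S,            # balanced metabolite
                  lb = c(0, 0, -bound), ub = rep(bound, 3), id = "fig1_toy")
}

fixture_random <- function(n_reactions, n_metabolites, reversible_fraction,
                           seed, bound) {
  n_back <- n_metabolites + 1
  if (n_reactions < n_back)
    stop_validation("random fixture needs n_reactions >= n_metabolites + 1")
  withr::with_seed(seed, {
    S <- matrix(0, n_metabolites, n_reactions)
    S[1, 1] <- 1                                   # uptake -> M1
    for (i in seq_len(n_metabolites - 1)) {        # backbone conversions
      S[i, i + 1] <- -1; S[i + 1, i + 1] <- 1
    }
    S[n_metabolites, n_back] <- -1                 # M_last -> sink
    for (j in seq(n_back + 1, length.out = n_reactions - n_back)) {
      ij <- sort(sample.int(n_metabolites, 2))     # forward shortcut Mi -> Mj
      S[ij[1], j] <- -1; S[ij[2], j] <- 1
    }
    lb <- rep(0, n_reactions)
    n_rev <- round(reversible_fraction * n_reactions)
    if (n_rev > 0) lb[sample.int(n_reactions, n_rev)] <- -bound
    subsystems <- paste0("pathway_", sample.int(3, n_reactions, replace = TRUE))
  })
  metabolic_model(paste0("R", seq_len(n_reactions)),
                  paste0("M", seq_len(n_metabolites)), S,
                  lb = lb, ub = rep(bound, n_reactions),
                  subsystem = subsystems, id = sprintf("random_%d", seed))
}

#' Brute-force minimal consistent subnetwork (oracle)
#'
#' Enumerates every subset of the non-core set `P` and tests, by plain LP
#' feasibility on the original (unsplit) model with per-reaction direction
#' enumeration for included reversible reactions, whether core + subset can
#' all carry flux of magnitude at least `epsilon` in a single steady-state
#' flux vector while excluded reactions carry none. Independent of the MILP
#' constraint builder, so agreement with [corex()] is evidence.
#'
#' @param model A [metabolic_model()].
#' @param core Core reaction selector (ids, logical or integer indices).
#' @param epsilon Minimum active flux.
#' @param spec A [solver_spec()].
#' @param max_p Refusal threshold on `|P|` (exhaustive `2^|P|` scan).
#' @return List with `Z` (minimal added cardinality, `NA` if no subset is
#'   feasible), `subsets` (all minimal subsets, as integer reaction indices)
#'   and `feasible`.
#' @export
brute_force_min_subnetwork <- function(model, core, epsilon = 1e-4,
                                       spec = solver_spec(), max_p = 14) {
  core <- sort(reaction_index(model, core))
  P <- setdiff(seq_along(model$reaction_ids), core)
  if (length(P) > max_p)
    stop_validation("|P| = %d exceeds the exhaustive-scan limit %d",
                    length(P), max_p)
  for (size in 0:length(P)) {
    subs <- if (size == 0) list(integer(0)) else
      utils::combn(P, size, simplify = FALSE)
    hits <- Filter(function(s)
      subnetwork_feasible(model, c(core, s), epsilon, spec), subs)
    if (length(hits) > 0)
      return(list(Z = size, subsets = hits, feasible = TRUE))
  }
  list(Z = NA_integer_, subsets = list(), feasible = FALSE)
}

# Single-witness activity check: all `included` reactions simultaneously at
# |v| >= epsilon, all others at 0. Reversible included reactions get their
# sign enumerated (the |v| constraint is non-convex).
subnetwork_feasible <- function(model, included, epsilon, spec) {
  n <- length(model$reaction_ids)
  lb <- model$lb; ub <- model$ub
  out <- setdiff(seq_len(n), included)
  lb[out] <- 0; ub[out] <- 0
  rev_in <- included[model$reversible[included]]
  irr_in <- setdiff(included, rev_in)
  lb[irr_in] <- pmax(lb[irr_in], epsilon)
  if (any(lb[irr_in] > ub[irr_in])) return(FALSE)
  S <- as.matrix(model$S)
  zeros <- rep(0, nrow(S))
  for (mask in 0:(2^length(rev_in) - 1)) {
    lbk <- lb; ubk <- ub
    bits <- as.logical(bitwAnd(mask, 2^(seq_along(rev_in) - 1)))
    fwd <- rev_in[!bits]; bwd <- rev_in[bits]
    lbk[fwd] <- pmax(lbk[fwd], epsilon)
    ubk[bwd] <- pmin(ubk[bwd], -epsilon)
    if (any(lbk > ubk)) next
    res <- af_lp(numeric(n), S, zeros, zeros, lbk, ubk, spec = spec)
    if (res$status == "optimal") return(TRUE)
  }
  FALSE
}

#' Brute-force extrema of the alternative optima space (oracle)
#'
#' For each reaction, minimizes and maximizes its flux over the optimum face
#' of the fitting problem: steady state, flux bounds, total (weighted)
#' absolute data error equal to the optimum's, and total l1 norm equal to the
#' optimum's. Signs of reversible reactions are enumerated so that every
#' subproblem is a plain LP, independent of the MILP builders.
#'
#' @param model A [metabolic_model()].
#' @param data A [reaction_data()].
#' @param solution A [regrex_lad()] optimum.
#' @param spec A [solver_spec()].
#' @return Data frame with `reaction_id`, `lo`, `hi`: the exact span each
#'   alternative-optima sample must respect.
#' @export
brute_force_aos_extrema <- function(model, data, solution,
                                    spec = solver_spec()) {
  n <- length(model$reaction_ids)
  rev <- which(model$reversible)
  if (length(rev) > 12)
    stop_validation("too many reversible reactions for sign enumeration")
  D <- data$data_bounded
  w <- solution$w[D]
  E_w <- solution$weighted_error
  L1 <- solution$l1_norm
  tol <- max(spec$feasibility_tol, 1e-7)
  S <- as.matrix(model$S)
  m <- nrow(S)
  lo <- rep(Inf, n); hi <- rep(-Inf, n)
  for (mask in 0:(2^length(rev) - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(seq_along(rev) - 1)))
    sgn <- rep(1, n); sgn[rev[bits]] <- -1
    lb <- model$lb; ub <- model$ub
    lb[rev[!bits]] <- 0                 # forward half: v >= 0
    ub[rev[bits]] <- 0                  # backward half: v <= 0
    if (any(lb > ub)) next
    # variables: [v (n) | t (|D|) error magnitudes]
    N <- n + length(D)
    A <- matrix(0, m + 2 * length(D) + 2, N)
    rlb <- rub <- numeric(nrow(A))
    A[seq_len(m), seq_len(n)] <- S
    r <- m
    for (k in seq_along(D)) {           # t_k >= |d_k - sgn*v_k|
      i <- D[k]
      r <- r + 1                        # t - sgn*v >= -d  (t >= sgn*v - d)
      A[r, i] <- -sgn[i]; A[r, n + k] <- 1
      rlb[r] <- -data$d[i]; rub[r] <- Inf
      r <- r + 1                        # t + sgn*v >= d
      A[r, i] <- sgn[i]; A[r, n + k] <- 1
      rlb[r] <- data$d[i]; rub[r] <- Inf
    }
    r <- r + 1                          # weighted error norm pinned
    A[r, n + seq_along(D)] <- w
    rlb[r] <- E_w - tol * max(1, E_w); rub[r] <- E_w + tol * max(1, E_w)
    r <- r + 1                          # l1 norm pinned: sum sgn*v = L1
    A[r, seq_len(n)] <- sgn
    rlb[r] <- L1 - tol * max(1, L1); rub[r] <- L1 + tol * max(1, L1)
    vlb <- c(lb, rep(0, length(D))); vub <- c(ub, rep(Inf, length(D)))
    for (i in seq_len(n)) {
      obj <- numeric(N); obj[i] <- 1
      a <- af_lp(obj, A, rlb, rub, vlb, vub, spec = spec)
      if (a$status != "optimal") break  # this sign pattern is infeasible
      b <- af_lp(obj, A, rlb, rub, vlb, vub, maximize = TRUE, spec = spec)
      lo[i] <- min(lo[i], a$objective); hi[i] <- max(hi[i], b$objective)
    }
  }
  if (any(!is.finite(lo)))
    stop_solver("no feasible sign pattern: solution inconsistent with model")
  data.frame(reaction_id = model$reaction_ids, lo = lo, hi = hi)
}
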