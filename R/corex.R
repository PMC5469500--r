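# Parsimonious context-specific network extraction (CorEx), the
# maximally-different alternative-network program, and the iterative AltNet
# enumeration procedure.

per_group_Z <- function(x, grp)
  vapply(c("MC", "NC", "OT"), function(g) sum(x[grp == g]), 0)

#' Define a core reaction set
#'
#' @param model A [metabolic_model()].
#' @param core Core reaction selector (ids, logical or integer indices): the
#'   reactions that must be active in the extracted network.
#' @param mode `"simple"` (core/non-core) or `"corda"` (non-core partitioned
#'   into medium-confidence MC, negative-confidence NC and other OT groups;
#'   alternative networks then conserve the added cardinality per group).
#' @param groups For `"corda"`: named list of reaction selectors `MC`, `NC`,
#'   `OT` partitioning the non-core set.
#' @return An object of class `core_set`.
#' @export
core_set <- function(model, core, mode = c("simple", "corda"), groups = NULL) {
  mode <- match.arg(mode)
  core <- sort(reaction_index(model, core))
  P <- setdiff(seq_along(model$reaction_ids), core)
  group_of <- NULL
  if (mode == "corda") {
    if (is.null(groups) || !all(c("MC", "NC", "OT") %in% names(groups)))
      stop_validation("corda mode requires groups MC, NC, OT")
    gidx <- lapply(groups[c("MC", "NC", "OT")], reaction_index, model = model)
    allg <- sort(unname(unlist(gidx)))
    if (!identical(allg, P))
      stop_validation("MC, NC, OT must partition the non-core set")
    group_of <- character(length(model$reaction_ids))
    for (g in names(gidx)) group_of[gidx[[g]]] <- g
  }
  structure(list(core = core, P = P, mode = mode, group_of = group_of,
                 reaction_ids = model$reaction_ids),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("<core_set> |C|=%d |P|=%d mode=%s\n",
              length(x$core), length(x$P), x$mode))
  invisible(x)
}

# Constraint blocks shared by the extraction and alternative-network MILPs.
# Variables: [v_irr | v_for | v_back | x (over P) | y (over reversibles)].
op3_build <- function(split, core, epsilon, vmax = NULL) {
  model <- split$origin
  n_i <- length(split$irr); n_r <- length(split$rev)
  P <- core$P
  C <- core$core
  # positions of each original reaction inside the irr / rev blocks
  irr_pos <- stats::setNames(seq_len(n_i), split$irr)
  rev_pos <- stats::setNames(seq_len(n_r), split$rev)
  ubf <- split$ub_ext[n_i + seq_len(n_r)]
  ubb <- split$ub_ext[n_i + n_r + seq_len(n_r)]
  if (is.null(vmax)) {
    vm_irr <- split$ub_ext[seq_len(n_i)]
    vm_rev <- pmax(ubf, ubb)
  } else {
    vm_irr <- rep(vmax, n_i); vm_rev <- rep(vmax, n_r)
  }
  o_vi <- 0; o_vf <- n_i; o_vb <- n_i + n_r
  o_x <- n_i + 2 * n_r; o_y <- o_x + length(P)
  N <- o_y + n_r
  C_irr <- intersect(C, split$irr); C_rev <- intersect(C, split$rev)
  P_irr <- intersect(P, split$irr); P_rev <- intersect(P, split$rev)
  m <- nrow(split$S_ext)
  nrows <- m + length(C_irr) + length(C_rev) + 2 * length(P) + 2 * n_r
  A <- matrix(0, nrows, N)
  rlb <- rub <- numeric(nrows)
  A[seq_len(m), seq_len(n_i + 2 * n_r)] <- as.matrix(split$S_ext)  # 1.
  r <- m
  for (i in C_irr) {                       # 2. core irreversible active
    r <- r + 1; A[r, o_vi + irr_pos[[as.character(i)]]] <- 1
    rlb[r] <- epsilon; rub[r] <- Inf
  }
  for (i in C_rev) {                       # 3. core reversible active
    r <- r + 1; j <- rev_pos[[as.character(i)]]
    A[r, o_vf + j] <- 1; A[r, o_vb + j] <- 1
    rlb[r] <- epsilon; rub[r] <- Inf
  }
  x_of <- stats::setNames(seq_along(P), P)
  for (i in P_irr) {                       # 4-5. non-core irr gating
    q <- irr_pos[[as.character(i)]]; xc <- o_x + x_of[[as.character(i)]]
    r <- r + 1; A[r, o_vi + q] <- 1; A[r, xc] <- -vm_irr[q]
    rlb[r] <- -Inf; rub[r] <- 0
    r <- r + 1; A[r, o_vi + q] <- 1; A[r, xc] <- -epsilon
    rlb[r] <- 0; rub[r] <- Inf
  }
  for (i in P_rev) {                       # 6-7. non-core rev gating
    j <- rev_pos[[as.character(i)]]; xc <- o_x + x_of[[as.character(i)]]
    r <- r + 1; A[r, o_vf + j] <- 1; A[r, o_vb + j] <- 1; A[r, xc] <- -vm_rev[j]
    rlb[r] <- -Inf; rub[r] <- 0
    r <- r + 1; A[r, o_vf + j] <- 1; A[r, o_vb + j] <- 1; A[r, xc] <- -epsilon
    rlb[r] <- 0; rub[r] <- Inf
  }
  for (j in seq_len(n_r)) {                # 8. v_for <= (1-y) vmax_f
    r <- r + 1; A[r, o_vf + j] <- 1; A[r, o_y + j] <- ubf[j]
    rlb[r] <- -Inf; rub[r] <- ubf[j]
  }
  for (j in seq_len(n_r)) {                # 9. v_back <= y vmax_b
    r <- r + 1; A[r, o_vb + j] <- 1; A[r, o_y + j] <- -ubb[j]
    rlb[r] <- -Inf; rub[r] <- 0
  }
  lb <- c(split$lb_ext, rep(0, length(P) + n_r))
  ub <- c(split$ub_ext, rep(1, length(P) + n_r))
  list(A = A, rlb = rlb, rub = rub, lb = lb, ub = ub, N = N,
       o_x = o_x, x_cols = o_x + seq_along(P), y_cols = o_y + seq_len(n_r),
       v_cols = seq_len(n_i + 2 * n_r), P = P)
}

#' Extract a parsimonious context-specific network (CorEx)
#'
#' Minimizes the number of non-core reactions carrying flux while every core
#' reaction is forced to carry flux of magnitude at least `epsilon` in one
#' common steady-state flux distribution. Selected non-core reactions are
#' likewise forced active; unselected ones carry none. Solved as a single
#' MILP at a tight feasibility tolerance (default `1e-9`).
#'
#' @param model A [metabolic_model()].
#' @param core A [core_set()] or a bare core selector.
#' @param epsilon Minimum active flux (default `1e-4`: well above the
#'   feasibility tolerance, well below typical bounds).
#' @param vmax Optional global big-M constant; by default the per-column
#'   split bound is used (tighter relaxations).
#' @param Z_lb Optional lower bound on the number of added reactions, to
#'   relax the parsimony condition.
#' @param spec A [solver_spec()].
#' @return An `extracted_network`: `include` (named logical over all
#'   reactions), `x` (named 0/1 over the non-core set), `Z`,
#'   `witness_flux` (original orientation), `core`, `epsilon`, `status`.
#' @export
corex <- function(model, core, epsilon = 1e-4, vmax = NULL, Z_lb = NULL,
                  spec = solver_spec(feasibility_tol = 1e-9)) {
  if (!inherits(core, "core_set")) core <- core_set(model, core)
  split <- split_reversible(model)
  bl <- op3_build(split, core, epsilon, vmax)
  obj <- numeric(bl$N); obj[bl$x_cols] <- 1
  A <- bl$A; rlb <- bl$rlb; rub <- bl$rub
  if (!is.null(Z_lb)) {
    row <- numeric(bl$N); row[bl$x_cols] <- 1
    A <- rbind(A, row); rlb <- c(rlb, Z_lb); rub <- c(rub, Inf)
  }
  res <- af_milp(obj, A, rlb, rub, bl$lb, bl$ub,
                 integer = c(bl$x_cols, bl$y_cols), spec = spec)
  if (res$status == "infeasible") {
    hint <- corex_diagnose(model, core, epsilon, spec)
    stop_solver("network extraction infeasible: core is inconsistent%s", hint)
  }
  if (res$status != "optimal")
    stop_solver("network extraction did not reach optimality (%s)", res$status)
  network_from_solution(model, split, core, bl, res, epsilon)
}

corex_diagnose <- function(model, core, epsilon, spec) {
  rng <- tryCatch(fva(model, spec = solver_spec()), error = function(e) NULL)
  if (is.null(rng)) return(" (model itself infeasible)")
  blocked <- core$core[pmax(abs(rng$vmin[core$core]),
                            abs(rng$vmax[core$core])) < epsilon]
  if (length(blocked) == 0) return("")
  sprintf(" (FVA-blocked core reactions: %s)",
          paste(model$reaction_ids[blocked], collapse = ", "))
}

network_from_solution <- function(model, split, core, bl, res, epsilon) {
  x <- stats::setNames(round(res$x[bl$x_cols]), model$reaction_ids[bl$P])
  include <- stats::setNames(logical(length(model$reaction_ids)),
                             model$reaction_ids)
  include[core$core] <- TRUE
  include[bl$P] <- x > 0.5
  Z <- if (core$mode == "corda")
    per_group_Z(x, core$group_of[bl$P]) else sum(x)
  structure(list(include = include, x = x, Z = Z,
                 witness_flux = recombine_fluxes(split, res$x[bl$v_cols]),
                 core = core, epsilon = epsilon, status = res$status,
                 gap = res$gap),
            class = "extracted_network")
}

#' @export
print.extracted_network <- function(x, ...) {
  cat(sprintf("<extracted_network> %d/%d reactions included (Z = %s)\n",
              sum(x$include), length(x$include),
              paste(x$Z, collapse = "+")))
  invisible(x)
}

#' Find the maximally different alternative optimal network
#'
#' Given an anchor inclusion vector `x_opt` over the non-core set, maximizes
#' the number of mismatches to it among networks that keep the core active,
#' keep every included reaction active at `epsilon`, and add exactly `Z`
#' non-core reactions (per confidence group in corda mode).
#'
#' @inheritParams corex
#' @param x_opt Named 0/1 vector over the non-core set (an
#'   `extracted_network` is also accepted).
#' @param Z Added-cardinality target: scalar, or named per-group (`MC`, `NC`,
#'   `OT`) in corda mode. Defaults to `sum(x_opt)` (per group in corda mode).
#' @return An `extracted_network` with an extra field `mismatches`; a
#'   mismatch count of 0 signals that the optimum at this cardinality is
#'   unique.
#' @export
altnet_step <- function(model, core, x_opt, Z = NULL, epsilon = 1e-4,
                        vmax = NULL, spec = solver_spec(feasibility_tol = 1e-9)) {
  if (!inherits(core, "core_set")) core <- core_set(model, core)
  if (inherits(x_opt, "extracted_network")) x_opt <- x_opt$x
  x_opt <- x_opt[model$reaction_ids[core$P]]
  if (anyNA(x_opt)) stop_validation("x_opt must cover the whole non-core set")
  split <- split_reversible(model)
  bl <- op3_build(split, core, epsilon, vmax)
  nP <- length(bl$P)
  # extend with binary mismatch indicators delta+ / delta-
  o_dp <- bl$N; o_dm <- bl$N + nP
  N <- bl$N + 2 * nP
  if (is.null(Z)) {
    Z <- if (core$mode == "corda")
      per_group_Z(x_opt, core$group_of[bl$P]) else sum(x_opt)
  }
  card_rows <- if (core$mode == "corda") {
    lapply(c("MC", "NC", "OT"), function(g) {
      row <- numeric(N)
      row[bl$x_cols[core$group_of[bl$P] == g]] <- 1
      list(row = row, rhs = Z[[g]])
    })
  } else {
    row <- numeric(N); row[bl$x_cols] <- 1
    list(list(row = row, rhs = sum(Z)))
  }
  extra <- length(card_rows) + 2 * nP
  A <- matrix(0, nrow(bl$A) + extra, N)
  A[seq_len(nrow(bl$A)), seq_len(bl$N)] <- bl$A
  rlb <- c(bl$rlb, numeric(extra)); rub <- c(bl$rub, numeric(extra))
  r <- nrow(bl$A)
  for (cr in card_rows) {                 # 10. cardinality conserved
    r <- r + 1; A[r, ] <- cr$row; rlb[r] <- rub[r] <- cr$rhs
  }
  for (k in seq_len(nP)) {                # 11. x + d+ - d- = x_opt
    r <- r + 1
    A[r, bl$x_cols[k]] <- 1; A[r, o_dp + k] <- 1; A[r, o_dm + k] <- -1
    rlb[r] <- rub[r] <- x_opt[[k]]
  }
  for (k in seq_len(nP)) {                # 12. d+ XOR d-
    r <- r + 1; A[r, o_dp + k] <- 1; A[r, o_dm + k] <- 1
    rlb[r] <- -Inf; rub[r] <- 1
  }
  lb <- c(bl$lb, rep(0, 2 * nP)); ub <- c(bl$ub, rep(1, 2 * nP))
  obj <- numeric(N); obj[(bl$N + 1):N] <- 1
  ints <- c(bl$x_cols, bl$y_cols, (bl$N + 1):N)
  res <- af_milp(obj, A, rlb, rub, lb, ub, integer = ints,
                 maximize = TRUE, spec = spec)
  if (res$status == "infeasible")
    stop_solver("alternative-network MILP infeasible: x_opt is not feasible at cardinality %s",
                paste(Z, collapse = "+"))
  if (res$status != "optimal")
    stop_solver("alternative-network MILP did not reach optimality (%s)", res$status)
  net <- network_from_solution(model, split, core, bl, res, epsilon)
  net$mismatches <- as.integer(round(res$objective))
  net
}

#' Enumerate alternative optimal networks (AltNet)
#'
#' Iteratively feeds the maximally-different-network program with each newly
#' found network. On stagnation (a duplicate network or a zero-mismatch
#' result), the last inclusion vector is randomly perturbed by flipping the
#' state of 1% of the non-core reactions (at least one), and the perturbed
#' vector is used as the next anchor only - never stored as a network. The
#' procedure does not guarantee exhaustive enumeration.
#'
#' @inheritParams altnet_step
#' @param x_seed Starting optimal network (an `extracted_network`); when
#'   `NULL`, [corex()] is run first.
#' @param max_iter Bound on both total steps and stagnation events.
#' @param seed Integer seed for the perturbations.
#' @return A `network_ensemble`: `networks` (list of distinct
#'   `extracted_network`s, the seed network first), `X` (binary matrix
#'   networks x non-core), `Z`, `seed`, `log` (iteration events).
#' @export
altnet_enumerate <- function(model, core, x_seed = NULL, epsilon = 1e-4,
                             vmax = NULL, max_iter = 50, seed = 1L,
                             spec = solver_spec(feasibility_tol = 1e-9)) {
  if (!inherits(core, "core_set")) core <- core_set(model, core)
  if (is.null(x_seed)) x_seed <- corex(model, core, epsilon, vmax, spec = spec)
  Z <- x_seed$Z
  networks <- list(x_seed)
  seen <- list(unname(x_seed$x))
  anchor <- x_seed$x
  log <- data.frame(step = integer(0), event = character(0),
                    mismatches = integer(0))
  steps <- 0L; stagnations <- 0L
  withr::with_seed(seed, {
    while (steps < max_iter && stagnations < max_iter) {
      steps <- steps + 1L
      net <- altnet_step(model, core, anchor, Z = Z, epsilon = epsilon,
                         vmax = vmax, spec = spec)
      dup <- any(vapply(seen, function(s) all(s == unname(net$x)), TRUE))
      if (net$mismatches == 0 || dup) {
        stagnations <- stagnations + 1L
        log <- rbind(log, data.frame(step = steps, event = "stagnation",
                                     mismatches = net$mismatches))
        n_flip <- max(1L, ceiling(0.01 * length(core$P)))
        flip <- sample(seq_along(anchor), n_flip)
        anchor[flip] <- 1 - anchor[flip]
      } else {
        networks <- c(networks, list(net))
        seen <- c(seen, list(unname(net$x)))
        anchor <- net$x
        log <- rbind(log, data.frame(step = steps, event = "network",
                                     mismatches = net$mismatches))
      }
    }
  })
  X <- do.call(rbind, lapply(networks, function(n) unname(n$x)))
  colnames(X) <- model$reaction_ids[core$P]
  structure(list(networks = networks, X = X, core = core, Z = Z,
                 seed = seed, log = log),
            class = "network_ensemble")
}

#' @export
print.network_ensemble <- function(x, ...) {
  cat(sprintf("<network_ensemble> %d distinct networks, |P|=%d, Z=%s, seed=%s\n",
              length(x$networks), length(x$core$P),
              paste(x$Z, collapse = "+"), format(x$seed)))
  invisible(x)
}

#' Convert an external context-specific network into an AltNet anchor
#'
#' Takes the inclusion vector of any externally produced context-specific
#' network (e.g. a FastCORE or CORDA output), verifies that all included
#' reactions can simultaneously be active at `epsilon` with the rest shut
#' off, and returns the anchor (`x_opt`, per-group `Z`) for
#' [altnet_step()]/[altnet_enumerate()].
#'
#' @inheritParams corex
#' @param include Logical/integer/character selector of included reactions;
#'   must cover the core.
#' @return List with `x_opt` (named 0/1 over the non-core set) and `Z`
#'   (scalar, or per-group in corda mode).
#' @export
audit_external_network <- function(model, core, include, epsilon = 1e-4,
                                   spec = solver_spec(feasibility_tol = 1e-9)) {
  if (!inherits(core, "core_set")) core <- core_set(model, core)
  inc_idx <- sort(reaction_index(model, include))
  missing_core <- setdiff(core$core, inc_idx)
  if (length(missing_core) > 0)
    stop_validation("network does not cover the core (missing: %s)",
                    paste(model$reaction_ids[missing_core], collapse = ", "))
  if (!subnetwork_feasible(model, inc_idx, epsilon, spec)) {
    # name the included reactions that cannot be active inside the network
    sub <- subset_model(model, inc_idx)
    rng <- tryCatch(fva(sub), error = function(e) NULL)
    bad <- if (is.null(rng)) character(0) else
      rng$reaction_id[pmax(abs(rng$vmin), abs(rng$vmax)) < epsilon]
    stop_validation("external network infeasible at epsilon=%g%s", epsilon,
                    if (length(bad) > 0)
                      sprintf(" (inactive included reactions: %s)",
                              paste(bad, collapse = ", ")) else "")
  }
  x_opt <- stats::setNames(as.numeric(core$P %in% inc_idx),
                           model$reaction_ids[core$P])
  Z <- if (core$mode == "corda")
    per_group_Z(x_opt, core$group_of[core$P]) else sum(x_opt)
  list(x_opt = x_opt, Z = Z)
}
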