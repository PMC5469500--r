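# Least-absolute-deviation data integration (RegrEx-LAD), lambda selection,
# and sampling of the alternative optimal flux distributions (RegrEx-AOS).
#
# Both programs act on the split model (non-negative fluxes, columns ordered
# irreversible | forward | backward). A binary x_j per reversible reaction
# selects its direction: x = 0 keeps the forward column active and pins the
# backward column to zero, x = 1 the converse.

# Variable layout and the shared constraint blocks of the fitting program.
# Variables: [v_irr | v_for | v_back | e+_irr | e-_irr | e+_for | e-_for |
#             e+_back | e-_back | x].
op1_build <- function(split, data, w) {
  n_i <- length(split$irr); n_r <- length(split$rev)
  d <- data$d
  Di <- which(!is.na(d[split$irr]))   # positions within irr block
  Dr <- which(!is.na(d[split$rev]))   # positions within rev block
  nDi <- length(Di); nDr <- length(Dr)
  off <- cumsum(c(vi = 0, vf = n_i, vb = n_r, eip = n_r, eim = nDi,
                  efp = nDi, efm = nDr, ebp = nDr, ebm = nDr, x = nDr))
  N <- off[["x"]] + n_r
  ubf <- split$ub_ext[n_i + seq_len(n_r)]
  ubb <- split$ub_ext[n_i + n_r + seq_len(n_r)]

  m <- nrow(split$S_ext)
  nrows <- m + nDi + 2 * nDr + 2 * n_r
  A <- matrix(0, nrows, N)
  rlb <- rub <- numeric(nrows)
  vcols <- seq_len(n_i + 2 * n_r)
  A[seq_len(m), vcols] <- as.matrix(split$S_ext)      # 1. S_ext v = 0
  r <- m
  d_irr <- d[split$irr][Di]; d_rev <- d[split$rev][Dr]
  for (k in seq_len(nDi)) {                            # 2. irr error balance
    r <- r + 1
    A[r, off[["vi"]] + Di[k]] <- 1
    A[r, off[["eip"]] + k] <- 1; A[r, off[["eim"]] + k] <- -1
    rlb[r] <- rub[r] <- d_irr[k]
  }
  for (k in seq_len(nDr)) {                            # 3. forward error
    r <- r + 1
    A[r, off[["vf"]] + Dr[k]] <- 1
    A[r, off[["efp"]] + k] <- 1; A[r, off[["efm"]] + k] <- -1
    A[r, off[["x"]] + Dr[k]] <- d_rev[k]
    rlb[r] <- rub[r] <- d_rev[k]
  }
  for (k in seq_len(nDr)) {                            # 4. backward error
    r <- r + 1
    A[r, off[["vb"]] + Dr[k]] <- 1
    A[r, off[["ebp"]] + k] <- 1; A[r, off[["ebm"]] + k] <- -1
    A[r, off[["x"]] + Dr[k]] <- -d_rev[k]
    rlb[r] <- rub[r] <- 0
  }
  for (j in seq_len(n_r)) {                            # 8. v_for <= (1-x) ub_f
    r <- r + 1
    A[r, off[["vf"]] + j] <- 1; A[r, off[["x"]] + j] <- ubf[j]
    rlb[r] <- -Inf; rub[r] <- ubf[j]
  }
  for (j in seq_len(n_r)) {                            # 9. v_back <= x ub_b
    r <- r + 1
    A[r, off[["vb"]] + j] <- 1; A[r, off[["x"]] + j] <- -ubb[j]
    rlb[r] <- -Inf; rub[r] <- 0
  }
  lb <- c(split$lb_ext, rep(0, 2 * nDi + 4 * nDr), rep(0, n_r))
  ub <- c(split$ub_ext, rep(Inf, 2 * nDi + 4 * nDr), rep(1, n_r))
  # per-error weights, expanded to the error components
  w_irr <- w[split$irr][Di]; w_rev <- w[split$rev][Dr]
  w_eps <- c(w_irr, w_irr, w_rev, w_rev, w_rev, w_rev)
  list(A = A, rlb = rlb, rub = rub, lb = lb, ub = ub,
       off = off, N = N, n_i = n_i, n_r = n_r, Di = Di, Dr = Dr,
       eps_cols = off[["eip"]] + seq_len(2 * nDi + 4 * nDr),
       x_cols = off[["x"]] + seq_len(n_r),
       v_cols = vcols, w_eps = w_eps)
}

resolve_weights <- function(model, w) {
  n <- length(model$reaction_ids)
  if (is.null(w)) return(rep(1, n))
  if (!is.null(names(w))) {
    full <- rep(1, n)
    full[reaction_index(model, names(w))] <- as.numeric(w)
    w <- full
  }
  if (length(w) != n) stop_validation("weight vector length mismatch")
  if (any(w <= 0)) stop_validation("weights must be positive")
  w
}

#' Fit a context-specific flux distribution to expression data (RegrEx-LAD)
#'
#' Solves the mixed-integer program that minimizes the weighted sum of
#' absolute deviations between the reaction data `d` and the absolute flux
#' values on the data-bounded set, plus an l1 penalty `lambda * ||v||_1`,
#' subject to steady state, flux bounds and directional exclusivity of split
#' reversible reactions.
#'
#' @param model A [metabolic_model()].
#' @param data A [reaction_data()] object.
#' @param lambda Non-negative l1 regularization weight.
#' @param w Optional positive per-reaction error weights (named or
#'   full-length); default all ones.
#' @param spec A [solver_spec()].
#' @return An object of class `regrex_solution`: `v_opt` (original
#'   orientation, named), `v_split`, `eps_plus`/`eps_minus`, `x` (direction
#'   selectors), `objective`, `error_norm` (unweighted sum of error
#'   components), `weighted_error`, `l1_norm`, `lambda`, `gap`.
#' @export
regrex_lad <- function(model, data, lambda = 0, w = NULL,
                       spec = solver_spec()) {
  if (lambda < 0) stop_validation("lambda must be >= 0")
  w <- resolve_weights(model, w)
  split <- split_reversible(model)
  bl <- op1_build(split, data, w)
  obj <- numeric(bl$N)
  obj[bl$eps_cols] <- bl$w_eps
  obj[bl$v_cols] <- obj[bl$v_cols] + lambda
  res <- af_milp(obj, bl$A, bl$rlb, bl$rub, bl$lb, bl$ub,
                 integer = bl$x_cols, spec = spec)
  if (res$status == "infeasible")
    stop_solver("RegrEx-LAD infeasible: model inconsistent")
  if (res$status == "unbounded")
    stop_solver("RegrEx-LAD unbounded: missing flux bounds")
  if (res$status != "optimal")
    stop_solver("RegrEx-LAD did not reach optimality (%s)", res$status)
  z <- res$x
  v_split <- z[bl$v_cols]
  eps_p_cols <- c(bl$off[["eip"]] + seq_along(bl$Di),
                  bl$off[["efp"]] + seq_along(bl$Dr),
                  bl$off[["ebp"]] + seq_along(bl$Dr))
  eps_m_cols <- c(bl$off[["eim"]] + seq_along(bl$Di),
                  bl$off[["efm"]] + seq_along(bl$Dr),
                  bl$off[["ebm"]] + seq_along(bl$Dr))
  eps_plus <- z[eps_p_cols]; eps_minus <- z[eps_m_cols]
  structure(list(
    v_opt = recombine_fluxes(split, v_split),
    v_split = v_split,
    eps_plus = eps_plus, eps_minus = eps_minus,
    x = stats::setNames(z[bl$x_cols], model$reaction_ids[split$rev]),
    objective = res$objective,
    error_norm = sum(z[bl$eps_cols]),
    weighted_error = sum(bl$w_eps * z[bl$eps_cols]),
    l1_norm = sum(v_split),
    lambda = lambda, w = w, gap = res$gap,
    data = data, model_id = model$id),
    class = "regrex_solution")
}

#' @export
print.regrex_solution <- function(x, ...) {
  cat(sprintf("<regrex_solution> lambda=%g objective=%.6g error_norm=%.6g l1_norm=%.6g\n",
              x$lambda, x$objective, x$error_norm, x$l1_norm))
  invisible(x)
}

#' Select the regularization weight by data-flux correlation
#'
#' Solves the fitting program for every lambda on the grid and returns the
#' value maximizing the Pearson correlation between the data and the absolute
#' optimal fluxes on the data-bounded set. A lambda whose fitted fluxes are
#' constant over that set (correlation undefined, e.g. all shrunk to zero) is
#' scored `-Inf`. Ties resolve to the smallest lambda.
#'
#' @inheritParams regrex_lad
#' @param grid Non-empty numeric vector of candidate lambda values.
#' @return List with `lambda` (the selected value), `scores` (data frame:
#'   lambda, correlation, error_norm, l1_norm) and `solutions` (per-lambda
#'   [regrex_lad()] results).
#' @export
select_lambda <- function(model, data, grid, w = NULL, spec = solver_spec()) {
  if (length(grid) == 0) stop_validation("lambda grid is empty")
  grid <- sort(unique(as.numeric(grid)))
  sols <- lapply(grid, function(l) regrex_lad(model, data, l, w, spec))
  dD <- data$d[data$data_bounded]
  score <- vapply(seq_along(grid), function(k) {
    vD <- abs(sols[[k]]$v_opt[data$data_bounded])
    if (stats::sd(vD) == 0 || stats::sd(dD) == 0) {
      message(sprintf("lambda=%g: constant |v| over data-bounded set; correlation undefined",
                      grid[k]))
      return(-Inf)
    }
    stats::cor(dD, vD)
  }, 0)
  best <- which.max(score)   # first maximum = smallest lambda on ties
  list(lambda = grid[best],
       scores = data.frame(lambda = grid, correlation = score,
                           error_norm = vapply(sols, `[[`, 0, "error_norm"),
                           l1_norm = vapply(sols, `[[`, 0, "l1_norm")),
       solutions = sols)
}

#' Sample alternative optimal flux distributions (RegrEx-AOS)
#'
#' Repeats `n` times: (i) draw a random flux vector coordinate-wise uniformly
#' within the bounds-only FVA ranges; (ii) flip the sign of its negative
#' reversible entries together with the matching stoichiometric columns, so
#' every reversible random flux falls in its forward range; (iii) solve the
#' distance-minimization MILP that finds the flux vector closest (l1) to the
#' random draw among those preserving the fitted optimum's total data
#' distance and l1 norm; (iv) flip the flipped entries back.
#'
#' @inheritParams regrex_lad
#' @param solution The [regrex_lad()] optimum being sampled.
#' @param n Number of samples.
#' @param seed Integer seed driving all random draws.
#' @param range Optional precomputed bounds-only [fva()] result.
#' @param spec A [solver_spec()]; defaults to a 1% MIP gap, which is
#'   sufficient since optimality of the distance objective is not needed for
#'   membership in the alternative optima space (the norm-preserving
#'   constraints are hard).
#' @return A `flux_sample` with `provenance = "regrex_aos"`.
#' @export
regrex_aos <- function(model, data, solution, n, seed = 1L, range = NULL,
                       spec = solver_spec(mip_gap = 0.01)) {
  stopifnot(inherits(solution, "regrex_solution"))
  if (is.null(range)) range <- fva(model, spec)
  r <- length(model$reaction_ids)
  V <- matrix(NA_real_, n, r, dimnames = list(NULL, model$reaction_ids))
  E_w <- solution$weighted_error
  L1 <- solution$l1_norm
  w <- solution$w
  withr::with_seed(seed, {
    for (k in seq_len(n)) {
      v_rand <- stats::runif(r, range$vmin, range$vmax)
      v <- aos_one(model, data, w, v_rand, E_w, L1, spec)
      V[k, ] <- v
    }
  })
  flux_sample(V, seed = seed, provenance = "regrex_aos",
              lambda = solution$lambda)
}

# One AOS draw: sign-flip, build the OP_2 extension over the OP_1 blocks,
# solve, recombine and un-flip.
aos_one <- function(model, data, w, v_rand, E_w, L1, spec) {
  flip <- model$reversible & v_rand < 0
  mod2 <- model
  if (any(flip)) {
    mod2$S[, flip] <- -mod2$S[, flip]
    lb_new <- -model$ub[flip]; ub_new <- -model$lb[flip]
    mod2$lb[flip] <- lb_new; mod2$ub[flip] <- ub_new
    mod2$reversible <- mod2$lb < 0
    v_rand[flip] <- -v_rand[flip]
  }
  split <- split_reversible(mod2)
  bl <- op1_build(split, data, w)
  n_i <- bl$n_i; n_r <- bl$n_r; N1 <- bl$N
  # extra distance variables: [d+_irr | d-_irr | d+_for | d-_for | d_back]
  o_dip <- N1; o_dim <- N1 + n_i; o_dfp <- N1 + 2 * n_i
  o_dfm <- o_dfp + n_r; o_db <- o_dfm + n_r
  N <- o_db + n_r
  nr1 <- nrow(bl$A)
  extra <- 2 + n_i + 2 * n_r
  A <- matrix(0, nr1 + extra, N)
  A[seq_len(nr1), seq_len(N1)] <- bl$A
  rlb <- c(bl$rlb, numeric(extra)); rub <- c(bl$rub, numeric(extra))
  r <- nr1
  tol <- spec$feasibility_tol
  # 10. weighted total error preserved
  r <- r + 1
  A[r, bl$eps_cols] <- bl$w_eps
  rlb[r] <- E_w - tol * max(1, abs(E_w)); rub[r] <- E_w + tol * max(1, abs(E_w))
  # 11. total l1 norm preserved
  r <- r + 1
  A[r, bl$v_cols] <- 1
  rlb[r] <- L1 - tol * max(1, abs(L1)); rub[r] <- L1 + tol * max(1, abs(L1))
  vr_irr <- v_rand[split$irr]; vr_rev <- v_rand[split$rev]
  for (q in seq_len(n_i)) {          # 12. v_irr - (d+ - d-) = v_rand
    r <- r + 1
    A[r, bl$off[["vi"]] + q] <- 1
    A[r, o_dip + q] <- -1; A[r, o_dim + q] <- 1
    rlb[r] <- rub[r] <- vr_irr[q]
  }
  for (j in seq_len(n_r)) {          # 13. forward distance, gated by x
    r <- r + 1
    A[r, bl$off[["vf"]] + j] <- 1
    A[r, o_dfp + j] <- -1; A[r, o_dfm + j] <- 1
    A[r, bl$x_cols[j]] <- vr_rev[j]
    rlb[r] <- rub[r] <- vr_rev[j]
  }
  for (j in seq_len(n_r)) {          # 14. backward distance d_back = v_back + x v_rand
    r <- r + 1
    A[r, o_db + j] <- 1
    A[r, bl$off[["vb"]] + j] <- -1
    A[r, bl$x_cols[j]] <- -vr_rev[j]
    rlb[r] <- rub[r] <- 0
  }
  lb <- c(bl$lb, rep(0, N - N1))
  ub <- c(bl$ub, rep(Inf, N - N1))
  obj <- numeric(N)
  obj[(N1 + 1):N] <- 1
  res <- af_milp(obj, A, rlb, rub, lb, ub, integer = bl$x_cols, spec = spec)
  if (res$status != "optimal")
    stop_solver("alternative-optimum MILP %s: the fitted optimum must always be feasible",
                res$status)
  v <- recombine_fluxes(split, res$x[bl$v_cols])
  v[flip] <- -v[flip]
  v
}
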