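# Flux Variability Analysis and unconditioned flux-cone sampling (the
# no-data baseline against which data-conditioned entropies are compared).

#' Flux Variability Analysis
#'
#' For each reaction solves the pair of linear programs
#' min / max v_i subject to S v = 0 and lb <= v <= ub (bounds-only
#' constraints: no reaction is held at a fraction of a prior optimum).
#'
#' @param model A [metabolic_model()].
#' @param spec A [solver_spec()].
#' @return An object of class `flux_range`: data frame with columns
#'   `reaction_id`, `vmin`, `vmax`.
#' @export
fva <- function(model, spec = solver_spec()) {
  validate_model(model)
  n <- length(model$reaction_ids)
  S <- as.matrix(model$S)
  zeros <- rep(0, nrow(S))
  vmin <- vmax <- numeric(n)
  for (i in seq_len(n)) {
    obj <- numeric(n); obj[i] <- 1
    lo <- af_lp(obj, S, zeros, zeros, model$lb, model$ub, spec = spec)
    hi <- af_lp(obj, S, zeros, zeros, model$lb, model$ub, maximize = TRUE,
                spec = spec)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop_solver("FVA infeasible for reaction '%s' (%s): model inconsistent",
                  model$reaction_ids[i], lo$status)
    vmin[i] <- lo$objective; vmax[i] <- hi$objective
  }
  structure(data.frame(reaction_id = model$reaction_ids,
                       vmin = vmin, vmax = vmax),
            class = c("flux_range", "data.frame"),
            constraint_mode = "bounds_only")
}

#' Reduce a model to its consistent part
#'
#' Removes blocked reactions: those whose FVA range satisfies
#' `max(|vmin|, |vmax|) < blocked_tol`. Metabolites left without reactions are
#' dropped. The operation is idempotent.
#'
#' @param model A [metabolic_model()].
#' @param blocked_tol Flux threshold below which a reaction counts as blocked.
#' @param spec A [solver_spec()].
#' @return The reduced [metabolic_model()].
#' @export
reduce_model <- function(model, blocked_tol = 1e-6, spec = solver_spec()) {
  rng <- fva(model, spec)
  keep <- pmax(abs(rng$vmin), abs(rng$vmax)) >= blocked_tol
  if (!any(keep))
    stop_solver("model carries no steady-state flux at all")
  if (all(keep)) return(model)
  subset_model(model, which(keep))
}

#' Sample the flux cone by random projection
#'
#' Iterates `n` times: draw a random flux vector coordinate-wise uniformly
#' within the FVA range, then project it onto the flux cone by solving the
#' quadratic program `min 1/2 ||v - v_rand||^2` s.t. `S v = 0`,
#' `lb <= v <= ub`.
#'
#' @param model A [metabolic_model()].
#' @param n Number of samples.
#' @param seed Integer seed driving all random draws.
#' @param range Optional precomputed [fva()] result.
#' @param spec A [solver_spec()].
#' @return A `flux_sample`: list with `V` (n x reactions matrix), `seed`,
#'   `provenance = "cone"`, `lambda = NULL`, `reaction_ids`.
#' @export
cone_sample <- function(model, n, seed = 1L, range = NULL,
                        spec = solver_spec()) {
  validate_model(model)
  if (n < 0) stop_validation("n must be non-negative")
  if (is.null(range)) range <- fva(model, spec)
  r <- length(model$reaction_ids)
  V <- matrix(NA_real_, n, r, dimnames = list(NULL, model$reaction_ids))
  S <- as.matrix(model$S)
  withr::with_seed(seed, {
    for (k in seq_len(n)) {
      ok <- FALSE
      for (attempt in 1:2) {
        v_rand <- stats::runif(r, range$vmin, range$vmax)
        v <- af_qp_project(S, model$lb, model$ub, v_rand)
        if (!is.null(v)) { V[k, ] <- v; ok <- TRUE; break }
      }
      if (!ok) stop_solver("QP projection failed twice at draw %d", k)
    }
  })
  flux_sample(V, seed = seed, provenance = "cone")
}

flux_sample <- function(V, seed, provenance, lambda = NULL) {
  structure(list(V = V, seed = seed, provenance = provenance,
                 lambda = lambda, reaction_ids = colnames(V)),
            class = "flux_sample")
}

#' @export
print.flux_sample <- function(x, ...) {
  cat(sprintf("<flux_sample> %d samples x %d reactions (%s%s, seed %s)\n",
              nrow(x$V), ncol(x$V), x$provenance,
              if (is.null(x$lambda)) "" else sprintf(", lambda=%g", x$lambda),
              format(x$seed)))
  invisible(x)
}
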