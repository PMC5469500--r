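# Solver-agnostic layer over the HiGHS LP/MILP engine (through SciPy) and the
# quadprog QP solver. All optimization programs in the package are expressed
# as one constraint matrix with two-sided row bounds, variable bounds and an
# optional integrality marker, and funnelled through af_milp().

.af <- new.env(parent = emptyenv())

stop_validation <- function(msg, ...) {
  stop(structure(class = c("ambiflux_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_solver <- function(msg, ...) {
  stop(structure(class = c("ambiflux_solver_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Locate the Python/SciPy optimization backend
#'
#' Lazily initialises the reticulate binding to `scipy.optimize`. The
#' interpreter is pinned to the `python` found on the PATH unless
#' `RETICULATE_PYTHON` is already set, so that no interpreter discovery (which
#' may touch the network) is attempted.
#'
#' @return Invisibly, the `scipy.optimize` module handle.
#' @keywords internal
af_backend <- function() {
  if (!is.null(.af$sp)) return(invisible(.af$sp))
  if (!nzchar(Sys.getenv("RETICULATE_PYTHON"))) {
    py <- Sys.which("python")
    if (!nzchar(py)) py <- Sys.which("python3")
    if (!nzchar(py)) {
      stop(structure(
        class = c("ambiflux_environment_error", "error", "condition"),
        list(message = "no python interpreter on PATH: the HiGHS backend (scipy.optimize) is unavailable",
             call = NULL)))
    }
    Sys.setenv(RETICULATE_PYTHON = py)
  }
  .af$sp <- reticulate::import("scipy.optimize", delay_load = FALSE)
  wrn <- reticulate::import("warnings")
  # HiGHS tolerance options are not in scipy's documented set; they are passed
  # through verbatim and scipy emits a RuntimeWarning each call.
  wrn$filterwarnings("ignore", message = "Unrecognized options")
  invisible(.af$sp)
}

#' Solver parameter specification
#'
#' Bundles the numerical parameters shared by every LP/MILP solve.
#'
#' @param feasibility_tol Primal feasibility tolerance (> 0). The network
#'   extraction programs are solved at `1e-9` by default (see [corex()]);
#'   elsewhere the default is `1e-6`.
#' @param integrality_tol Tolerance within which binary variables must sit at
#'   0/1 before rounding on extraction.
#' @param mip_gap Relative MIP optimality gap in `[0, 1)`. `0` requests a
#'   proven optimum.
#' @param time_limit Wall-clock limit per solve, in seconds.
#' @param seed Optional integer seed forwarded to the solver's internal
#'   randomization, for run-to-run reproducibility.
#' @param threads Number of solver threads; kept at 1 so that MILP
#'   tie-breaking is deterministic.
#' @return An object of class `solver_spec`.
#' @export
solver_spec <- function(feasibility_tol = 1e-6, integrality_tol = 1e-6,
                        mip_gap = 0, time_limit = 300, seed = NULL,
                        threads = 1L) {
  if (feasibility_tol <= 0 || integrality_tol <= 0)
    stop_validation("solver tolerances must be positive")
  if (mip_gap < 0 || mip_gap >= 1)
    stop_validation("mip_gap must lie in [0, 1)")
  structure(list(feasibility_tol = feasibility_tol,
                 integrality_tol = integrality_tol,
                 mip_gap = mip_gap, time_limit = time_limit,
                 seed = seed, threads = as.integer(threads)),
            class = "solver_spec")
}

# Solve  min/max  obj'z  s.t.  row_lb <= A z <= row_ub,  lb <= z <= ub,
# z[integer] in Z. Returns list(status, objective, x, gap).
af_milp <- function(obj, A, row_lb, row_ub, lb, ub, integer = integer(0),
                    maximize = FALSE, spec = solver_spec()) {
  sp <- af_backend()
  n <- length(obj)
  stopifnot(length(lb) == n, length(ub) == n)
  A <- as.matrix(A)
  if (nrow(A) > 0 && ncol(A) != n)
    stop_validation("constraint matrix has %d columns for %d variables",
                    ncol(A), n)
  integrality <- numeric(n)
  integrality[integer] <- 1
  cvec <- if (maximize) -obj else obj
  opts <- list(presolve = TRUE, disp = FALSE, output_flag = FALSE,
               time_limit = spec$time_limit,
               mip_rel_gap = spec$mip_gap,
               primal_feasibility_tolerance = spec$feasibility_tol,
               mip_feasibility_tolerance = max(spec$feasibility_tol, 1e-9),
               threads = spec$threads)
  if (!is.null(spec$seed)) opts$random_seed <- as.integer(spec$seed %% 2147483647)
  cons <- if (nrow(A) > 0) {
    list(sp$LinearConstraint(A, row_lb, row_ub))
  } else list()
  res <- sp$milp(c = cvec, constraints = cons,
                 integrality = integrality,
                 bounds = sp$Bounds(lb, ub),
                 options = opts)
  status <- switch(as.character(res$status),
                   "0" = "optimal", "1" = "iteration_limit",
                   "2" = "infeasible", "3" = "unbounded", "time_limit")
  x <- if (!is.null(res$x)) as.numeric(res$x) else NULL
  if (status == "optimal" && length(integer) > 0) {
    xi <- x[integer]
    if (any(abs(xi - round(xi)) > spec$integrality_tol))
      stop_solver("binary variables not integral within tolerance")
    x[integer] <- round(xi)
  }
  objective <- if (!is.null(res$fun)) (if (maximize) -res$fun else res$fun) else NA_real_
  gap <- tryCatch(as.numeric(res$mip_gap), error = function(e) NA_real_)
  list(status = status, objective = objective, x = x, gap = gap,
       message = res$message)
}

# LP special case (no integer variables).
af_lp <- function(obj, A, row_lb, row_ub, lb, ub, maximize = FALSE,
                  spec = solver_spec()) {
  af_milp(obj, A, row_lb, row_ub, lb, ub, integer = integer(0),
          maximize = maximize, spec = spec)
}

# Euclidean projection onto {v : S v = 0, lb <= v <= ub}:
#   min 1/2 ||v - target||^2.
# Linearly dependent rows of S are dropped (QR with pivoting) because
# quadprog requires consistent, full-rank equality constraints.
af_qp_project <- function(S, lb, ub, target) {
  S <- as.matrix(S)
  n <- ncol(S)
  big <- 1e6
  lb <- pmax(lb, -big)
  ub <- pmin(ub, big)
  if (nrow(S) > 0) {
    qrS <- qr(t(S))
    keep <- qrS$pivot[seq_len(qrS$rank)]
    Seq <- S[keep, , drop = FALSE]
  } else {
    Seq <- matrix(0, 0, n)
  }
  Amat <- t(rbind(Seq, diag(n), -diag(n)))
  bvec <- c(rep(0, nrow(Seq)), lb, -ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = target, Amat = Amat,
                       bvec = bvec, meq = nrow(Seq)),
    error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  sol$solution
}
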