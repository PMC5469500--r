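# Downstream statistics over ensembles of alternative networks: binarization,
# Hamming distances, non-core classification, pathway ambiguity scores and
# the metabolic-task harness.

#' Binarize flux vectors into reaction-inclusion vectors
#'
#' @param x A `flux_sample`, a matrix of flux vectors (rows = samples), or a
#'   single flux vector.
#' @param threshold A reaction counts as present when `|v| >= threshold`.
#' @param dedup Remove repeated rows (when building network sets from
#'   samples).
#' @return A binary matrix (rows = vectors).
#' @export
binarize <- function(x, threshold = 1e-6, dedup = FALSE) {
  V <- if (inherits(x, "flux_sample")) x$V else x
  if (is.null(dim(V))) V <- matrix(V, 1, dimnames = list(NULL, names(V)))
  B <- (abs(V) >= threshold) * 1L
  if (dedup) B <- B[!duplicated(B), , drop = FALSE]
  B
}

#' Hamming distance between two binary vectors
#' @param a,b Equal-length binary vectors.
#' @return The number of mismatching entries.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b))
    stop_validation("vectors of unequal length (%d vs %d)",
                    length(a), length(b))
  sum(abs(a - b))
}

#' Pairwise Hamming distances over an ensemble
#'
#' @param x A `network_ensemble` or a binary matrix (rows = networks).
#' @param n_total Optional total reaction count used for the normalized
#'   distances ("% of model"); defaults to the number of columns.
#' @return List with `D` (distance matrix), `values` (upper-triangle
#'   distances), `max`, `max_pct_P` (max as % of the non-core/columns),
#'   `mean`, `cv`, and normalized (`/ n_total`) variants.
#' @export
hamming_summary <- function(x, n_total = NULL) {
  B <- if (inherits(x, "network_ensemble")) x$X else x
  n <- nrow(B)
  if (is.null(n_total)) n_total <- ncol(B)
  D <- as.matrix(stats::dist(B, method = "manhattan"))
  vals <- D[upper.tri(D)]
  if (length(vals) == 0) vals <- numeric(0)
  mx <- if (length(vals)) max(vals) else 0
  mn <- if (length(vals)) mean(vals) else 0
  list(D = D, values = vals, n_networks = n,
       max = mx, max_pct_P = 100 * mx / ncol(B),
       mean = mn, cv = if (mn > 0) stats::sd(vals) / mn else 0,
       max_norm = mx / n_total, mean_norm = mn / n_total)
}

#' Compare two ensembles' pairwise-distance distributions
#'
#' One-sided rank-sum (Wilcoxon) test between the pairwise Hamming distance
#' distributions of two ensembles; the alternative is that the first
#' distribution is shifted below the second (i.e. the first approach gives
#' more mutually similar alternative networks).
#'
#' @param d1,d2 Numeric distance vectors (e.g. `hamming_summary(e)$values`).
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object.
#' @export
compare_ensembles <- function(d1, d2, alternative = "less") {
  stats::wilcox.test(d1, d2, alternative = alternative, exact = FALSE)
}

#' Classify non-core reactions across an ensemble
#'
#' @param ensemble A `network_ensemble` (or binary matrix over the non-core).
#' @return A `noncore_classification`: `frequency` (named inclusion
#'   fractions), `active` (in all networks), `inactive` (in none) and
#'   `variable` (in some) reaction-id sets.
#' @export
classify_noncore <- function(ensemble) {
  B <- if (inherits(ensemble, "network_ensemble")) ensemble$X else ensemble
  if (nrow(B) == 0) stop_validation("empty ensemble")
  freq <- colMeans(B)
  structure(list(frequency = freq,
                 active = names(freq)[freq == 1],
                 inactive = names(freq)[freq == 0],
                 variable = names(freq)[freq > 0 & freq < 1]),
            class = "noncore_classification")
}

#' @export
print.noncore_classification <- function(x, ...) {
  cat(sprintf("<noncore_classification> active %d | variable %d | inactive %d\n",
              length(x$active), length(x$variable), length(x$inactive)))
  invisible(x)
}

#' Ranked non-core frequency list
#' @param cls A [classify_noncore()] result.
#' @param model Optional [metabolic_model()] supplying subsystem labels.
#' @return Data frame `reaction_id`, `subsystem`, `frequency`, sorted by
#'   decreasing frequency.
#' @export
rank_noncore <- function(cls, model = NULL) {
  out <- data.frame(reaction_id = names(cls$frequency),
                    frequency = unname(cls$frequency))
  out$subsystem <- if (is.null(model)) "" else
    model$subsystem[match(out$reaction_id, model$reaction_ids)]
  out[order(-out$frequency, out$reaction_id),
      c("reaction_id", "subsystem", "frequency")]
}

#' Pathway ambiguity scores
#'
#' For every pathway (subsystem) M, counts its non-core reactions assigned to
#' the active, variable and inactive sets, and scores each count both as a
#' fraction of the total non-core set P (`S_X = X_M / |P|`) and as a fraction
#' of the pathway's own non-core reactions (`X_M / |M intersect P|`). Both
#' normalizations are reported. Reactions without a subsystem label are
#' grouped under `"unassigned"`.
#'
#' @param cls A [classify_noncore()] result.
#' @param model The [metabolic_model()] supplying subsystem labels.
#' @return A data frame with columns `subsystem`, `n_noncore`, `A`, `V`, `I`,
#'   `S_A`, `S_V`, `S_I` (total-non-core normalization) and `S_A_pathway`,
#'   `S_V_pathway`, `S_I_pathway` (per-pathway normalization).
#' @export
pathway_scores <- function(cls, model) {
  ids <- names(cls$frequency)
  sub <- model$subsystem[match(ids, model$reaction_ids)]
  sub[is.na(sub) | !nzchar(sub)] <- "unassigned"
  P <- length(ids)
  cls_of <- ifelse(ids %in% cls$active, "A",
                   ifelse(ids %in% cls$inactive, "I", "V"))
  out <- do.call(rbind, lapply(sort(unique(sub)), function(s) {
    in_s <- sub == s
    A <- sum(in_s & cls_of == "A"); V <- sum(in_s & cls_of == "V")
    I <- sum(in_s & cls_of == "I"); nM <- sum(in_s)
    data.frame(subsystem = s, n_noncore = nM, A = A, V = V, I = I,
               S_A = A / P, S_V = V / P, S_I = I / P,
               S_A_pathway = if (nM > 0) A / nM else 0,
               S_V_pathway = if (nM > 0) V / nM else 0,
               S_I_pathway = if (nM > 0) I / nM else 0)
  }))
  rownames(out) <- NULL
  out
}

# --- metabolic-task harness --------------------------------------------------

#' Read a metabolic-task suite from YAML or JSON
#'
#' Each task has an `id`, a list of `uptakes` (`exchange`, `lb`, `ub`) and a
#' `product` (`exchange`, `min_flux`).
#'
#' @param path Task-suite file (`.yml`/`.yaml` or `.json`).
#' @return A `task_suite`.
#' @export
read_task_suite <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path)
  if (is.null(doc$tasks)) stop_validation("task suite has no 'tasks' element")
  task_suite(doc$tasks)
}

#' Construct a task suite from a list of task definitions
#' @param tasks List of tasks: each a list with `id`, `uptakes` (list of
#'   `list(exchange =, lb =, ub =)`) and `product`
#'   (`list(exchange =, min_flux =)`).
#' @return A `task_suite`.
#' @export
task_suite <- function(tasks) {
  for (t in tasks) {
    if (is.null(t$id) || is.null(t$product) || is.null(t$product$exchange))
      stop_validation("every task needs an id and a product exchange")
  }
  structure(list(tasks = tasks), class = "task_suite")
}

#' Exchange reactions of a model
#'
#' Exchanges are the boundary reactions: columns of S with exactly one
#' non-zero stoichiometric entry.
#' @param model A [metabolic_model()].
#' @return Integer indices of exchange reactions.
#' @export
exchange_reactions <- function(model) {
  which(Matrix::colSums(model$S != 0) == 1)
}

#' Run a metabolic-task suite against a model or extracted network
#'
#' Per task: all exchange reactions are closed, the task's uptake exchanges
#' are opened at their stated bounds, and an LP maximizes the product
#' exchange flux; the task passes iff the optimum reaches the required
#' minimum. When `network` is given, excluded reactions are shut off first.
#'
#' @param model A [metabolic_model()].
#' @param suite A `task_suite`.
#' @param network Optional `extracted_network` (or logical inclusion vector).
#' @param spec A [solver_spec()].
#' @return A `task_report`: data frame `task`, `optimum`, `required`,
#'   `passed`, with attribute `fraction` (share of passed tasks; 1 with a
#'   warning for an empty suite).
#' @export
run_tasks <- function(model, suite, network = NULL, spec = solver_spec()) {
  stopifnot(inherits(suite, "task_suite"))
  ex <- exchange_reactions(model)
  ex_ids <- model$reaction_ids[ex]
  for (t in suite$tasks) {
    refs <- c(vapply(t$uptakes, function(u) as.character(u$exchange), ""),
              t$product$exchange)
    bad <- setdiff(refs, ex_ids)
    if (length(bad) > 0)
      stop_validation("task '%s' references missing exchange(s): %s",
                      t$id, paste(bad, collapse = ", "))
  }
  if (length(suite$tasks) == 0) {
    warning("empty task suite: fraction vacuously 1")
    out <- data.frame(task = character(0), optimum = numeric(0),
                      required = numeric(0), passed = logical(0))
    attr(out, "fraction") <- 1
    class(out) <- c("task_report", "data.frame")
    return(out)
  }
  lb0 <- model$lb; ub0 <- model$ub
  if (!is.null(network)) {
    inc <- if (inherits(network, "extracted_network")) network$include else network
    lb0[!inc] <- 0; ub0[!inc] <- 0
  }
  S <- as.matrix(model$S)
  zeros <- rep(0, nrow(S))
  n <- length(model$reaction_ids)
  rows <- lapply(suite$tasks, function(t) {
    lb <- lb0; ub <- ub0
    lb[ex] <- pmax(lb[ex], 0); ub[ex] <- pmin(ub[ex], 0)  # close all exchanges
    for (u in t$uptakes) {               # reopen allowed uptakes, intersected
      i <- match(u$exchange, model$reaction_ids)         # with network bounds
      lb[i] <- max(lb0[i], as.numeric(u$lb))
      ub[i] <- min(ub0[i],
                   if (is.null(u$ub)) model$ub[i] else as.numeric(u$ub))
      if (lb[i] > ub[i]) { lb[i] <- 0; ub[i] <- 0 }
    }
    ip <- match(t$product$exchange, model$reaction_ids)
    ub[ip] <- ub0[ip]; lb[ip] <- max(lb0[ip], 0)  # reopen the product export
    obj <- numeric(n); obj[ip] <- 1
    res <- af_lp(obj, S, zeros, zeros, lb, ub, maximize = TRUE, spec = spec)
    opt <- if (res$status == "optimal") res$objective else -Inf
    req <- as.numeric(t$product$min_flux)
    data.frame(task = t$id, optimum = opt, required = req,
               passed = is.finite(opt) && opt >= req - spec$feasibility_tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "fraction") <- mean(out$passed)
  class(out) <- c("task_report", "data.frame")
  out
}

#' Filter an ensemble to the networks passing all tasks
#'
#' Requiring alternative networks to fulfil the metabolic tasks adds an
#' implicit constraint, so the variable non-core set of the filtered
#' ensemble can only shrink.
#'
#' @param ensemble A `network_ensemble`.
#' @param model The underlying [metabolic_model()].
#' @param suite A `task_suite`.
#' @param spec A [solver_spec()].
#' @return A `network_ensemble` containing the passing networks.
#' @export
filter_ensemble <- function(ensemble, model, suite, spec = solver_spec()) {
  keep <- vapply(ensemble$networks, function(net) {
    rep <- run_tasks(model, suite, network = net, spec = spec)
    all(rep$passed)
  }, TRUE)
  networks <- ensemble$networks[keep]
  out <- ensemble
  out$networks <- networks
  out$X <- ensemble$X[keep, , drop = FALSE]
  out$log <- rbind(ensemble$log,
                   data.frame(step = NA_integer_, event = "task_filter",
                              mismatches = sum(!keep)))
  out
}
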