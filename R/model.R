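# The metabolic model container: stoichiometry, flux bounds, reversibility,
# gene-protein-reaction (GPR) rules and pathway (subsystem) labels.

#' Construct a metabolic model
#'
#' @param reaction_ids Character vector of unique reaction identifiers.
#' @param metabolite_ids Character vector of unique (internal) metabolite
#'   identifiers; one row of `S` per metabolite.
#' @param S Stoichiometric matrix (metabolites x reactions); dense or sparse.
#' @param lb,ub Per-reaction flux bounds. `NA`/infinite entries are replaced
#'   by `-default_bound` / `default_bound`.
#' @param gpr Per-reaction GPR rule strings (boolean expressions over gene
#'   ids, e.g. `"g1 and (g2 or g3)"`); `""` for reactions without one.
#' @param subsystem Per-reaction pathway label; `""` when unassigned.
#' @param id Model identifier.
#' @param default_bound Magnitude used for missing/unbounded flux bounds
#'   (conventional COBRA default 1000); this constant also serves as the
#'   big-M bound in the mixed-integer programs downstream.
#'
#' @details Reversibility is defined by the bounds: a reaction is reversible
#'   iff `lb < 0`. When an input format carries an explicit reversible flag
#'   that disagrees with the bounds, the bounds win, since they define the
#'   feasible flux cone.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reaction_ids, metabolite_ids, S, lb, ub,
                            gpr = NULL, subsystem = NULL, id = "model",
                            default_bound = 1000) {
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "dMatrix"),
                   "CsparseMatrix")
  n <- length(reaction_ids)
  m <- length(metabolite_ids)
  if (is.null(gpr)) gpr <- rep("", n)
  if (is.null(subsystem)) subsystem <- rep("", n)
  lb <- as.numeric(lb); ub <- as.numeric(ub)
  lb[!is.finite(lb)] <- -default_bound
  ub[!is.finite(ub)] <- default_bound
  model <- structure(list(id = id, reaction_ids = as.character(reaction_ids),
                          metabolite_ids = as.character(metabolite_ids),
                          S = S, lb = lb, ub = ub,
                          reversible = lb < 0,
                          gpr = as.character(gpr),
                          subsystem = as.character(subsystem),
                          default_bound = default_bound),
                     class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model's invariants
#'
#' Checks dimensional consistency, bound ordering and identifier uniqueness;
#' raises a validation error describing the first violated invariant.
#'
#' @param model A [metabolic_model()].
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  n <- length(model$reaction_ids)
  m <- length(model$metabolite_ids)
  if (ncol(model$S) != n)
    stop_validation("S has %d columns but there are %d reactions",
                    ncol(model$S), n)
  if (nrow(model$S) != m)
    stop_validation("S has %d rows but there are %d metabolites",
                    nrow(model$S), m)
  for (f in c("lb", "ub", "reversible", "gpr", "subsystem"))
    if (length(model[[f]]) != n)
      stop_validation("field '%s' has length %d, expected %d",
                      f, length(model[[f]]), n)
  bad <- which(model$lb > model$ub)
  if (length(bad) > 0)
    stop_validation("lb > ub for reaction '%s'", model$reaction_ids[bad[1]])
  if (anyDuplicated(model$reaction_ids))
    stop_validation("duplicated reaction ids")
  if (anyDuplicated(model$metabolite_ids))
    stop_validation("duplicated metabolite ids")
  if (!identical(model$reversible, model$lb < 0))
    stop_validation("reversible flags inconsistent with bounds")
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s: %d reactions, %d metabolites (%d reversible)\n",
              x$id, length(x$reaction_ids), length(x$metabolite_ids),
              sum(x$reversible)))
  invisible(x)
}

#' Extract a submodel containing a subset of reactions
#'
#' Metabolites that no longer participate in any retained reaction are
#' dropped.
#'
#' @param model A [metabolic_model()].
#' @param keep Integer/logical index or character vector of reaction ids.
#' @return A [metabolic_model()].
#' @export
subset_model <- function(model, keep) {
  idx <- reaction_index(model, keep)
  S <- model$S[, idx, drop = FALSE]
  used <- Matrix::rowSums(S != 0) > 0
  metabolic_model(model$reaction_ids[idx], model$metabolite_ids[used],
                  S[used, , drop = FALSE],
                  model$lb[idx], model$ub[idx], model$gpr[idx],
                  model$subsystem[idx], id = model$id,
                  default_bound = model$default_bound)
}

# Resolve a reaction selector (ids, logical, or integer) to integer indices.
reaction_index <- function(model, sel) {
  if (is.character(sel)) {
    idx <- match(sel, model$reaction_ids)
    if (anyNA(idx))
      stop_validation("unknown reaction id(s): %s",
                      paste(sel[is.na(idx)], collapse = ", "))
    idx
  } else if (is.logical(sel)) {
    which(sel)
  } else {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > length(model$reaction_ids)))
      stop_validation("reaction index out of range")
    sel
  }
}
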