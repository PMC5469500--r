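# Splitting reversible reactions into forward/backward components with
# non-negative fluxes, and recombining split fluxes.

#' Split reversible reactions into forward and backward directions
#'
#' Produces the extended model used by all mixed-integer programs: columns are
#' ordered irreversible | forward | backward; forward columns keep the
#' original orientation with bounds `[0, ub]`, backward columns are the
#' negated originals with bounds `[0, -lb]`.
#'
#' @param model A [metabolic_model()].
#' @return An object of class `split_model` with fields `S_ext`, `lb_ext`,
#'   `ub_ext`, `irr`/`rev` (original indices), `col_origin` (original reaction
#'   index per extended column), `col_part` (`"irr"|"for"|"back"`) and
#'   `origin` (the source model).
#' @export
split_reversible <- function(model) {
  validate_model(model)
  irr <- which(!model$reversible)
  rev <- which(model$reversible)
  S_ext <- cbind(model$S[, irr, drop = FALSE],
                 model$S[, rev, drop = FALSE],
                 -model$S[, rev, drop = FALSE])
  lb_ext <- c(pmax(model$lb[irr], 0), rep(0, 2 * length(rev)))
  ub_ext <- c(model$ub[irr], model$ub[rev], -model$lb[rev])
  structure(list(S_ext = S_ext, lb_ext = lb_ext, ub_ext = ub_ext,
                 irr = irr, rev = rev,
                 col_origin = c(irr, rev, rev),
                 col_part = rep(c("irr", "for", "back"),
                                c(length(irr), length(rev), length(rev))),
                 origin = model),
            class = "split_model")
}

#' @export
print.split_model <- function(x, ...) {
  cat(sprintf("<split_model> %d columns (%d irreversible + 2 x %d reversible)\n",
              ncol(x$S_ext), length(x$irr), length(x$rev)))
  invisible(x)
}

#' Recombine a split flux vector into the original orientation
#'
#' @param split A [split_reversible()] result.
#' @param v_ext Flux vector over the extended columns.
#' @return Flux vector over the original reactions
#'   (`v[rev] = v_for - v_back`), named by reaction id.
#' @export
recombine_fluxes <- function(split, v_ext) {
  n_i <- length(split$irr); n_r <- length(split$rev)
  stopifnot(length(v_ext) == n_i + 2 * n_r)
  v <- numeric(length(split$origin$reaction_ids))
  v[split$irr] <- v_ext[seq_len(n_i)]
  v[split$rev] <- v_ext[n_i + seq_len(n_r)] - v_ext[n_i + n_r + seq_len(n_r)]
  stats::setNames(v, split$origin$reaction_ids)
}
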