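# Shannon-entropy quantification of alternative-optima uncertainty and the
# fixed-direction fraction of reversible reactions.

#' Shannon entropy of sampled flux distributions
#'
#' Per reaction, sampled flux values are binned into `n_bins` equally spaced
#' intervals spanning that reaction's sampled range, and the entropy
#' `H_i = -sum_k f_ik log(f_ik)` (natural log, nats; `0 log 0 = 0`) of the
#' bin frequencies is computed. A constant column (zero-width range) has
#' `H = 0`. Group totals over the data-bounded/data-orphan partition and the
#' mean entropy are reported alongside.
#'
#' @param sample A `flux_sample` (from [cone_sample()] or [regrex_aos()]).
#' @param n_bins Number of bins (default 20, so `max H = log(20)`).
#' @param data Optional [reaction_data()] giving the data-bounded/orphan
#'   partition for the group sums.
#' @param range `"sample"` bins within the sampled min/max per reaction (the
#'   default); `"fva"` bins within the FVA range, in which case `model` must
#'   be given.
#' @param model Required when `range = "fva"`.
#' @param spec A [solver_spec()] (FVA range only).
#' @return An `entropy_report`: list with `H` (named per-reaction entropies),
#'   `n_bins`, `H_Data`, `H_Orphan`, `H_Total`, `H_mean`.
#' @export
flux_entropy <- function(sample, n_bins = 20, data = NULL,
                         range = c("sample", "fva"), model = NULL,
                         spec = solver_spec()) {
  range <- match.arg(range)
  if (n_bins < 2) stop_validation("n_bins must be at least 2")
  V <- sample$V
  if (nrow(V) == 0) stop_validation("empty flux sample")
  if (range == "fva") {
    if (is.null(model)) stop_validation("range = 'fva' requires the model")
    rng <- fva(model, spec)
    lo <- rng$vmin; hi <- rng$vmax
  } else {
    lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  }
  H <- vapply(seq_len(ncol(V)), function(i)
    bin_entropy(V[, i], lo[i], hi[i], n_bins), 0)
  names(H) <- colnames(V)
  H_Data <- H_Orphan <- NA_real_
  if (!is.null(data)) {
    H_Data <- sum(H[data$data_bounded])
    H_Orphan <- sum(H[data$data_orphan])
  }
  structure(list(H = H, n_bins = n_bins,
                 H_Data = H_Data, H_Orphan = H_Orphan,
                 H_Total = sum(H), H_mean = mean(H)),
            class = "entropy_report")
}

bin_entropy <- function(v, lo, hi, n_bins) {
  width <- hi - lo
  if (width <= 0) return(0)
  idx <- pmin(pmax(floor((v - lo) / width * n_bins) + 1L, 1L), n_bins)
  f <- tabulate(idx, n_bins) / length(v)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' @export
print.entropy_report <- function(x, ...) {
  cat(sprintf("<entropy_report> %d reactions, %d bins\n", length(x$H), x$n_bins))
  cat(sprintf("  H_Data=%.4g  H_Orphan=%.4g  H_Total=%.4g  H_mean=%.4g\n",
              x$H_Data, x$H_Orphan, x$H_Total, x$H_mean))
  invisible(x)
}

#' Fixed-direction fraction of reversible reactions
#'
#' Restricts to reversible reactions carrying a non-zero flux somewhere in
#' the sample (`max |v| >= active_tol`); such a reaction has a fixed
#' direction if all its above-threshold sampled values share one sign.
#'
#' @param sample A `flux_sample`.
#' @param model The sampled [metabolic_model()].
#' @param active_tol Activity threshold (matches the binarization threshold).
#' @return List with `fraction` (`NA` with a warning when no reversible
#'   reaction qualifies), `fixed` (named logical over qualifying reversible
#'   reactions) and `n_active`.
#' @export
fixed_direction <- function(sample, model, active_tol = 1e-6) {
  V <- sample$V
  if (nrow(V) == 0) stop_validation("empty flux sample")
  rev <- which(model$reversible)
  active <- rev[apply(abs(V[, rev, drop = FALSE]), 2, max) >= active_tol]
  if (length(active) == 0) {
    warning("no reversible reaction carries flux above active_tol; fraction undefined")
    return(list(fraction = NA_real_, fixed = logical(0), n_active = 0L))
  }
  fixed <- vapply(active, function(i) {
    v <- V[, i]
    v <- v[abs(v) >= active_tol]
    all(v > 0) || all(v < 0)
  }, TRUE)
  names(fixed) <- model$reaction_ids[active]
  list(fraction = mean(fixed), fixed = fixed, n_active = length(active))
}
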