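# GPR rule parsing/evaluation and mapping of gene expression to reactions.

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean expression over gene ids (operators `and`/`or`, case
#' insensitive, `&`/`&&` and `|`/`||` accepted, parentheses allowed) into an
#' expression tree.
#'
#' @param rule GPR string; `""` gives `NULL` (no rule).
#' @return `NULL`, or a tree of nested lists: leaves `list(gene = "g1")`,
#'   internal nodes `list(op = "and"|"or", args = list(...))`.
#' @export
parse_gpr <- function(rule) {
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokens(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop_validation("trailing input in GPR rule '%s'", rule)
  tree
}

gpr_tokens <- function(rule) {
  s <- gsub("([()])", " \\1 ", rule)
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
gpr_next <- function(st) { t <- gpr_peek(st); st$pos <- st$pos + 1L; t }

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_next(st)
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_next(st)
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  t <- gpr_next(st)
  if (is.na(t)) stop_validation("unexpected end of GPR rule")
  if (t == "(") {
    e <- gpr_parse_or(st)
    if (!identical(gpr_next(st), ")"))
      stop_validation("unbalanced parentheses in GPR rule")
    return(e)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop_validation("unexpected token '%s' in GPR rule", t)
  list(gene = t)
}

#' Evaluate a parsed GPR rule against gene values
#'
#' `and` nodes combine with `and_fun` (default `min`, enzyme-complex
#' semantics) and `or` nodes with `or_fun` (default `max`, isoenzyme
#' semantics). Genes without a value evaluate to `NA` and are dropped at each
#' operator; a node whose children are all `NA` is `NA`.
#'
#' @param tree Result of [parse_gpr()].
#' @param values Named numeric vector of gene values.
#' @param and_fun,or_fun Combining functions.
#' @return A single numeric value, or `NA` if no referenced gene is measured.
#' @export
eval_gpr <- function(tree, values, and_fun = min, or_fun = max) {
  if (is.null(tree)) return(NA_real_)
  if (!is.null(tree$gene)) {
    v <- unname(values[tree$gene])
    return(if (length(v) == 0 || is.na(v)) NA_real_ else v)
  }
  kids <- vapply(tree$args, eval_gpr, 0, values = values,
                 and_fun = and_fun, or_fun = or_fun)
  kids <- kids[!is.na(kids)]
  if (length(kids) == 0) return(NA_real_)
  f <- if (tree$op == "and") and_fun else or_fun
  f(kids)
}

#' Genes referenced by a model's GPR rules
#' @param model A [metabolic_model()].
#' @return Character vector of unique gene ids.
#' @export
model_genes <- function(model) {
  leaves <- function(tr) {
    if (is.null(tr)) return(character(0))
    if (!is.null(tr$gene)) return(tr$gene)
    unlist(lapply(tr$args, leaves))
  }
  unique(unlist(lapply(model$gpr, function(g) leaves(parse_gpr(g)))))
}

#' Map gene expression to reaction data through GPR rules
#'
#' Per replicate, expression values are scaled to the replicate maximum and
#' each reaction's GPR rule is evaluated against the scaled values; replicate
#' means are then taken as the representative per-reaction values. Reactions
#' with no GPR, or whose GPR references only unmeasured genes, form the
#' data-orphan set.
#'
#' @param model A [metabolic_model()].
#' @param expr A data frame with columns `gene_id` and `value` (one
#'   replicate), or a list of such data frames (replicates).
#' @param and_fun,or_fun GPR combining functions (see [eval_gpr()]).
#' @return An object of class `reaction_data`: list with `d` (full-length
#'   numeric, `NA` on orphans), `data_bounded` and `data_orphan` (integer
#'   index sets) and `reaction_ids`.
#' @export
map_expression_to_reactions <- function(model, expr, and_fun = min,
                                        or_fun = max) {
  if (is.data.frame(expr)) expr <- list(expr)
  if (length(expr) < 1) stop_validation("no expression replicates supplied")
  trees <- lapply(model$gpr, parse_gpr)
  genes <- model_genes(model)
  vals <- matrix(NA_real_, length(trees), length(expr))
  seen_overlap <- FALSE
  for (k in seq_along(expr)) {
    tab <- expr[[k]]
    if (!all(c("gene_id", "value") %in% names(tab)))
      stop_validation("expression table must have columns gene_id and value")
    if (anyDuplicated(tab$gene_id))
      stop_validation("duplicated gene id in expression table (one value per gene required)")
    if (any(tab$value < 0, na.rm = TRUE))
      stop_validation("negative expression value")
    v <- stats::setNames(as.numeric(tab$value), as.character(tab$gene_id))
    v <- v[!is.na(v)]
    if (any(names(v) %in% genes)) seen_overlap <- TRUE
    if (length(v) > 0 && max(v) > 0) v <- v / max(v)
    vals[, k] <- vapply(trees, eval_gpr, 0, values = v,
                        and_fun = and_fun, or_fun = or_fun)
  }
  if (!seen_overlap)
    stop_validation("no overlap between expression gene ids and model GPR genes")
  d <- rowMeans(vals, na.rm = TRUE)
  d[is.nan(d)] <- NA_real_
  reaction_data(model, d)
}

#' Construct reaction data from per-reaction values
#'
#' @param model A [metabolic_model()].
#' @param d Numeric vector over all reactions (`NA` = data-orphan), or a named
#'   vector over a subset of reaction ids.
#' @return An object of class `reaction_data`.
#' @export
reaction_data <- function(model, d) {
  n <- length(model$reaction_ids)
  if (!is.null(names(d)) && length(d) != n) {
    full <- rep(NA_real_, n)
    idx <- reaction_index(model, names(d))
    full[idx] <- as.numeric(d)
    d <- full
  }
  if (length(d) != n)
    stop_validation("reaction data length %d does not match %d reactions",
                    length(d), n)
  if (any(d < 0, na.rm = TRUE))
    stop_validation("reaction data values must be non-negative")
  structure(list(d = as.numeric(d),
                 data_bounded = which(!is.na(d)),
                 data_orphan = which(is.na(d)),
                 reaction_ids = model$reaction_ids),
            class = "reaction_data")
}

#' @export
print.reaction_data <- function(x, ...) {
  cat(sprintf("<reaction_data> %d data-bounded, %d data-orphan reactions\n",
              length(x$data_bounded), length(x$data_orphan)))
  invisible(x)
}

#' Export reaction data as a data frame
#' @param x A [reaction_data()] object.
#' @param ... Unused.
#' @return Data frame with `reaction_id`, `d`, `is_data_bounded`.
#' @export
as.data.frame.reaction_data <- function(x, ...) {
  data.frame(reaction_id = x$reaction_ids, d = x$d,
             is_data_bounded = !is.na(x$d))
}
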