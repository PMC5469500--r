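# Model reading and writing: a cobrapy-shaped JSON dialect (the round-trip
# format) and SBML Level 3 with the FBC extension (read-only).

#' Read a metabolic model from JSON or SBML
#'
#' @param path Path to the model file.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension;
#'   `.xml`/`.sbml` is SBML, anything else JSON).
#' @param default_bound Replacement magnitude for missing/unbounded bounds.
#' @return A [metabolic_model()].
#'
#' @details The JSON dialect mirrors the cobrapy JSON schema: a top-level
#'   object with `id`, a `metabolites` array of `{id}` objects and a
#'   `reactions` array of
#'   `{id, metabolites: {<metabolite>: <coefficient>}, lower_bound,
#'   upper_bound, gene_reaction_rule, subsystem}` objects. For SBML, flux
#'   bounds are taken from the FBC `lowerFluxBound`/`upperFluxBound`
#'   parameters, GPRs from `geneProductAssociation` trees and boundary-condition
#'   species are excluded from the mass-balance rows.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml"),
                       default_bound = 1000) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_validation("model file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE))
      "sbml" else "json"
  }
  if (format == "json") read_model_json(path, default_bound)
  else read_model_sbml(path, default_bound)
}

read_model_json <- function(path, default_bound = 1000) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop_validation("cannot parse JSON model '%s': %s",
                                    path, conditionMessage(e)))
  for (f in c("metabolites", "reactions"))
    if (is.null(doc[[f]]))
      stop_validation("JSON model missing required element '%s'", f)
  met_ids <- vapply(doc$metabolites, function(m) as.character(m$id), "")
  rxns <- doc$reactions
  rids <- vapply(rxns, function(r) as.character(r$id), "")
  n <- length(rids); m <- length(met_ids)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]$metabolites
    if (length(st) == 0) next
    i <- match(names(st), met_ids)
    if (anyNA(i))
      stop_validation("reaction '%s' references unknown metabolite '%s'",
                      rids[j], names(st)[which(is.na(i))[1]])
    trip$i <- c(trip$i, i)
    trip$j <- c(trip$j, rep(j, length(i)))
    trip$x <- c(trip$x, vapply(st, as.numeric, 0))
  }
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(m, n))
  num_or <- function(v, d) if (is.null(v)) d else as.numeric(v)
  chr_or <- function(v) if (is.null(v)) "" else as.character(v)
  metabolic_model(
    rids, met_ids, S,
    lb = vapply(rxns, function(r) num_or(r$lower_bound, -default_bound), 0),
    ub = vapply(rxns, function(r) num_or(r$upper_bound, default_bound), 0),
    gpr = vapply(rxns, function(r) chr_or(r$gene_reaction_rule), ""),
    subsystem = vapply(rxns, function(r) chr_or(r$subsystem), ""),
    id = if (is.null(doc$id)) "model" else as.character(doc$id),
    default_bound = default_bound)
}

#' Write a metabolic model to the JSON dialect
#'
#' `read_model(write_model(m))` reproduces `m` exactly.
#'
#' @param model A [metabolic_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    col <- model$S[, j]
    nz <- which(col != 0)
    st <- as.list(col[nz])
    names(st) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j], metabolites = st,
         lower_bound = model$lb[j], upper_bound = model$ub[j],
         gene_reaction_rule = model$gpr[j], subsystem = model$subsystem[j])
  })
  doc <- list(id = model$id,
              metabolites = lapply(model$metabolite_ids, function(m) list(id = m)),
              reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# --- SBML L3 + FBC -----------------------------------------------------------

read_model_sbml <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop_validation("cannot parse SBML file '%s': %s",
                                    path, conditionMessage(e)))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]],
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop_validation("SBML file '%s' has no <model> element", path)

  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  boundary <- xml2::xml_attr(sp, "boundaryCondition") %in% c("true", "1")
  met_ids <- sp_id[!boundary]

  par <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                             xml2::xml_attr(par, "id"))

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))
  gp_label[is.na(gp_label)] <- names(gp_label)[is.na(gp_label)]

  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx) == 0) stop_validation("SBML model has no reactions")
  rids <- xml2::xml_attr(rx, "id")
  n <- length(rids); m <- length(met_ids)
  lb <- ub <- numeric(n); gpr <- character(n)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (j in seq_along(rx)) {
    r <- rx[[j]]
    lbid <- xml2::xml_attr(r, "lowerFluxBound")
    ubid <- xml2::xml_attr(r, "upperFluxBound")
    lb[j] <- if (!is.na(lbid) && lbid %in% names(par_val)) par_val[[lbid]] else -default_bound
    ub[j] <- if (!is.na(ubid) && ubid %in% names(par_val)) par_val[[ubid]] else default_bound
    # reversible attribute is informative only; bounds define the cone
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, sprintf("./s:%s/s:speciesReference", side), ns)
      if (length(refs) == 0) next
      sps <- xml2::xml_attr(refs, "species")
      sto <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      sto[is.na(sto)] <- 1
      if (side == "listOfReactants") sto <- -sto
      ii <- match(sps, met_ids)
      keep <- !is.na(ii)   # boundary species do not enter mass balance
      if (any(is.na(ii) & !(sps %in% sp_id)))
        stop_validation("reaction '%s' references undeclared species '%s'",
                        rids[j], sps[which(is.na(ii) & !(sps %in% sp_id))[1]])
      trip$i <- c(trip$i, ii[keep]); trip$j <- c(trip$j, rep(j, sum(keep)))
      trip$x <- c(trip$x, sto[keep])
    }
    ga <- xml2::xml_find_first(r, "./fbc:geneProductAssociation/*", ns)
    gpr[j] <- if (inherits(ga, "xml_missing")) "" else sbml_gpr_string(ga, ns, gp_label)
  }
  S <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x, dims = c(m, n))
  metabolic_model(rids, met_ids, S, lb, ub, gpr = gpr,
                  id = xml2::xml_attr(mdl, "id"),
                  default_bound = default_bound)
}

sbml_gpr_string <- function(node, ns, gp_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(if (ref %in% names(gp_label)) gp_label[[ref]] else ref)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpr_string, "", ns = ns, gp_label = gp_label)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}
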