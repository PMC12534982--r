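# Model I/O: COBRA-style JSON (read/write, the canonical fixture dialect)
# and SBML Level-3 FBC (read-only).

#' Load a metabolic model from file
#'
#' @param path file path.
#' @param dialect `"cobra-json"` (COBRA-style JSON) or `"sbml-fbc"`
#'   (SBML Level 3 with the FBC extension, read-only).
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, dialect = c("cobra-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  switch(dialect,
         "cobra-json" = .read_cobra_json(path),
         "sbml-fbc" = .read_sbml_fbc(path))
}

#' Write a metabolic model to COBRA-style JSON
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lb,
         upper_bound = r$ub,
         gene_reaction_rule = r$gpr,
         objective_coefficient = if (identical(r$id, model$objective)) 1 else 0,
         is_sink = r$is_sink)
  })
  doc <- list(
    metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
      as.list(model$metabolites[i, c("id", "name", "compartment")])
    }),
    reactions = unname(rxns),
    genes = lapply(model$genes, function(g) list(id = g)),
    objective = model$objective)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.read_cobra_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("cannot parse COBRA JSON '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("COBRA JSON '", path, "' lacks 'metabolites' or 'reactions'")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("COBRA JSON metabolite without 'id'")
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               stringsAsFactors = FALSE)
  }))
  objective <- doc$objective
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("COBRA JSON reaction without 'id'")
    if (is.null(r$metabolites)) {
      stop("COBRA JSON reaction '", r$id, "' lacks 'metabolites' stoichiometry")
    }
    list(id = r$id,
         stoichiometry = unlist(r$metabolites),
         lb = if (is.null(r$lower_bound)) -1000 else r$lower_bound,
         ub = if (is.null(r$upper_bound)) 1000 else r$upper_bound,
         gpr = if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule,
         is_sink = isTRUE(r$is_sink))
  })
  if (is.null(objective)) {
    oc <- vapply(doc$reactions, function(r) {
      if (is.null(r$objective_coefficient)) 0 else as.numeric(r$objective_coefficient)
    }, numeric(1))
    if (!any(oc != 0)) stop("COBRA JSON '", path, "' declares no objective")
    objective <- rxns[[which(oc != 0)[1]]]$id
  }
  genes <- vapply(doc$genes, function(g) as.character(g$id), character(1))
  declared <- unique(unlist(lapply(rxns, function(r) gpr_genes(r$gpr))))
  unknown <- setdiff(declared, genes)
  if (length(genes) && length(unknown)) {
    stop("GPR rules reference genes absent from the gene list: ",
         paste(unknown, collapse = ", "))
  }
  if (!length(genes)) genes <- declared
  metabolic_model(mets, rxns, objective, genes)
}

# SBML Level-3 FBC reader: species, reactions with speciesReference
# stoichiometry, fbc bound parameters, geneProductAssociation trees and the
# active fbc objective.
.read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))
  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gps, "label"),
                              xml2::xml_attr(gps, "id"))
  species <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  mets <- data.frame(
    id = xml2::xml_attr(species, "id"),
    name = ifelse(is.na(xml2::xml_attr(species, "name")),
                  xml2::xml_attr(species, "id"),
                  xml2::xml_attr(species, "name")),
    compartment = xml2::xml_attr(species, "compartment"),
    stringsAsFactors = FALSE)

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rxns <- lapply(rnodes, function(rn) {
    rid <- xml2::xml_attr(rn, "id")
    sub <- xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)
    prod <- xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)
    sto <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(sub, "stoichiometry")),
                      xml2::xml_attr(sub, "species")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "species")))
    sto <- tapply(sto, names(sto), sum)  # merge duplicated species refs
    sto <- sto[sto != 0]
    lb_id <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_id <- xml2::xml_attr(rn, "upperFluxBound")
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation/*", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      .gpr_deparse(.sbml_gpa_tree(gpa, gp_label, ns))
    }
    list(id = rid,
         stoichiometry = stats::setNames(as.numeric(sto), names(sto)),
         lb = if (is.na(lb_id)) -1000 else pval[[lb_id]],
         ub = if (is.na(ub_id)) 1000 else pval[[ub_id]],
         gpr = gpr, is_sink = FALSE)
  })

  fo <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(fo, "xml_missing")) stop("SBML '", path, "' declares no FBC objective")
  objective <- xml2::xml_attr(fo, "reaction")
  genes <- unname(gp_label)
  if (!length(genes)) genes <- NULL
  metabolic_model(mets, rxns, objective, genes)
}

.sbml_gpa_tree <- function(node, gp_label, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    lab <- if (ref %in% names(gp_label)) gp_label[[ref]] else ref
    return(list(op = "gene", gene = lab))
  }
  kids <- lapply(xml2::xml_children(node), .sbml_gpa_tree,
                 gp_label = gp_label, ns = ns)
  if (length(kids) == 0L) stop("SBML gene association node '", nm, "' is empty")
  op <- switch(nm, "and" = "and", "or" = "or",
               stop("unsupported gene association node '", nm, "'"))
  list(op = op, children = kids)
}
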