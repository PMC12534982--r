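# Constraint-based metabolic model container and curation operations:
# dead-end metabolite detection/pruning and sink-reaction insertion.

#' Construct a constraint-based metabolic model
#'
#' A metabolic model holds a stoichiometric network with flux bounds
#' (mmol/gDW/h), GPR rules linking genes to reactions, and a biomass
#' objective reaction. Reversibility is encoded solely by `lb < 0`.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions list of reactions, each a list with `id`,
#'   `stoichiometry` (named numeric, metabolite id -> signed coefficient),
#'   `lb`, `ub`, optional `gpr` (rule text, "" for none) and `is_sink`.
#' @param objective id of the biomass (objective) reaction.
#' @param genes character vector of gene ids; defaults to the union of all
#'   GPR leaves.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, objective, genes = NULL) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- lapply(reactions, function(r) {
    r$gpr <- if (is.null(r$gpr) || is.na(r$gpr)) "" else as.character(r$gpr)
    r$is_sink <- isTRUE(r$is_sink)
    r$lb <- as.numeric(r$lb)
    r$ub <- as.numeric(r$ub)
    r$stoichiometry <- unlist(r$stoichiometry)
    r
  })
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr))))
    if (is.null(genes)) genes <- character(0)
  }
  m <- structure(
    list(metabolites = metabolites, reactions = reactions,
         objective = objective, genes = sort(unique(genes))),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, non-empty compartments, bound ordering, non-empty
#' finite stoichiometries, that every referenced metabolite exists, that the
#' objective reaction exists, and that every GPR leaf gene is declared.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with a descriptive error otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  }
  if (any(!nzchar(mets$compartment))) {
    stop("metabolites with empty compartment: ",
         paste(mets$id[!nzchar(mets$compartment)], collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  for (r in model$reactions) {
    if (length(r$stoichiometry) == 0L) {
      stop("reaction '", r$id, "' has empty stoichiometry")
    }
    if (any(!is.finite(r$stoichiometry)) || any(r$stoichiometry == 0)) {
      stop("reaction '", r$id, "' has non-finite or zero coefficients")
    }
    if (r$lb > r$ub) {
      stop("reaction '", r$id, "' has lb > ub (", r$lb, " > ", r$ub, ")")
    }
    missing_mets <- setdiff(names(r$stoichiometry), mets$id)
    if (length(missing_mets)) {
      stop("reaction '", r$id, "' references unknown metabolites: ",
           paste(missing_mets, collapse = ", "))
    }
    gg <- gpr_genes(r$gpr)
    unknown <- setdiff(gg, model$genes)
    if (length(unknown)) {
      stop("reaction '", r$id, "' GPR uses undeclared genes: ",
           paste(unknown, collapse = ", "))
    }
  }
  if (!model$objective %in% rids) {
    stop("objective reaction '", model$objective, "' not in model")
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", length(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,", length(x$genes), "genes\n")
  cat("  objective:", x$objective, "\n")
  n_sink <- sum(vapply(x$reactions, `[[`, logical(1), "is_sink"))
  if (n_sink > 0) cat("  sink reactions:", n_sink, "\n")
  invisible(x)
}

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector in declaration order.
#' @export
reaction_ids <- function(model) names(model$reactions)

# bound vectors in declaration order
.model_bounds <- function(model) {
  list(lb = vapply(model$reactions, `[[`, numeric(1), "lb"),
       ub = vapply(model$reactions, `[[`, numeric(1), "ub"))
}

#' Stoichiometric matrix of a model
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix (metabolites x reactions) in declaration order,
#'   with dimnames; entry (m, r) is the signed coefficient of metabolite m
#'   in reaction r, 0 if absent.
#' @export
stoichiometric_matrix <- function(model) {
  mids <- model$metabolites$id
  rids <- reaction_ids(model)
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (r in model$reactions) {
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  }
  S
}

#' Find dead-end metabolites
#'
#' A metabolite is a dead end when it cannot both be produced and consumed
#' under the reaction directionalities: a reaction with `ub > 0` acts in its
#' forward direction and one with `lb < 0` also in reverse, so reversible
#' reactions count as both producer and consumer of every participant.
#' Dead-end metabolites block mass balance and cannot carry steady-state
#' flux.
#'
#' @param model a `metabolic_model`.
#' @return character vector of dead-end metabolite ids.
#' @export
find_dead_end_metabolites <- function(model) {
  produced <- consumed <- character(0)
  for (r in model$reactions) {
    coefs <- r$stoichiometry
    fwd <- r$ub > 0
    rev <- r$lb < 0
    if (fwd) {
      produced <- c(produced, names(coefs)[coefs > 0])
      consumed <- c(consumed, names(coefs)[coefs < 0])
    }
    if (rev) {
      produced <- c(produced, names(coefs)[coefs < 0])
      consumed <- c(consumed, names(coefs)[coefs > 0])
    }
  }
  mids <- model$metabolites$id
  mids[!(mids %in% produced & mids %in% consumed)]
}

#' Remove dead-end metabolites and their reactions
#'
#' Iterates removal of dead-end metabolites together with every reaction
#' touching them until no dead end remains (removals can cascade). The
#' operation is idempotent and its result does not depend on metabolite
#' declaration order.
#'
#' @param model a `metabolic_model`.
#' @return list with `model` (pruned) and `removed` (data.frame of removed
#'   ids in removal order, with a `type` column of "metabolite"/"reaction").
#' @export
prune_dead_ends <- function(model) {
  removed <- data.frame(type = character(0), id = character(0),
                        stringsAsFactors = FALSE)
  repeat {
    dead <- find_dead_end_metabolites(model)
    if (length(dead) == 0L) break
    dead <- sort(dead)
    touching <- vapply(model$reactions, function(r) {
      any(names(r$stoichiometry) %in% dead)
    }, logical(1))
    gone_rxns <- sort(names(model$reactions)[touching])
    if (model$objective %in% gone_rxns) {
      stop("pruning dead ends would remove the objective reaction '",
           model$objective, "'; model irreparable without added sinks")
    }
    removed <- rbind(removed,
                     data.frame(type = "metabolite", id = dead,
                                stringsAsFactors = FALSE),
                     if (length(gone_rxns))
                       data.frame(type = "reaction", id = gone_rxns,
                                  stringsAsFactors = FALSE))
    model$metabolites <- model$metabolites[!model$metabolites$id %in% dead, ,
                                           drop = FALSE]
    model$reactions <- model$reactions[!names(model$reactions) %in% gone_rxns]
    if (length(model$reactions) == 0L) {
      stop("pruning dead ends removed every reaction; model irreparable")
    }
  }
  validate_model(model)
  list(model = model, removed = removed)
}

#' Add a sink reaction for a metabolite
#'
#' A sink is a pseudo-reaction with stoichiometry `{metabolite: -1}`;
#' positive flux removes the metabolite, negative flux supplies it. The
#' default bounds are reversible so a sink can add or remove an
#' intracellular metabolite.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id metabolite to sink.
#' @param lb,ub flux bounds (mmol/gDW/h), default reversible c(-1000, 1000).
#' @param id reaction id, default `sink_<metabolite_id>`.
#' @return the model with the sink appended.
#' @export
add_sink_reaction <- function(model, metabolite_id, lb = -1000, ub = 1000,
                              id = paste0("sink_", metabolite_id)) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite '", metabolite_id, "'")
  }
  if (lb > ub) stop("sink bounds must satisfy lb <= ub")
  existing <- vapply(model$reactions, function(r) {
    r$is_sink && identical(names(r$stoichiometry), metabolite_id)
  }, logical(1))
  if (any(existing)) {
    stop("a sink for metabolite '", metabolite_id, "' already exists (",
         names(model$reactions)[existing][1], ")")
  }
  if (id %in% names(model$reactions)) {
    stop("reaction id '", id, "' already in model")
  }
  sink <- list(id = id,
               stoichiometry = stats::setNames(-1, metabolite_id),
               lb = lb, ub = ub, gpr = "", is_sink = TRUE)
  model$reactions[[id]] <- sink
  validate_model(model)
  model
}
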