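# Expression integration: normalization of counts, GPR evaluation against a
# profile, and multiplicative rescaling of reaction bounds
# (bound' = bound * gamma * reaction_expression).

#' Integration configuration
#'
#' Parameters controlling how expression is mapped onto reaction bounds.
#'
#' @param gamma positive scaling hyperparameter multiplying the mapped
#'   expression before bound rescaling; default 2.
#' @param and_operator how an AND node combines subunit values: `"min"`
#'   (complex limited by its scarcest subunit, default) or `"mean"`.
#' @param or_operator how an OR node combines isoenzyme values: `"max"`
#'   (best-expressed isoenzyme, default) or `"sum"`.
#' @param missing_gene_value value used for genes absent from a profile;
#'   default 1 (neutral) so missing annotation never silently blocks a
#'   reaction.
#' @param cap_factor optional upper clip for the bound multiplier
#'   `gamma * expression`; `NULL` (default) leaves the multiplier free.
#' @param exempt_objective if TRUE the objective reaction's bounds are left
#'   untouched; default FALSE.
#' @return a list of class `integration_config`.
#' @export
integration_config <- function(gamma = 2,
                               and_operator = c("min", "mean"),
                               or_operator = c("max", "sum"),
                               missing_gene_value = 1,
                               cap_factor = NULL,
                               exempt_objective = FALSE) {
  and_operator <- match.arg(and_operator)
  or_operator <- match.arg(or_operator)
  stopifnot(is.numeric(gamma), length(gamma) == 1, gamma > 0)
  if (!is.null(cap_factor)) stopifnot(cap_factor > 0)
  structure(list(gamma = gamma, and_operator = and_operator,
                 or_operator = or_operator,
                 missing_gene_value = missing_gene_value,
                 cap_factor = cap_factor,
                 exempt_objective = isTRUE(exempt_objective)),
            class = "integration_config")
}

#' Construct an expression profile
#'
#' @param sample_id sample identifier.
#' @param condition `"control"` or `"treated"`.
#' @param values named numeric vector, gene id -> normalized abundance
#'   (non-negative, control mean about 1).
#' @param flagged genes whose control mean was zero (value forced to 0).
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(sample_id, condition, values,
                               flagged = character(0)) {
  condition <- match.arg(condition, c("control", "treated"))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative")
  }
  structure(list(sample_id = sample_id, condition = condition,
                 values = values, flagged = flagged),
            class = "expression_profile")
}

#' Normalize a raw counts table into expression profiles
#'
#' Each sample is first scaled to the mean library size; each gene is then
#' divided by its mean across control samples, so control genes average 1
#' and treated values read directly as fold changes versus control. Genes
#' with zero control mean get value 0 and are flagged.
#'
#' @param counts gene-by-sample matrix (or data.frame) of non-negative
#'   counts with gene ids as rownames.
#' @param conditions named character vector mapping sample (column) name to
#'   `"control"`/`"treated"`; at least one control sample required.
#' @return list of [expression_profile()] objects, one per sample.
#' @export
normalize_expression <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  samples <- colnames(counts)
  if (is.null(samples)) stop("counts must have sample column names")
  conditions <- conditions[samples]
  if (any(is.na(conditions))) stop("every sample needs a condition label")
  if (!any(conditions == "control")) stop("no control samples in the design")

  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("samples with zero library size: ",
                              paste(samples[libsize == 0], collapse = ", "))
  scaled <- sweep(counts, 2, libsize / mean(libsize), "/")
  ctrl_mean <- rowMeans(scaled[, conditions == "control", drop = FALSE])
  flagged <- rownames(counts)[ctrl_mean == 0]
  denom <- ifelse(ctrl_mean == 0, 1, ctrl_mean)
  norm <- sweep(scaled, 1, denom, "/")
  norm[ctrl_mean == 0, ] <- 0

  lapply(samples, function(s) {
    expression_profile(s, conditions[[s]],
                       stats::setNames(norm[, s], rownames(counts)),
                       flagged = flagged)
  })
}

#' Evaluate a GPR rule against an expression profile
#'
#' Leaves take the gene's normalized value (or `missing_gene_value`); AND
#' nodes combine children with `and_operator`, OR nodes with `or_operator`.
#'
#' @param rule parsed GPR tree (see [parse_gpr()]) or rule text.
#' @param profile an [expression_profile()] (or a named numeric vector).
#' @param config an [integration_config()].
#' @return non-negative scalar reaction expression value.
#' @export
evaluate_gpr <- function(rule, profile, config = integration_config()) {
  values <- if (inherits(profile, "expression_profile")) profile$values else profile
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (is.null(rule)) stop("evaluate_gpr needs a non-empty rule")
  and_fn <- switch(config$and_operator, min = min, mean = mean)
  or_fn <- switch(config$or_operator, max = max, sum = sum)
  eval_node <- function(node) {
    switch(node$op,
      gene = if (node$gene %in% names(values)) values[[node$gene]]
             else config$missing_gene_value,
      and = and_fn(vapply(node$children, eval_node, numeric(1))),
      or = or_fn(vapply(node$children, eval_node, numeric(1))),
      stop("malformed GPR tree: unknown node '", node$op, "'"))
  }
  eval_node(rule)
}

#' Map an expression profile onto model reactions
#'
#' Reactions with a GPR get the rule evaluated against the profile;
#' reactions without a GPR get the neutral value 1.
#'
#' @param model a `metabolic_model`.
#' @param profile an [expression_profile()].
#' @param config an [integration_config()].
#' @return data.frame with columns `reaction_id`, `expression`,
#'   `provenance` (`"gpr-evaluated"` or `"no-gpr-neutral"`), one row per
#'   model reaction in declaration order.
#' @export
map_expression_to_reactions <- function(model, profile,
                                        config = integration_config()) {
  rows <- lapply(model$reactions, function(r) {
    if (nzchar(r$gpr)) {
      data.frame(reaction_id = r$id,
                 expression = evaluate_gpr(r$gpr, profile, config),
                 provenance = "gpr-evaluated", stringsAsFactors = FALSE)
    } else {
      data.frame(reaction_id = r$id, expression = 1,
                 provenance = "no-gpr-neutral", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rescale reaction bounds by mapped expression
#'
#' Applies the multiplicative constraint `lb' = lb * f`, `ub' = ub * f`
#' with `f = gamma * reaction_expression`. Since `f >= 0`, signs are
#' preserved and `lb' <= ub'` is maintained; an irreversible reaction stays
#' irreversible and `f = 0` blocks the reaction. If `cap_factor` is set,
#' `f` is clipped to `[0, cap_factor]`.
#'
#' @param model a `metabolic_model`.
#' @param rmap reaction expression map from [map_expression_to_reactions()].
#' @param config an [integration_config()].
#' @return the model with rescaled bounds.
#' @export
apply_expression_bounds <- function(model, rmap,
                                    config = integration_config()) {
  missing_rxn <- setdiff(reaction_ids(model), rmap$reaction_id)
  if (length(missing_rxn)) {
    stop("expression map lacks reactions: ",
         paste(missing_rxn, collapse = ", "))
  }
  expr <- stats::setNames(rmap$expression, rmap$reaction_id)
  for (rid in reaction_ids(model)) {
    if (config$exempt_objective && identical(rid, model$objective)) next
    f <- config$gamma * expr[[rid]]
    if (!is.finite(f)) stop("non-finite bound multiplier for '", rid, "'")
    if (!is.null(config$cap_factor)) f <- min(f, config$cap_factor)
    f <- max(f, 0)
    model$reactions[[rid]]$lb <- model$reactions[[rid]]$lb * f
    model$reactions[[rid]]$ub <- model$reactions[[rid]]$ub * f
  }
  validate_model(model)
  model
}

#' Build a condition-specific model for one sample
#'
#' Convenience wrapper: maps a profile to reactions and rescales bounds.
#'
#' @inheritParams apply_expression_bounds
#' @param profile an [expression_profile()].
#' @return the constrained model.
#' @export
constrain_model <- function(model, profile, config = integration_config()) {
  rmap <- map_expression_to_reactions(model, profile, config)
  apply_expression_bounds(model, rmap, config)
}
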