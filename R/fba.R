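# Flux balance analysis, flux variability analysis and differential flux
# tables. All LPs go through the package's bounded-variable simplex with a
# deterministic variable ordering (declaration order), so repeated runs are
# bit-identical.

#' Maximize biomass flux (flux balance analysis)
#'
#' Solves `max c'v` subject to `S v = 0` and `lb <= v <= ub`, where `c`
#' selects the model's objective reaction.
#'
#' @param model a `metabolic_model`.
#' @return list of class `fba_solution` with `fmax`, `flux` (named vector),
#'   and `status` ("optimal", "infeasible", "unbounded").
#' @export
optimize_biomass <- function(model) {
  validate_model(model)
  S <- stoichiometric_matrix(model)
  bb <- .model_bounds(model)
  obj <- as.numeric(reaction_ids(model) == model$objective)
  sol <- lp_solve(obj, S, rep(0, nrow(S)), bb$lb, bb$ub, maximize = TRUE)
  flux <- if (sol$status == "optimal") {
    stats::setNames(sol$x, reaction_ids(model))
  } else {
    stats::setNames(rep(NA_real_, length(bb$lb)), reaction_ids(model))
  }
  structure(list(fmax = if (sol$status == "optimal") sol$objval else NA_real_,
                 flux = flux, status = sol$status,
                 objective = model$objective),
            class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat("FBA solution (", x$status, "): objective '", x$objective,
      "' fmax = ", format(x$fmax), "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' For every reaction, minimizes and maximizes its flux subject to
#' `S v = 0`, the bounds, and the biomass constraint
#' `c'v = alpha * fmax` (equality by default; `biomass_constraint = "ge"`
#' relaxes it to `>=`), where `fmax` comes from a preliminary biomass
#' maximization.
#'
#' @param model a `metabolic_model`.
#' @param alpha fraction of optimal biomass enforced, in (0, 1]; default 1.
#' @param biomass_constraint `"eq"` (default) or `"ge"`.
#' @return object of class `fva_result`: data.frame `ranges` with columns
#'   `reaction_id`, `vmin`, `vmax`, plus attributes `alpha`, `fmax_used`.
#' @export
flux_variability <- function(model, alpha = 1,
                             biomass_constraint = c("eq", "ge")) {
  biomass_constraint <- match.arg(biomass_constraint)
  stopifnot(alpha > 0, alpha <= 1)
  fba <- optimize_biomass(model)
  if (fba$status != "optimal") {
    stop("biomass optimization did not solve (status: ", fba$status, ")")
  }
  S <- stoichiometric_matrix(model)
  bb <- .model_bounds(model)
  rids <- reaction_ids(model)
  n <- length(rids)
  obj_row <- as.numeric(rids == model$objective)
  target <- alpha * fba$fmax

  if (biomass_constraint == "eq") {
    Acon <- rbind(S, obj_row)
    bcon <- c(rep(0, nrow(S)), target)
    lb <- bb$lb; ub <- bb$ub
  } else {
    # >= relaxation via a bounded surplus variable: c'v - s = target
    Acon <- rbind(cbind(S, 0), c(obj_row, -1))
    bcon <- c(rep(0, nrow(S)), target)
    smax <- max(abs(fba$fmax), sum(abs(c(bb$lb, bb$ub)))) + 1
    lb <- c(bb$lb, 0); ub <- c(bb$ub, smax)
  }
  nv <- ncol(Acon)
  vmin <- vmax <- numeric(n)
  for (i in seq_len(n)) {
    ei <- numeric(nv); ei[i] <- 1
    lo <- lp_solve(ei, Acon, bcon, lb, ub, maximize = FALSE)
    hi <- lp_solve(ei, Acon, bcon, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem for '", rids[i], "' did not solve (status: ",
           lo$status, "/", hi$status, "); biomass constraint at alpha = ",
           alpha, " may be infeasible")
    }
    vmin[i] <- lo$objval
    vmax[i] <- hi$objval
  }
  ranges <- data.frame(reaction_id = rids, vmin = vmin, vmax = vmax,
                       stringsAsFactors = FALSE)
  structure(list(ranges = ranges, alpha = alpha, fmax_used = fba$fmax,
                 biomass_constraint = biomass_constraint),
            class = "fva_result")
}

#' @export
print.fva_result <- function(x, ...) {
  cat("FVA result: alpha =", x$alpha, "( fmax =", format(x$fmax_used), ",",
      x$biomass_constraint, "constraint )\n")
  print(utils::head(x$ranges, 10))
  if (nrow(x$ranges) > 10) cat("...", nrow(x$ranges), "reactions total\n")
  invisible(x)
}

# midpoint summary of an FVA result, as a named vector
fva_midpoints <- function(fva) {
  stats::setNames((fva$ranges$vmin + fva$ranges$vmax) / 2,
                  fva$ranges$reaction_id)
}

#' Treated-versus-control differential flux table
#'
#' Summarizes each condition's FVA interval by its midpoint and computes
#' per-reaction fold change treated/control. Reactions whose control
#' midpoint is within `eps` of zero are flagged `near-zero-denominator` and
#' should be excluded from ranking; for the rest
#' `fold_change = (treated_mid + eps*s) / (control_mid + eps*s)` with
#' `s = sign(control_mid)` guarding the denominator.
#'
#' @param treated,control `fva_result` objects over the same reactions.
#' @param eps denominator guard; default `1e-6 * max(|vmin|, |vmax|)` over
#'   both results.
#' @return data.frame with columns `reaction_id`, `control_vmin/vmax/mid`,
#'   `treated_vmin/vmax/mid`, `fold_change`, `log2_fc`, `flag`.
#' @export
flux_fold_change <- function(treated, control, eps = NULL) {
  if (!setequal(treated$ranges$reaction_id, control$ranges$reaction_id)) {
    stop("treated and control FVA results cover different reaction sets")
  }
  tr <- treated$ranges[match(control$ranges$reaction_id,
                             treated$ranges$reaction_id), ]
  co <- control$ranges
  if (is.null(eps)) {
    eps <- 1e-6 * max(abs(c(tr$vmin, tr$vmax, co$vmin, co$vmax, 1)))
  }
  c_mid <- (co$vmin + co$vmax) / 2
  t_mid <- (tr$vmin + tr$vmax) / 2
  flag <- ifelse(abs(c_mid) < eps, "near-zero-denominator", "ok")
  s <- ifelse(c_mid >= 0, 1, -1)
  fc <- (t_mid + eps * s) / (c_mid + eps * s)
  # a midpoint sign flip has no meaningful positive ratio; flag it rather
  # than report a negative fold change
  flag[flag == "ok" & fc <= 0] <- "sign-flip"
  fc[flag != "ok"] <- NA_real_
  out <- data.frame(reaction_id = co$reaction_id,
                    control_vmin = co$vmin, control_vmax = co$vmax,
                    control_mid = c_mid,
                    treated_vmin = tr$vmin, treated_vmax = tr$vmax,
                    treated_mid = t_mid,
                    fold_change = fc,
                    log2_fc = log2(fc),
                    flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
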