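# Gene-knockout analysis: GPR-based reaction disabling, MOMA flux
# prediction (quadratic program via quadprog), FBA knockout prediction, and
# a simplified robust metabolic-transformation score ranking knockouts that
# move a source (treated) flux state toward a target (control) state.

#' Reactions disabled by a gene knockout
#'
#' Evaluates every reaction's GPR with the gene set to FALSE; reactions
#' whose rule becomes FALSE lose their catalyst and are disabled.
#'
#' @param model a `metabolic_model`.
#' @param gene gene id in `model$genes`.
#' @return character vector of disabled reaction ids.
#' @export
gene_knockout_reactions <- function(model, gene) {
  if (!gene %in% model$genes) stop("unknown gene '", gene, "'")
  disabled <- vapply(model$reactions, function(r) {
    nzchar(r$gpr) && !gpr_boolean(r$gpr, knocked_out = gene)
  }, logical(1))
  names(model$reactions)[disabled]
}

#' MOMA knockout flux prediction
#'
#' Minimization of metabolic adjustment: after a knockout, the cell's flux
#' state is predicted as the feasible flux vector closest (in squared
#' Euclidean distance) to a reference state, i.e. the solution of
#' `min sum_i (v_i - ref_i)^2` subject to `S v = 0`, the model bounds, and
#' `v_i = 0` for every disabled reaction.
#'
#' @param model a `metabolic_model` (the un-knocked bounds).
#' @param reference named flux vector satisfying `S v = 0` and the bounds.
#' @param disabled character vector of reaction ids forced to zero.
#' @return list of class `knockout_prediction` with `flux` (named vector),
#'   `distance` (sum of squared deviations), `disabled`, `status`.
#' @export
moma_knockout <- function(model, reference, disabled = character(0)) {
  rids <- reaction_ids(model)
  ref <- reference[rids]
  if (any(is.na(ref))) stop("reference flux vector does not cover all reactions")
  unknown <- setdiff(disabled, rids)
  if (length(unknown)) stop("unknown reactions in disabled set: ",
                            paste(unknown, collapse = ", "))
  S <- stoichiometric_matrix(model)
  bb <- .model_bounds(model)
  sol <- .qp_project(ref, S, bb$lb, bb$ub, zero = match(disabled, rids))
  if (sol$status != "optimal") {
    stop("MOMA QP infeasible after knocking out {",
         paste(disabled, collapse = ", "),
         "}; the zero-flux and bound constraints conflict with S v = 0")
  }
  v <- stats::setNames(sol$x, rids)
  structure(list(flux = v, distance = sum((v - ref)^2),
                 disabled = disabled, status = "optimal"),
            class = "knockout_prediction")
}

# min ||x - ref||^2 s.t. S x = 0, lb <= x <= ub, x[zero] = 0 (quadprog).
# Disabled variables are eliminated by column deletion (not extra equality
# rows) and the problem is rescaled to unit bounds, which keeps quadprog's
# active-set method away from spurious "constraints are inconsistent"
# failures on degenerate networks. Feasibility of the knockout itself is
# checked with an LP first so a genuine infeasibility is still reported.
.qp_project <- function(ref, S, lb, ub, zero = integer(0)) {
  n <- length(ref)
  x <- numeric(n)
  keep_var <- setdiff(seq_len(n), zero)
  if (length(zero)) {
    if (any(lb[zero] > 0 | ub[zero] < 0)) {
      return(list(status = "infeasible", x = rep(NA_real_, n)))
    }
    feas <- lp_solve(numeric(length(keep_var)),
                     S[, keep_var, drop = FALSE], rep(0, nrow(S)),
                     lb[keep_var], ub[keep_var])
    if (feas$status != "optimal") {
      return(list(status = "infeasible", x = rep(NA_real_, n)))
    }
  }
  Sk <- S[, keep_var, drop = FALSE]
  Sk <- Sk[rowSums(Sk != 0) > 0, , drop = FALSE]
  sc <- max(abs(c(lb, ub, ref, 1)))
  refk <- ref[keep_var] / sc
  lbk <- lb[keep_var] / sc
  ubk <- ub[keep_var] / sc
  nk <- length(keep_var)
  # quadprog needs full-rank equality rows
  if (nrow(Sk)) {
    qrA <- qr(t(Sk))
    Sk <- Sk[qrA$pivot[seq_len(qrA$rank)], , drop = FALSE]
  }
  Amat <- t(rbind(Sk, diag(nk), -diag(nk)))
  bvec <- c(rep(0, nrow(Sk)), lbk, -ubk)
  out <- tryCatch(
    quadprog::solve.QP(Dmat = diag(nk), dvec = refk, Amat = Amat,
                       bvec = bvec, meq = nrow(Sk)),
    error = function(e) NULL)
  if (is.null(out)) return(list(status = "infeasible", x = rep(NA_real_, n)))
  x[keep_var] <- out$solution * sc
  list(status = "optimal", x = x)
}

#' FBA knockout flux prediction
#'
#' Disables the given reactions (bounds set to zero) and re-maximizes
#' biomass; the simplex's deterministic vertex solution is returned as the
#' predicted state.
#'
#' @inheritParams moma_knockout
#' @return a `knockout_prediction` (distance measured against `reference`).
#' @export
fba_knockout <- function(model, reference, disabled = character(0)) {
  rids <- reaction_ids(model)
  ref <- reference[rids]
  for (rid in disabled) {
    if (!rid %in% rids) stop("unknown reaction '", rid, "'")
    model$reactions[[rid]]$lb <- 0
    model$reactions[[rid]]$ub <- 0
  }
  fba <- optimize_biomass(model)
  if (fba$status != "optimal") {
    stop("FBA after knockout {", paste(disabled, collapse = ", "),
         "} did not solve (status: ", fba$status, ")")
  }
  structure(list(flux = fba$flux, distance = sum((fba$flux - ref)^2),
                 disabled = disabled, status = "optimal"),
            class = "knockout_prediction")
}

#' Metabolic transformation score for one knockout prediction
#'
#' Scores how well a predicted knockout flux state moves the source state
#' toward the target state. Per reaction, the desired direction is
#' `d_i = sign(target_mid_i - source_mid_i)` with a dead band `tau`; the
#' achieved change is `a_i = v_i - source_mid_i`. A reaction is a success
#' when it moves in the desired direction by at least `tau` (or stays put,
#' `|a_i| < tau`, when no change is desired) and a violation when it moves
#' against the desired direction by at least `tau`. Successes and
#' violations are weighted by the magnitude of the desired change
#' (`1/n` for steady reactions) and the score is normalized to `[-1, 1]`:
#' a prediction matching the target midpoints scores +1, one opposing every
#' desired change scores -1.
#'
#' @param source,target `fva_result` objects (source = treated state,
#'   target = control state).
#' @param prediction a `knockout_prediction` or a named flux vector.
#' @param tau dead-band flux; default `1e-3 * max(|vmin|, |vmax|)` over both
#'   states.
#' @return list with `ts` (the normalized score), `n_success`,
#'   `n_violation`, and the per-reaction `detail` data.frame.
#' @export
mta_score <- function(source, target, prediction, tau = NULL) {
  if (!setequal(source$ranges$reaction_id, target$ranges$reaction_id)) {
    stop("source and target FVA results cover different reaction sets")
  }
  v <- if (inherits(prediction, "knockout_prediction")) prediction$flux else prediction
  src <- fva_midpoints(source)
  tgt <- fva_midpoints(target)[names(src)]
  v <- v[names(src)]
  if (any(is.na(v))) stop("prediction does not cover all scored reactions")
  if (is.null(tau)) {
    tau <- 1e-3 * max(abs(c(source$ranges$vmin, source$ranges$vmax,
                            target$ranges$vmin, target$ranges$vmax, 1)))
  }
  stopifnot(tau > 0)
  delta <- tgt - src
  d <- ifelse(abs(delta) <= tau, 0, sign(delta))
  a <- v - src
  n <- length(src)
  w <- ifelse(d != 0,
              abs(delta) / max(sum(abs(delta[d != 0])), .Machine$double.eps),
              1 / n)
  success <- (d != 0 & sign(a) == d & abs(a) >= tau) | (d == 0 & abs(a) <= tau)
  violation <- d != 0 & sign(a) == -d & abs(a) >= tau
  ts <- (sum(w[success]) - sum(w[violation])) / sum(w)
  list(ts = ts, n_success = sum(success), n_violation = sum(violation),
       detail = data.frame(reaction_id = names(src), source_mid = src,
                           target_mid = tgt, predicted = v, desired = d,
                           achieved = a, weight = w,
                           outcome = ifelse(success, "success",
                                            ifelse(violation, "violation",
                                                   "neutral")),
                           row.names = NULL, stringsAsFactors = FALSE))
}

#' Rank gene knockouts by robust transformation score
#'
#' For each candidate gene, disables its reactions in the source-state
#' model, predicts the knockout flux state with both MOMA and FBA, scores
#' each prediction with [mta_score()], and takes the worst case
#' `robust_score = min(ts_moma, ts_fba)` (simplified-rMTA). The MOMA
#' reference is the feasible flux vector closest to the source FVA
#' midpoints.
#'
#' @param model the source-state (e.g. treated) constrained model.
#' @param source `fva_result` of the source state.
#' @param target `fva_result` of the target (e.g. control) state.
#' @param genes candidate genes; default all model genes.
#' @param tau dead band passed to [mta_score()].
#' @return data.frame sorted by `robust_score` descending (ties broken
#'   lexicographically by gene id) with columns `gene`, `ts_moma`,
#'   `ts_fba`, `robust_score`, `n_success`, `n_violation`,
#'   `disabled_reactions` (semicolon-joined). Genes whose knockout is
#'   infeasible carry `robust_score = -Inf`.
#' @export
rank_gene_knockouts <- function(model, source, target,
                                genes = model$genes, tau = NULL) {
  if (length(genes) == 0L) {
    return(data.frame(gene = character(0), ts_moma = numeric(0),
                      ts_fba = numeric(0), robust_score = numeric(0),
                      n_success = integer(0), n_violation = integer(0),
                      disabled_reactions = character(0),
                      stringsAsFactors = FALSE))
  }
  S <- stoichiometric_matrix(model)
  bb <- .model_bounds(model)
  if (is.null(tau)) tau <- 1e-3 * max(abs(c(bb$lb, bb$ub, 1)))
  mids <- fva_midpoints(source)[reaction_ids(model)]
  proj <- .qp_project(mids, S, bb$lb, bb$ub)
  if (proj$status != "optimal") stop("cannot project source midpoints onto a feasible reference state")
  reference <- stats::setNames(proj$x, reaction_ids(model))

  rows <- lapply(sort(genes), function(g) {
    disabled <- gene_knockout_reactions(model, g)
    res <- tryCatch({
      pm <- moma_knockout(model, reference, disabled)
      pf <- fba_knockout(model, reference, disabled)
      sm <- mta_score(source, target, pm, tau = tau)
      sf <- mta_score(source, target, pf, tau = tau)
      worst <- if (sm$ts <= sf$ts) sm else sf
      data.frame(gene = g, ts_moma = sm$ts, ts_fba = sf$ts,
                 robust_score = min(sm$ts, sf$ts),
                 n_success = worst$n_success,
                 n_violation = worst$n_violation,
                 disabled_reactions = paste(disabled, collapse = ";"),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(gene = g, ts_moma = NA_real_, ts_fba = NA_real_,
                 robust_score = -Inf, n_success = NA_integer_,
                 n_violation = NA_integer_,
                 disabled_reactions = paste(disabled, collapse = ";"),
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$robust_score, out$gene), ]
  rownames(out) <- NULL
  out
}
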