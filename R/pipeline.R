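# Pipeline orchestration: curate -> constrain -> FVA -> differential flux,
# the knockout screen, and the kinetics report. Each stage writes TSV
# artifacts plus a JSON metadata sidecar carrying parameters, seed and
# input hashes so runs are reproducible and verifiable.

.run_metadata <- function(params, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "fluxkin",
       version = as.character(utils::packageVersion("fluxkin")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       params = params,
       input_md5 = hashes)
}

.write_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# average per-sample FVA results (vmin and vmax element-wise) into one
# condition-level fva_result
.average_fva <- function(fvas) {
  base <- fvas[[1]]
  vmin <- rowMeans(sapply(fvas, function(f) f$ranges$vmin))
  vmax <- rowMeans(sapply(fvas, function(f) f$ranges$vmax))
  base$ranges$vmin <- vmin
  base$ranges$vmax <- vmax
  base$fmax_used <- mean(vapply(fvas, `[[`, numeric(1), "fmax_used"))
  base
}

# condition-mean expression profile (arithmetic mean per gene)
.mean_profile <- function(profiles, condition) {
  sel <- Filter(function(p) p$condition == condition, profiles)
  if (length(sel) == 0) stop("no '", condition, "' samples in the design")
  vals <- rowMeans(sapply(sel, function(p) p$values[names(sel[[1]]$values)]))
  expression_profile(paste0(condition, "_mean"), condition,
                     stats::setNames(vals, names(sel[[1]]$values)))
}

#' Run the differential flux pipeline
#'
#' Stages, in order: load the model, prune dead-end metabolites, add any
#' requested sink reactions, build a condition-specific model per sample
#' (bounds scaled by gamma times the GPR-mapped expression), run FVA at the
#' given alpha, average the per-sample FVA ranges within each condition,
#' and compute the treated-versus-control fold-change table.
#'
#' @param model a `metabolic_model`, or a path to one (COBRA JSON).
#' @param expression path to the expression TSV, or a list of
#'   [expression_profile()] objects.
#' @param samples path to the sample sheet TSV (ignored when `expression`
#'   is a profile list).
#' @param out_dir output directory (created if missing).
#' @param gamma,alpha integration and FVA parameters; defaults 2 and 1.
#' @param config optional [integration_config()] (overrides `gamma`).
#' @param prune prune dead ends first; default TRUE.
#' @param add_sinks metabolite ids to give (reversible) sink reactions
#'   after pruning; default none.
#' @param eps fold-change denominator guard (see [flux_fold_change()]).
#' @return list of class `run_report` with paths `differential_flux`,
#'   `per_sample_fva`, `metadata`, and the in-memory `table`.
#' @export
run_differential_flux <- function(model, expression, samples = NULL,
                                  out_dir = ".", gamma = 2, alpha = 1,
                                  config = NULL, prune = TRUE,
                                  add_sinks = character(0), eps = NULL) {
  inputs <- character(0)
  if (is.character(model)) {
    inputs <- c(inputs, model)
    model <- load_model(model)
  }
  if (is.character(expression)) {
    if (is.null(samples)) stop("config error: sample sheet path is required")
    if (!file.exists(expression)) stop("config error: expression table not found: ", expression)
    if (!file.exists(samples)) stop("config error: sample sheet not found: ", samples)
    inputs <- c(inputs, expression, samples)
    expression <- read_expression_tsv(expression, samples)
  }
  if (is.null(config)) config <- integration_config(gamma = gamma)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (prune) model <- prune_dead_ends(model)$model
  for (m in add_sinks) model <- add_sink_reaction(model, m)

  fvas <- lapply(expression, function(p) {
    flux_variability(constrain_model(model, p, config), alpha = alpha)
  })
  cond <- vapply(expression, `[[`, character(1), "condition")
  if (!any(cond == "control") || !any(cond == "treated")) {
    stop("need both control and treated samples for differential flux")
  }
  ctrl <- .average_fva(fvas[cond == "control"])
  trt <- .average_fva(fvas[cond == "treated"])
  table <- flux_fold_change(trt, ctrl, eps = eps)

  per_sample <- do.call(rbind, lapply(seq_along(fvas), function(i) {
    cbind(sample = expression[[i]]$sample_id, condition = cond[i],
          fvas[[i]]$ranges)
  }))
  paths <- list(
    differential_flux = .write_tsv(table, file.path(out_dir, "differential_flux.tsv")),
    per_sample_fva = .write_tsv(per_sample, file.path(out_dir, "per_sample_fva.tsv")),
    metadata = .write_metadata(
      .run_metadata(list(stage = "differential-flux", gamma = config$gamma,
                         alpha = alpha, prune = prune,
                         add_sinks = add_sinks,
                         and_operator = config$and_operator,
                         or_operator = config$or_operator), inputs),
      file.path(out_dir, "differential_flux_meta.json")))
  structure(c(paths, list(table = table)), class = "run_report")
}

#' Run the gene-knockout transformation screen
#'
#' Builds condition-mean expression profiles, constrains the model for the
#' treated (source) and control (target) conditions, runs FVA for both, and
#' ranks candidate gene knockouts of the treated model by robust
#' transformation score (see [rank_gene_knockouts()]): knockouts that move
#' the treated flux state back toward the control state score highest.
#'
#' @inheritParams run_differential_flux
#' @param genes candidate knockout genes; default all model genes.
#' @param tau score dead band; default `1e-3 * max(|bound|)` of the source
#'   model.
#' @return `run_report` with `knockout_ranking` path, `metadata`, and the
#'   in-memory `ranking`.
#' @export
run_knockout_screen <- function(model, expression, samples = NULL,
                                out_dir = ".", gamma = 2, alpha = 1,
                                config = NULL, prune = TRUE,
                                add_sinks = character(0),
                                genes = NULL, tau = NULL) {
  inputs <- character(0)
  if (is.character(model)) {
    inputs <- c(inputs, model)
    model <- load_model(model)
  }
  if (is.character(expression)) {
    if (is.null(samples)) stop("config error: sample sheet path is required")
    inputs <- c(inputs, expression, samples)
    expression <- read_expression_tsv(expression, samples)
  }
  if (is.null(config)) config <- integration_config(gamma = gamma)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (prune) model <- prune_dead_ends(model)$model
  for (m in add_sinks) model <- add_sink_reaction(model, m)

  ctrl_model <- constrain_model(model, .mean_profile(expression, "control"), config)
  trt_model <- constrain_model(model, .mean_profile(expression, "treated"), config)
  target <- flux_variability(ctrl_model, alpha = alpha)
  source <- flux_variability(trt_model, alpha = alpha)
  if (is.null(genes)) genes <- model$genes
  ranking <- rank_gene_knockouts(trt_model, source, target,
                                 genes = genes, tau = tau)
  paths <- list(
    knockout_ranking = .write_tsv(ranking, file.path(out_dir, "knockout_ranking.tsv")),
    metadata = .write_metadata(
      .run_metadata(list(stage = "knockout-screen", gamma = config$gamma,
                         alpha = alpha, tau = tau, genes = genes,
                         scoring = "simplified-rMTA"), inputs),
      file.path(out_dir, "knockout_ranking_meta.json")))
  structure(c(paths, list(ranking = ranking)), class = "run_report")
}

#' Run the kinetics report
#'
#' Fits a dose-response curve per substrate level, classifies the
#' inhibition mode from the IC50 trend, derives the Cheng-Prusoff Ki when
#' competitive and Km is supplied, and extracts Tm (and delta-Tm versus an
#' `apo` curve) from any melt curves.
#'
#' @param assays a data.frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `activity` (and optionally `replicate`), or a path to such a CSV.
#' @param melt_curves named list of melt-curve data.frames
#'   (`temperature_C`, `ratio_350_330`) or CSV paths; the entry named
#'   `"apo"` is the reference for delta-Tm.
#' @param Km optional Michaelis constant (uM) for the Ki derivation.
#' @param rel_tol mode-classification dead band; default 0.25.
#' @param tm_method Tm extraction method; see [fit_melting_temperature()].
#' @param out_dir output directory.
#' @return `run_report` with paths `ic50_fits`, `melting`, `summary`
#'   (JSON), and in-memory `fits`, `mode_call`, `tm_table`.
#' @export
run_kinetics_report <- function(assays = NULL, melt_curves = NULL, Km = NULL,
                                rel_tol = 0.25, tm_method = "derivative",
                                out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character(0)
  if (is.character(assays)) {
    inputs <- c(inputs, assays)
    assays <- utils::read.csv(assays)
  }
  fits_tab <- NULL
  mode_call <- NULL
  if (!is.null(assays)) {
    levels_S <- sort(unique(assays$substrate_uM))
    fits <- lapply(levels_S, function(s) {
      sub <- assays[assays$substrate_uM == s, ]
      fit_dose_response(sub$inhibitor_uM, sub$activity)
    })
    fits_tab <- data.frame(
      substrate_uM = levels_S,
      Vmax = vapply(fits, `[[`, numeric(1), "Vmax"),
      IC50_uM = vapply(fits, `[[`, numeric(1), "IC50"),
      h = vapply(fits, `[[`, numeric(1), "h"),
      residual_ss = vapply(fits, `[[`, numeric(1), "residual_ss"),
      converged = vapply(fits, `[[`, logical(1), "converged"))
    ok <- fits_tab$converged
    if (sum(ok) >= 2) {
      mode_call <- classify_inhibition_mode(fits_tab$substrate_uM[ok],
                                            fits_tab$IC50_uM[ok],
                                            rel_tol = rel_tol, Km = Km)
    }
  }
  tm_tab <- NULL
  if (!is.null(melt_curves) && length(melt_curves)) {
    curves <- lapply(melt_curves, function(mc) {
      if (is.character(mc)) {
        inputs <<- c(inputs, mc)
        utils::read.csv(mc)
      } else mc
    })
    tms <- vapply(curves, function(cu) {
      fit_melting_temperature(cu$temperature_C, cu$ratio_350_330,
                              method = tm_method)
    }, numeric(1))
    tm_apo <- if ("apo" %in% names(tms)) tms[["apo"]] else NA_real_
    tm_tab <- data.frame(curve = names(tms), Tm_C = unname(tms),
                         delta_Tm_C = if (is.na(tm_apo)) NA_real_
                                      else unname(tms) - tm_apo)
  }
  summary <- list(
    mode = if (is.null(mode_call)) NULL else mode_call$mode,
    fold_shift = if (is.null(mode_call)) NULL else mode_call$fold_shift,
    Ki_uM = if (is.null(mode_call) || is.na(mode_call$Ki)) NULL else mode_call$Ki,
    Km_uM = Km,
    note = if (is.null(fits_tab) && is.null(tm_tab)) "no kinetics inputs" else NULL)
  paths <- list(
    ic50_fits = if (!is.null(fits_tab))
      .write_tsv(fits_tab, file.path(out_dir, "ic50_fits.tsv")) else NULL,
    melting = if (!is.null(tm_tab))
      .write_tsv(tm_tab, file.path(out_dir, "melting.tsv")) else NULL,
    summary = .write_metadata(
      c(.run_metadata(list(stage = "kinetics", rel_tol = rel_tol,
                           tm_method = tm_method), inputs),
        summary),
      file.path(out_dir, "kinetics_summary.json")))
  structure(c(paths, list(fits = fits_tab, mode_call = mode_call,
                          tm_table = tm_tab)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("fluxkin run report\n")
  for (nm in names(x)) {
    if (is.character(x[[nm]]) && length(x[[nm]]) == 1 && file.exists(x[[nm]])) {
      cat("  ", nm, ": ", x[[nm]], "\n", sep = "")
    }
  }
  invisible(x)
}
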