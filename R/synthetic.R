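# Generators for every input the pipeline consumes: a hand-specified toy
# pyrimidine-metabolism network, condition-labeled expression profiles,
# inhibition-assay tables and nanoDSF melt curves. All generators are pure
# functions of their configuration and seed.

#' Default seed used by the generators
#' @export
FLUXKIN_DEFAULT_SEED <- 20250233L

#' Build the toy pyrimidine-metabolism model
#'
#' A 16-reaction network mirroring the pathways interrogated by the
#' analysis: glutamine uptake feeding a lumped CAD reaction into
#' dihydroorotate (DHO), the DHODH reaction (DHO + ubiquinone -> orotate +
#' ubiquinol, GPR "DHODH") with a lumped ETC regenerating ubiquinone,
#' UMPS and a nucleotide kinase to UTP, a uridine salvage branch
#' (uptake capped by `salvage_ub`, salvage kinase GPR "UCK2") entering at
#' UMP, optional glycolysis to lactate and a glutathione branch, and a
#' biomass reaction consuming UTP (+ pyruvate and GSH when the branches are
#' on). Orotate and GSH carry forward-only sink reactions so excess de novo
#' flux can drain without letting the sinks feed the pathway backwards.
#'
#' The nucleotide kinase's capacity (`ndpk_ub`) is set below the de novo +
#' salvage capacity so the unperturbed (control) state has slack in the
#' salvage branch, while a DHODH-constrained (treated) state must run
#' salvage at full capacity -- the flux signature of uridine rescue.
#'
#' @param salvage_ub uridine uptake capacity (mmol/gDW/h); 0 closes the
#'   salvage pathway. Default 5.
#' @param uptake_ub glutamine and glucose uptake capacity; default 10.
#' @param ndpk_ub UMP-to-UTP kinase capacity; default 8.
#' @param include_glycolysis,include_glutathione include those branches.
#' @param biomass_stoichiometry named coefficients (negative = consumed)
#'   for the biomass reaction; defaults to UTP 1, pyruvate 1, GSH 0.1
#'   (branch terms dropped when a branch is off).
#' @return a feasible `metabolic_model` with `fmax > 0`.
#' @export
build_toy_pyrimidine_model <- function(salvage_ub = 5, uptake_ub = 10,
                                       ndpk_ub = 8,
                                       include_glycolysis = TRUE,
                                       include_glutathione = TRUE,
                                       biomass_stoichiometry = NULL) {
  stopifnot(salvage_ub >= 0, uptake_ub > 0, ndpk_ub > 0)
  met <- function(id, name) data.frame(id = id, name = name,
                                       compartment = "c",
                                       stringsAsFactors = FALSE)
  mets <- rbind(
    met("gln", "L-glutamine"), met("dho", "(S)-dihydroorotate"),
    met("oro", "orotate"), met("q", "ubiquinone"), met("qh2", "ubiquinol"),
    met("ump", "UMP"), met("utp", "UTP"), met("uri", "uridine"))
  rxn <- function(id, sto, lb, ub, gpr = "", is_sink = FALSE) {
    list(id = id, stoichiometry = sto, lb = lb, ub = ub, gpr = gpr,
         is_sink = is_sink)
  }
  rxns <- list(
    rxn("EX_gln", c(gln = 1), 0, uptake_ub),
    rxn("CAD", c(gln = -1, dho = 1), 0, 1000, gpr = "CAD"),
    rxn("DHODH", c(dho = -1, q = -1, oro = 1, qh2 = 1), 0, uptake_ub,
        gpr = "DHODH"),
    rxn("ETC", c(qh2 = -1, q = 1), 0, 1000, gpr = "SDHA"),
    rxn("UMPS", c(oro = -1, ump = 1), 0, 1000, gpr = "UMPS"),
    rxn("NDPK", c(ump = -1, utp = 1), 0, ndpk_ub, gpr = "NME1"),
    rxn("EX_uri", c(uri = 1), 0, salvage_ub),
    rxn("UCK", c(uri = -1, ump = 1), 0, 1000, gpr = "UCK2"),
    rxn("sink_oro", c(oro = -1), 0, 1000, is_sink = TRUE))

  biomass <- c(utp = -1)
  if (include_glycolysis) {
    mets <- rbind(mets, met("glc", "glucose"), met("pyr", "pyruvate"),
                  met("lac", "lactate"))
    rxns <- c(rxns, list(
      rxn("EX_glc", c(glc = 1), 0, uptake_ub),
      rxn("GLYC", c(glc = -1, pyr = 2), 0, 1000, gpr = "GAPDH"),
      rxn("LDH", c(pyr = -1, lac = 1), 0, 1000, gpr = "LDHA"),
      rxn("EX_lac", c(lac = -1), 0, 1000)))
    biomass <- c(biomass, pyr = -1)
  }
  if (include_glutathione) {
    mets <- rbind(mets, met("gsh", "glutathione"))
    rxns <- c(rxns, list(
      rxn("GCL", c(gln = -1, gsh = 1), 0, 1000, gpr = "GCLC"),
      rxn("sink_gsh", c(gsh = -1), 0, 1000, is_sink = TRUE)))
    biomass <- c(biomass, gsh = -0.1)
  }
  if (!is.null(biomass_stoichiometry)) biomass <- unlist(biomass_stoichiometry)
  rxns <- c(rxns, list(rxn("BIOMASS", biomass, 0, 1000)))

  model <- metabolic_model(mets, rxns, objective = "BIOMASS")
  fba <- optimize_biomass(model)
  if (fba$status != "optimal" || fba$fmax <= 0) {
    stop("toy model configuration yields no biomass flux (fmax = ",
         format(fba$fmax), ")")
  }
  model
}

#' Simulate condition-labeled expression profiles
#'
#' Control values are lognormal with mean 1 and coefficient of variation
#' `noise_cv`; treated values are lognormal with mean equal to the gene's
#' effect (1 for genes not listed). `noise_cv = 0` gives the means exactly.
#'
#' @param model a `metabolic_model` (profiles cover `model$genes`).
#' @param effects named numeric vector of multiplicative treated-condition
#'   effects (e.g. `c(DHODH = 0.2)` for a 5-fold knockdown).
#' @param noise_cv biological coefficient of variation; default 0.1.
#' @param n_replicates profiles per condition; default 3.
#' @param seed RNG seed; default [FLUXKIN_DEFAULT_SEED].
#' @return list of [expression_profile()] objects (controls first).
#' @export
simulate_expression_profiles <- function(model, effects = c(DHODH = 0.2),
                                         noise_cv = 0.1, n_replicates = 3,
                                         seed = FLUXKIN_DEFAULT_SEED) {
  stopifnot(noise_cv >= 0, n_replicates >= 1)
  if (any(effects <= 0)) stop("effects must be positive multipliers")
  unknown <- setdiff(names(effects), model$genes)
  if (length(unknown)) stop("effect genes absent from the model: ",
                            paste(unknown, collapse = ", "))
  genes <- model$genes
  means_trt <- stats::setNames(rep(1, length(genes)), genes)
  means_trt[names(effects)] <- effects
  sdlog <- sqrt(log(1 + noise_cv^2))

  draw <- function(means) {
    if (noise_cv == 0) return(means)
    mulog <- log(means) - sdlog^2 / 2
    stats::setNames(stats::rlnorm(length(means), mulog, sdlog), genes)
  }
  set.seed(seed)
  profiles <- list()
  for (i in seq_len(n_replicates)) {
    profiles[[length(profiles) + 1L]] <- expression_profile(
      sprintf("ctrl_%d", i), "control",
      draw(stats::setNames(rep(1, length(genes)), genes)))
  }
  for (i in seq_len(n_replicates)) {
    profiles[[length(profiles) + 1L]] <- expression_profile(
      sprintf("trt_%d", i), "treated", draw(means_trt))
  }
  profiles
}

#' Write expression profiles as a gene-by-sample TSV plus sample sheet
#'
#' @param profiles list of [expression_profile()] objects.
#' @param values_path output TSV (first column `gene_id`, one column per
#'   sample, normalized abundances).
#' @param samples_path output sample-sheet TSV (`sample`, `condition`).
#' @return invisibly, a list with both paths.
#' @export
write_expression_tsv <- function(profiles, values_path, samples_path) {
  genes <- names(profiles[[1]]$values)
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (p in profiles) tab[[p$sample_id]] <- unname(p$values[genes])
  utils::write.table(tab, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- data.frame(
    sample = vapply(profiles, `[[`, character(1), "sample_id"),
    condition = vapply(profiles, `[[`, character(1), "condition"),
    stringsAsFactors = FALSE)
  utils::write.table(sheet, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(values = values_path, samples = samples_path))
}

#' Read expression profiles from TSV
#'
#' @param values_path gene-by-sample TSV of normalized abundances
#'   (first column `gene_id`).
#' @param samples_path sample sheet TSV with columns `sample`, `condition`.
#' @return list of [expression_profile()] objects.
#' @export
read_expression_tsv <- function(values_path, samples_path) {
  tab <- utils::read.delim(values_path, check.names = FALSE)
  sheet <- utils::read.delim(samples_path)
  if (!"gene_id" %in% names(tab)) stop("expression TSV lacks a gene_id column")
  lapply(seq_len(nrow(sheet)), function(i) {
    s <- sheet$sample[i]
    if (!s %in% names(tab)) stop("sample '", s, "' missing from expression TSV")
    expression_profile(s, sheet$condition[i],
                       stats::setNames(tab[[s]], tab$gene_id))
  })
}

#' Simulate an enzyme inhibition assay
#'
#' Activities follow the mode's steady-state rate law -- competitive:
#' `v = Vmax * S / (Km * (1 + I/Ki) + S)`; uncompetitive:
#' `v = Vmax * S / (Km + S * (1 + I/Ki))` -- with multiplicative lognormal
#' noise of coefficient of variation `noise_cv`.
#'
#' @param mode `"competitive"` or `"uncompetitive"`.
#' @param Ki inhibition constant (uM).
#' @param Km Michaelis constant (uM).
#' @param Vmax maximal rate.
#' @param S substrate concentration (uM).
#' @param I inhibitor concentration grid (uM); must be non-empty.
#' @param noise_cv multiplicative noise CV; 0 for noiseless.
#' @param n_replicates replicate measurements per concentration.
#' @param seed RNG seed.
#' @return data.frame with columns `substrate_uM`, `inhibitor_uM`,
#'   `activity`, `replicate`.
#' @export
simulate_inhibition_assay <- function(mode, Ki, Km, Vmax, S, I,
                                      noise_cv = 0, n_replicates = 1,
                                      seed = FLUXKIN_DEFAULT_SEED) {
  mode <- match.arg(mode, c("competitive", "uncompetitive"))
  if (length(I) == 0) stop("inhibitor concentration grid is empty")
  stopifnot(Ki > 0, Km > 0, Vmax > 0, S > 0, all(I >= 0), noise_cv >= 0)
  Ki <- unname(Ki); Km <- unname(Km); Vmax <- unname(Vmax)
  S <- unname(S); I <- unname(I)
  v <- switch(mode,
              competitive = Vmax * S / (Km * (1 + I / Ki) + S),
              uncompetitive = Vmax * S / (Km + S * (1 + I / Ki)))
  set.seed(seed)
  rows <- lapply(seq_len(n_replicates), function(rep) {
    act <- if (noise_cv == 0) v else {
      sdlog <- sqrt(log(1 + noise_cv^2))
      v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog)
    }
    data.frame(substrate_uM = S, inhibitor_uM = I, activity = act,
               replicate = rep)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a nanoDSF melt curve
#'
#' `ratio(T) = low(T) + (high(T) - low(T)) / (1 + exp((Tm - T)/slope))`
#' with linear baselines `low(T) = baselines[1] + drifts[1]*(T - Tmin)`,
#' `high(T) = baselines[2] + drifts[2]*(T - Tmin)`, plus gaussian noise.
#'
#' @param Tm melting temperature (degrees C); must lie inside `T_range`.
#' @param slope transition width (degrees C); default 1.5.
#' @param baselines folded and unfolded 350/330 ratios; default c(0.8, 1.0).
#' @param drifts per-degree linear drifts of the two baselines; default 0.
#' @param noise_sd gaussian noise standard deviation; default 0.
#' @param T_range temperature grid (degrees C, ascending); default
#'   `seq(35, 80, by = 0.5)`.
#' @param seed RNG seed.
#' @return data.frame with columns `temperature_C`, `ratio_350_330`.
#' @export
simulate_melt_curve <- function(Tm, slope = 1.5, baselines = c(0.8, 1.0),
                                drifts = c(0, 0), noise_sd = 0,
                                T_range = seq(35, 80, by = 0.5),
                                seed = FLUXKIN_DEFAULT_SEED) {
  stopifnot(slope > 0, noise_sd >= 0)
  if (Tm <= min(T_range) || Tm >= max(T_range)) {
    stop("Tm = ", Tm, " lies outside the scanned temperature range")
  }
  Tm0 <- min(T_range)
  low <- baselines[1] + drifts[1] * (T_range - Tm0)
  high <- baselines[2] + drifts[2] * (T_range - Tm0)
  ratio <- low + (high - low) / (1 + exp((Tm - T_range) / slope))
  if (noise_sd > 0) {
    set.seed(seed)
    ratio <- ratio + stats::rnorm(length(ratio), 0, noise_sd)
  }
  data.frame(temperature_C = T_range, ratio_350_330 = ratio)
}

#' Random feasible model generator (for oracle fuzz tests)
#'
#' Emits small random stoichiometric networks with finite bounds containing
#' zero flux (so always feasible), used to cross-check the LP machinery
#' against brute-force enumeration. Not a biological simulator.
#'
#' @param n_reactions number of reactions (>= 2).
#' @param n_metabolites number of metabolites (>= 1).
#' @param seed RNG seed.
#' @return a `metabolic_model` with objective at the last reaction.
#' @export
random_feasible_model <- function(n_reactions = 6, n_metabolites = 3,
                                  seed = FLUXKIN_DEFAULT_SEED) {
  set.seed(seed)
  repeat {
    S <- matrix(sample(c(-1L, 0L, 0L, 1L), n_metabolites * n_reactions,
                       replace = TRUE), n_metabolites, n_reactions)
    if (all(colSums(S != 0) > 0)) break
  }
  mids <- sprintf("m%d", seq_len(n_metabolites))
  rids <- sprintf("r%d", seq_len(n_reactions))
  lb <- sample(c(0, -5, -10), n_reactions, replace = TRUE)
  ub <- sample(c(3, 5, 10), n_reactions, replace = TRUE)
  mets <- data.frame(id = mids, name = mids, compartment = "c",
                     stringsAsFactors = FALSE)
  rxns <- lapply(seq_len(n_reactions), function(j) {
    nz <- which(S[, j] != 0)
    list(id = rids[j],
         stoichiometry = stats::setNames(as.numeric(S[nz, j]), mids[nz]),
         lb = lb[j], ub = ub[j], gpr = "", is_sink = FALSE)
  })
  metabolic_model(mets, rxns, objective = rids[n_reactions])
}
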