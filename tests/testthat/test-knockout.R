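test_that("GPR boolean semantics decide which reactions a knockout disables", {
  m <- build_toy_pyrimidine_model()
  expect_equal(gene_knockout_reactions(m, "DHODH"), "DHODH")
  expect_error(gene_knockout_reactions(m, "NOPE"), "unknown gene")

  mets <- data.frame(id = "A", name = "A", compartment = "c")
  rxns <- list(
    list(id = "single", stoichiometry = c(A = 1), lb = 0, ub = 1, gpr = "g1"),
    list(id = "iso", stoichiometry = c(A = 1), lb = 0, ub = 1,
         gpr = "g1 or g2"),
    list(id = "complex", stoichiometry = c(A = 1), lb = 0, ub = 1,
         gpr = "g1 and g2"),
    list(id = "out", stoichiometry = c(A = -1), lb = 0, ub = 3))
  mm <- metabolic_model(mets, rxns, objective = "out")
  expect_setequal(gene_knockout_reactions(mm, "g1"), c("single", "complex"))
  expect_setequal(gene_knockout_reactions(mm, "g2"), "complex")
})

test_that("MOMA returns the closest feasible state (chain and diamond)", {
  m <- chain_model()
  ref <- setNames(c(10, 10, 10), reaction_ids(m))
  # disabling the middle reaction forces the whole chain to zero
  pred <- moma_knockout(m, ref, "AB")
  expect_equal(unname(pred$flux), c(0, 0, 0), tolerance = 1e-7)
  expect_equal(pred$distance, 300, tolerance = 1e-5)
  # disabling a reaction already at zero returns the reference exactly
  d <- diamond_model()
  refd <- setNames(c(10, 10, 0, 10, 0, 10), reaction_ids(d))
  pred_b <- moma_knockout(d, refd, c("AC", "CD"))
  expect_equal(pred_b$flux, refd, tolerance = 1e-7)
  expect_equal(pred_b$distance, 0, tolerance = 1e-10)
  # knocking the used branch reroutes through the other
  pred_c <- moma_knockout(d, refd, c("AB", "BD"))
  expect_equal(unname(pred_c$flux[c("AC", "CD")]), c(5, 5), tolerance = 1e-6)
  expect_lt(max(abs(stoichiometric_matrix(d) %*% pred_c$flux)), 1e-7)
})

test_that("MOMA distance is optimal against randomized feasible sampling", {
  set.seed(11)
  for (trial in 1:5) {
    m <- random_feasible_model(n_reactions = 6, n_metabolites = 2,
                               seed = 300 + trial)
    S <- stoichiometric_matrix(m)
    lb <- vapply(m$reactions, `[[`, numeric(1), "lb")
    ub <- vapply(m$reactions, `[[`, numeric(1), "ub")
    V <- enumerate_vertices(S, lb, ub)
    if (is.null(V) || nrow(V) < 2) next
    # random feasible reference: convex combination of vertices
    wts <- runif(nrow(V)); wts <- wts / sum(wts)
    ref <- setNames(as.numeric(t(V) %*% wts), reaction_ids(m))
    dis <- reaction_ids(m)[1]
    pred <- tryCatch(moma_knockout(m, ref, dis), error = function(e) NULL)
    if (is.null(pred)) next
    # 1e4 random feasible points honoring the knockout must not beat it
    keep <- V[abs(V[, 1]) < 1e-9, , drop = FALSE]
    if (nrow(keep) == 0) next
    W <- matrix(runif(1e4 * nrow(keep)), ncol = nrow(keep))
    W <- W / rowSums(W)
    samples <- W %*% keep
    d_samp <- min(rowSums(sweep(samples, 2, ref)^2))
    expect_lte(pred$distance, d_samp + 1e-6)
  }
})

test_that("transformation score hits its extremes and flips sign", {
  sc <- toy_scenario()
  source <- flux_variability(sc$trt_model, 1)
  target <- flux_variability(sc$ctrl_model, 1)
  src_mid <- (source$ranges$vmin + source$ranges$vmax) / 2
  tgt_mid <- (target$ranges$vmin + target$ranges$vmax) / 2
  rid <- source$ranges$reaction_id
  tau <- 2

  # prediction at the target midpoints scores +1
  s_best <- mta_score(source, target, setNames(tgt_mid, rid), tau = tau)
  expect_equal(s_best$ts, 1)
  # prediction at the source midpoints: only steady reactions contribute
  s_stay <- mta_score(source, target, setNames(src_mid, rid), tau = tau)
  expect_gte(s_stay$ts, 0)
  expect_equal(s_stay$n_violation, 0)
  # antisymmetry: achieving every desired move versus opposing every one
  # (steady reactions perturbed identically in both) flips the sign
  d <- sign(tgt_mid - src_mid) * (abs(tgt_mid - src_mid) > tau)
  v_bad <- src_mid - d * (tau * 2) + (d == 0) * (tau * 3)
  v_good <- src_mid + d * (tau * 2) + (d == 0) * (tau * 3)
  s_worst <- mta_score(source, target, setNames(v_bad, rid), tau = tau)
  s_good <- mta_score(source, target, setNames(v_good, rid), tau = tau)
  expect_lt(s_worst$ts, 0)
  expect_equal(s_good$ts, -s_worst$ts, tolerance = 1e-12)
  expect_equal(s_good$n_success, s_worst$n_violation)

  # with no steady reactions the opposing prediction is exactly -1: build a
  # two-state pair where every midpoint differs
  shifted <- target
  shifted$ranges$vmin <- source$ranges$vmin + 10
  shifted$ranges$vmax <- source$ranges$vmax + 10
  s_min <- mta_score(source, shifted, setNames(src_mid - 3 * tau, rid),
                     tau = tau)
  expect_equal(s_min$ts, -1)
  s_max <- mta_score(source, shifted, setNames(src_mid + 10, rid), tau = tau)
  expect_equal(s_max$ts, 1)
})

test_that("knockout ranking is deterministic, complete and oracle-consistent", {
  sc <- toy_scenario()
  source <- flux_variability(sc$trt_model, 1)
  target <- flux_variability(sc$ctrl_model, 1)

  rk1 <- rank_gene_knockouts(sc$trt_model, source, target)
  rk2 <- rank_gene_knockouts(sc$trt_model, source, target)
  expect_identical(rk1, rk2)
  expect_setequal(rk1$gene, sc$model$genes)
  # ordering is by robust score, ties broken by gene id
  expect_true(all(diff(rk1$robust_score) <= 1e-12))

  # empty candidate set gives an empty (but typed) table
  rk0 <- rank_gene_knockouts(sc$trt_model, source, target, genes = character(0))
  expect_equal(nrow(rk0), 0L)
  expect_named(rk0, c("gene", "ts_moma", "ts_fba", "robust_score",
                      "n_success", "n_violation", "disabled_reactions"))

  # brute-force oracle: score each gene independently and compare
  S <- stoichiometric_matrix(sc$trt_model)
  lb <- vapply(sc$trt_model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(sc$trt_model$reactions, `[[`, numeric(1), "ub")
  tau <- 1e-3 * max(abs(c(lb, ub)))
  proj <- fluxkin:::.qp_project((source$ranges$vmin + source$ranges$vmax) / 2,
                                S, lb, ub)
  ref <- setNames(proj$x, reaction_ids(sc$trt_model))
  manual <- vapply(sc$model$genes, function(g) {
    dis <- gene_knockout_reactions(sc$trt_model, g)
    sm <- mta_score(source, target, moma_knockout(sc$trt_model, ref, dis),
                    tau = tau)
    sf <- mta_score(source, target, fba_knockout(sc$trt_model, ref, dis),
                    tau = tau)
    min(sm$ts, sf$ts)
  }, numeric(1))
  manual <- sort(manual, decreasing = TRUE)
  expect_equal(rk1$robust_score, unname(manual), tolerance = 1e-10)

  # the salvage-kinase knockout (reverting compensatory salvage flux)
  # outranks genes whose reactions carry equal flux in both states
  expect_lt(which(rk1$gene == "UCK2"), which(rk1$gene == "LDHA"))
  expect_lt(which(rk1$gene == "UCK2"), which(rk1$gene == "GAPDH"))
})

test_that("knocking a gene outside all GPRs leaves the flux state alone", {
  m <- build_toy_pyrimidine_model()
  m$genes <- sort(c(m$genes, "ORPHAN"))
  expect_length(gene_knockout_reactions(m, "ORPHAN"), 0)
  ref <- optimize_biomass(m)$flux
  pred <- moma_knockout(m, ref, gene_knockout_reactions(m, "ORPHAN"))
  expect_equal(pred$flux, ref, tolerance = 1e-6)
  expect_lt(pred$distance, 1e-8)
})
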