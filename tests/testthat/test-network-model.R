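test_that("COBRA JSON round-trip preserves the model field by field", {
  m <- build_toy_pyrimidine_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- load_model(path, "cobra-json")
  expect_equal(reaction_ids(m2), reaction_ids(m))
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$objective, m$objective)
  expect_equal(m2$genes, m$genes)
  for (rid in reaction_ids(m)) {
    expect_identical(m2$reactions[[rid]]$lb, m$reactions[[rid]]$lb)
    expect_identical(m2$reactions[[rid]]$ub, m$reactions[[rid]]$ub)
    expect_identical(m2$reactions[[rid]]$gpr, m$reactions[[rid]]$gpr)
    expect_identical(m2$reactions[[rid]]$is_sink, m$reactions[[rid]]$is_sink)
    expect_equal(sort(m2$reactions[[rid]]$stoichiometry),
                 sort(m$reactions[[rid]]$stoichiometry))
  }
})

test_that("malformed COBRA JSON is rejected with a format error", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "A", "compartment": "c"}],
              "reactions": [{"id": "r1"}], "genes": [], "objective": "r1"}',
             bad)
  expect_error(load_model(bad, "cobra-json"), "stoichiometry")
  expect_error(load_model(tempfile(), "cobra-json"), "not found")
})

test_that("SBML-FBC reader recovers species, bounds, GPRs and objective", {
  path <- system.file("extdata", "toy_chain.sbml.xml", package = "fluxkin")
  m <- load_model(path, "sbml-fbc")
  expect_equal(nrow(m$metabolites), 2L)
  expect_equal(length(m$reactions), 3L)
  expect_equal(m$objective, "EX_B")
  expect_equal(m$reactions[["EX_A"]]$ub, 10)
  expect_equal(m$reactions[["AB"]]$gpr, "g1 and g2")
  expect_equal(m$reactions[["AB"]]$stoichiometry[c("A", "B")],
               c(A = -1, B = 1))
  expect_equal(optimize_biomass(m)$fmax, 10)
})

test_that("stoichiometric matrix follows declaration order with signed entries", {
  m <- chain_model()
  S <- stoichiometric_matrix(m)
  expect_equal(dim(S), c(2L, 3L))
  expect_equal(rownames(S), m$metabolites$id)
  expect_equal(colnames(S), reaction_ids(m))
  # internal conversion column: one -1 and one +1
  expect_equal(sort(unname(S[, "AB"])), c(-1, 1))
  # exchange columns: exactly one nonzero
  expect_equal(sum(S[, "EX_A"] != 0), 1L)
  expect_equal(sum(S[, "EX_B"] != 0), 1L)
})

test_that("dead-end detection respects reversibility and sinks", {
  m <- chain_model()
  expect_length(find_dead_end_metabolites(m), 0)

  # drop the terminal export: B becomes a dead end
  m_noexp <- metabolic_model(m$metabolites, m$reactions[c("EX_A", "AB")],
                             objective = "AB")
  expect_equal(find_dead_end_metabolites(m_noexp), "B")

  # a sink fixes it
  m_sink <- add_sink_reaction(m_noexp, "B")
  expect_length(find_dead_end_metabolites(m_sink), 0)

  # a reversible reaction counts as producer and consumer of everything
  m_rev <- m_noexp
  m_rev$reactions[["AB"]]$lb <- -1000
  m_rev <- validate_model(m_rev)
  expect_equal(sort(find_dead_end_metabolites(m_rev)), character(0))
})

test_that("pruning cascades, is idempotent and order-independent", {
  # A -> B -> C, C unconsumed: removing C cascades back to A's producer
  mets <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", stoichiometry = c(A = 1), lb = 0, ub = 10),
    list(id = "AB", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 10),
    list(id = "BC", stoichiometry = c(B = -1, C = 1), lb = 0, ub = 10),
    list(id = "obj", stoichiometry = c(A = -1), lb = 0, ub = 10))
  m <- metabolic_model(mets, rxns, objective = "obj")
  pr <- prune_dead_ends(m)
  # C dead -> BC removed -> B dead -> AB removed; A keeps EX_A + obj
  expect_equal(sort(pr$removed$id[pr$removed$type == "metabolite"]),
               c("B", "C"))
  expect_equal(sort(pr$removed$id[pr$removed$type == "reaction"]),
               c("AB", "BC"))
  expect_equal(reaction_ids(pr$model), c("EX_A", "obj"))

  # idempotence
  pr2 <- prune_dead_ends(pr$model)
  expect_equal(pr2$model, pr$model)
  expect_equal(nrow(pr2$removed), 0L)

  # declaration-order independence of the surviving model
  m_shuf <- metabolic_model(mets[c(3, 1, 2), ], rxns, objective = "obj")
  pr_shuf <- prune_dead_ends(m_shuf)
  expect_setequal(reaction_ids(pr_shuf$model), reaction_ids(pr$model))
  expect_setequal(pr_shuf$model$metabolites$id, pr$model$metabolites$id)

  # a model with no dead ends is untouched
  ok <- chain_model()
  expect_equal(prune_dead_ends(ok)$model, ok)

  # pruning that would take the objective is an error
  bad <- metabolic_model(mets, rxns[-4], objective = "BC")
  expect_error(prune_dead_ends(bad), "objective")
})

test_that("sink insertion validates inputs and rejects duplicates", {
  m <- build_toy_pyrimidine_model()
  m2 <- add_sink_reaction(m, "dho", lb = -1000, ub = 1000)
  s <- m2$reactions[["sink_dho"]]
  expect_true(s$is_sink)
  expect_equal(s$stoichiometry, c(dho = -1))
  expect_equal(c(s$lb, s$ub), c(-1000, 1000))
  expect_error(add_sink_reaction(m2, "dho"), "already exists")
  expect_error(add_sink_reaction(m, "nonexistent"), "unknown metabolite")
  # orotate already carries a built-in sink in the toy model
  expect_error(add_sink_reaction(m, "oro"), "already exists")
})

test_that("model validation catches structural defects", {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  ok <- list(list(id = "r", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1))
  expect_error(metabolic_model(mets, ok, objective = "missing"), "objective")
  bad_bounds <- list(list(id = "r", stoichiometry = c(A = -1), lb = 2, ub = 1))
  expect_error(metabolic_model(mets, bad_bounds, objective = "r"), "lb > ub")
  bad_met <- list(list(id = "r", stoichiometry = c(Z = -1), lb = 0, ub = 1))
  expect_error(metabolic_model(mets, bad_met, objective = "r"),
               "unknown metabolites")
  bad_gene <- list(list(id = "r", stoichiometry = c(A = -1), lb = 0, ub = 1,
                        gpr = "gX"))
  expect_error(metabolic_model(mets, bad_gene, objective = "r",
                               genes = "gY"), "undeclared genes")
})

test_that("GPR grammar parses nesting and rejects malformed rules", {
  tree <- parse_gpr("(g1 and g2) or g3")
  expect_equal(tree$op, "or")
  expect_setequal(gpr_genes(tree), c("g1", "g2", "g3"))
  # case-insensitive operators
  expect_equal(parse_gpr("g1 AND g2")$op, "and")
  expect_null(parse_gpr(""))
  expect_error(parse_gpr("g1 and"), "malformed")
  expect_error(parse_gpr("(g1 or g2"), "malformed")
  expect_error(parse_gpr("and g1"), "malformed")
  # boolean semantics under knockout
  expect_false(gpr_boolean("g1 and g2", "g1"))
  expect_true(gpr_boolean("g1 or g2", "g1"))
})
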