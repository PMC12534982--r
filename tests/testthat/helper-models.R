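# Shared fixtures and an independent brute-force LP oracle.

# linear chain: uptake (ub 10) -> A -> B -> export; objective = export
chain_model <- function(uptake_ub = 10) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", stoichiometry = c(A = 1), lb = 0, ub = uptake_ub,
         gpr = "", is_sink = FALSE),
    list(id = "AB", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE),
    list(id = "EX_B", stoichiometry = c(B = -1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE))
  metabolic_model(mets, rxns, objective = "EX_B")
}

# diamond: A -> B -> D and A -> C -> D, uptake ub 10, objective = D export
diamond_model <- function(uptake_ub = 10) {
  mets <- data.frame(id = c("A", "B", "C", "D"), name = c("A", "B", "C", "D"),
                     compartment = "c", stringsAsFactors = FALSE)
  rxns <- list(
    list(id = "EX_A", stoichiometry = c(A = 1), lb = 0, ub = uptake_ub,
         gpr = "", is_sink = FALSE),
    list(id = "AB", stoichiometry = c(A = -1, B = 1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE),
    list(id = "AC", stoichiometry = c(A = -1, C = 1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE),
    list(id = "BD", stoichiometry = c(B = -1, D = 1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE),
    list(id = "CD", stoichiometry = c(C = -1, D = 1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE),
    list(id = "EX_D", stoichiometry = c(D = -1), lb = 0, ub = 1000,
         gpr = "", is_sink = FALSE))
  metabolic_model(mets, rxns, objective = "EX_D")
}

# Exact vertex enumeration of the bounded polytope {S v = 0, lb <= v <= ub}.
# Every vertex has at least (n - rank(S)) active bound constraints, so all
# choices of that many fixed bounds are enumerated and checked. A linear
# objective attains its optimum at a vertex, which makes this an exact,
# solver-independent LP oracle for small models.
enumerate_vertices <- function(S, lb, ub, tol = 1e-8) {
  n <- length(lb)
  d <- n - qr(S)$rank
  if (d == 0) {
    v <- rep(0, n)
    return(if (all(v >= lb - tol & v <= ub + tol)) matrix(v, 1) else NULL)
  }
  verts <- list()
  combos <- utils::combn(n, d)
  for (ci in seq_len(ncol(combos))) {
    idx <- combos[, ci]
    grid <- as.matrix(expand.grid(rep(list(c(1, 2)), d)))
    for (g in seq_len(nrow(grid))) {
      fixed <- ifelse(grid[g, ] == 1, lb[idx], ub[idx])
      free <- setdiff(seq_len(n), idx)
      rhs <- -S[, idx, drop = FALSE] %*% fixed
      A <- S[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      if (max(abs(A %*% sol - rhs)) > tol) next
      v <- numeric(n)
      v[idx] <- fixed
      v[free] <- sol
      if (all(v >= lb - tol) && all(v <= ub + tol)) {
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  if (length(verts) == 0) return(NULL)
  do.call(rbind, verts)
}

# oracle FVA: per-reaction min/max over vertices of the alpha-constrained
# polytope (biomass row appended as an equality)
oracle_fva <- function(model, alpha = 1) {
  S <- stoichiometric_matrix(model)
  lb <- vapply(model$reactions, `[[`, numeric(1), "lb")
  ub <- vapply(model$reactions, `[[`, numeric(1), "ub")
  obj <- as.numeric(reaction_ids(model) == model$objective)
  V0 <- enumerate_vertices(S, lb, ub)
  fmax <- max(V0 %*% obj)
  # c'v = alpha*fmax as an extra balance row via slack-free substitution:
  # append the row and a fixed auxiliary variable carrying the rhs
  Sx <- rbind(cbind(S, 0), c(obj, -1))
  V <- enumerate_vertices(Sx, c(lb, alpha * fmax), c(ub, alpha * fmax))
  list(fmax = fmax,
       vmin = apply(V[, seq_along(lb), drop = FALSE], 2, min),
       vmax = apply(V[, seq_along(lb), drop = FALSE], 2, max))
}

# toy scenario shared by knockout/pipeline tests: noiseless 5-fold DHODH
# knockdown, single replicate per condition
toy_scenario <- function() {
  model <- build_toy_pyrimidine_model()
  profiles <- simulate_expression_profiles(model, c(DHODH = 0.2),
                                           noise_cv = 0, n_replicates = 1)
  cfg <- integration_config(gamma = 2)
  ctrl <- constrain_model(model, profiles[[1]], cfg)
  trt <- constrain_model(model, profiles[[2]], cfg)
  list(model = model, profiles = profiles, cfg = cfg,
       ctrl_model = ctrl, trt_model = trt)
}
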