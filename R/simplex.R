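# Dense bounded-variable two-phase simplex. Problems here are tiny (tens of
# variables), so the basis is refactorized with solve() at every iteration;
# Bland's rule keeps degenerate FVA subproblems from cycling.

#' Solve a small linear program with equality constraints and box bounds
#'
#' Minimizes (or maximizes) `obj' x` subject to `Aeq x = beq` and
#' `lb <= x <= ub`. All bounds may be infinite; internally infinite bounds
#' are replaced by a large box and a solution resting on that artificial box
#' is reported as unbounded.
#'
#' @param obj numeric objective coefficients.
#' @param Aeq equality constraint matrix (rows are constraints).
#' @param beq equality right-hand sides.
#' @param lb,ub variable bounds (`lb <= ub`, may be +/-Inf).
#' @param maximize maximize instead of minimize.
#' @param tol pivot tolerance.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (solution, NA unless optimal) and `objval`.
#' @keywords internal
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n)
  stopifnot(length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  big <- 1e7
  art_lo <- !is.finite(lb)
  art_hi <- !is.finite(ub)
  lb2 <- ifelse(art_lo, -big, lb)
  ub2 <- ifelse(art_hi, big, ub)

  cost <- if (maximize) -obj else obj
  if (length(beq) == 0L) {
    # pure box problem: optimize each variable at a bound
    x <- ifelse(cost > 0, lb, ifelse(cost < 0, ub, pmin(pmax(0, lb), ub)))
    if (any(!is.finite(x) & cost != 0)) {
      return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
    }
    x[!is.finite(x)] <- pmin(pmax(0, lb), ub)[!is.finite(x)]
    return(list(status = "optimal", x = x, objval = sum(obj * x)))
  }
  # shift x = v - lb so x in [0, u]
  u <- ub2 - lb2
  b <- as.numeric(beq - Aeq %*% lb2)
  flip <- b < 0
  A <- Aeq
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  m <- length(b)

  # phase 1: artificial basis
  Afull <- cbind(A, diag(1, m))
  ufull <- c(u, rep(Inf, m))
  c1 <- c(rep(0, n), rep(1, m))
  st <- .simplex_iterate(Afull, b, c1, ufull,
                         basis = n + seq_len(m),
                         at_upper = rep(FALSE, n + m), tol = tol)
  if (st$status != "optimal" || st$objval > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objval = NA_real_))
  }
  # phase 2: freeze artificials at zero
  ufull[n + seq_len(m)] <- 0
  c2 <- c(cost, rep(0, m))
  st <- .simplex_iterate(Afull, b, c2, ufull,
                         basis = st$basis, at_upper = st$at_upper, tol = tol)
  if (st$status != "optimal") {
    return(list(status = st$status, x = rep(NA_real_, n), objval = NA_real_))
  }
  x <- st$x[seq_len(n)] + lb2
  # artificial box active on a variable whose true bound is infinite
  hit_lo <- art_lo & (x < -big + 1e-4)
  hit_hi <- art_hi & (x > big - 1e-4)
  if (any(hit_lo | hit_hi)) {
    return(list(status = "unbounded", x = rep(NA_real_, n), objval = NA_real_))
  }
  objval <- sum(obj * x)
  list(status = "optimal", x = x, objval = objval)
}

# Bounded-variable simplex on min c'x, A x = b, 0 <= x <= u, from a given
# starting basis. Nonbasic variables sit at 0 or at u (at_upper). Bland's
# rule for both entering and leaving choices.
.simplex_iterate <- function(A, b, cost, u, basis, at_upper, tol = 1e-9,
                             max_iter = 20000L) {
  n <- ncol(A)
  for (iter in seq_len(max_iter)) {
    nonbasic <- setdiff(seq_len(n), basis)
    xN <- ifelse(at_upper[nonbasic], u[nonbasic], 0)
    B <- A[, basis, drop = FALSE]
    rhs <- b - A[, nonbasic, drop = FALSE] %*% xN
    xB <- as.numeric(solve(B, rhs))
    y <- as.numeric(solve(t(B), cost[basis]))
    dN <- cost[nonbasic] - as.numeric(y %*% A[, nonbasic, drop = FALSE])

    elig_lo <- !at_upper[nonbasic] & dN < -tol
    elig_hi <- at_upper[nonbasic] & dN > tol
    elig <- which(elig_lo | elig_hi)
    if (length(elig) == 0L) {
      x <- numeric(n)
      x[basis] <- xB
      x[nonbasic] <- xN
      return(list(status = "optimal", x = x, objval = sum(cost * x),
                  basis = basis, at_upper = at_upper))
    }
    k <- elig[which.min(nonbasic[elig])]  # Bland: smallest variable index
    j <- nonbasic[k]
    s <- if (at_upper[j]) -1 else 1       # direction of change of x_j
    w <- s * as.numeric(solve(B, A[, j]))
    # x_j moves by t >= 0; basic vars move by -t * w
    t_flip <- u[j]
    t_basic <- rep(Inf, length(basis))
    pos <- w > tol
    neg <- w < -tol
    t_basic[pos] <- xB[pos] / w[pos]
    t_basic[neg] <- (u[basis[neg]] - xB[neg]) / (-w[neg])
    t_min <- min(t_basic)
    t_star <- min(t_flip, t_min)
    if (!is.finite(t_star)) {
      return(list(status = "unbounded", x = rep(NA_real_, n),
                  objval = NA_real_, basis = basis, at_upper = at_upper))
    }
    if (t_flip <= t_min) {
      at_upper[j] <- !at_upper[j]
    } else {
      cand <- which(abs(t_basic - t_min) <= tol * (1 + abs(t_min)))
      if (length(cand) == 0L) cand <- which.min(t_basic)
      r <- cand[which.min(basis[cand])]   # Bland on the leaving variable
      leaving <- basis[r]
      at_upper[leaving] <- w[r] < 0       # hit upper bound if moved up
      basis[r] <- j
      at_upper[j] <- FALSE                # entering becomes basic
    }
  }
  stop("simplex iteration limit reached")
}
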