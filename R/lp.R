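# Linear programming layer.
#
# Flux problems are boxed (finite lb/ub everywhere, big-M 1000), so every LP
# here is bounded and the interesting statuses are optimal/infeasible. The
# solver is a dense two-phase primal simplex with Bland's anti-cycling rule:
# the degenerate, rank-deficient equality systems of stoichiometric networks
# are exactly where naive pivoting breaks down, so pivot selection favours
# correctness over speed (model sizes here are tens to a few hundred
# columns).

# Solve: minimize c'x  s.t.  A x (<=,=) b, x >= 0.
# rows: sense vector of "le"/"eq"; b any sign (normalized internally).
simplex_core <- function(cc, A, b, sense, tol = 1e-9, max_iter = 20000L) {
  M <- nrow(A); N <- ncol(A)
  if (M == 0)
    return(list(status = "optimal", x = rep(0, N)))
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  sense[flip & sense == "le"] <- "ge"
  # columns: x (N), slacks/surplus (one per le/ge row), artificials
  n_slack <- sum(sense != "eq")
  slack_col <- integer(M); art_col <- integer(M)
  Ntot <- N + n_slack
  art_rows <- which(sense != "le")
  Ntot2 <- Ntot + length(art_rows)
  T <- matrix(0, M, Ntot2 + 1)
  T[, seq_len(N)] <- A
  T[, Ntot2 + 1] <- b
  sc <- N
  for (i in which(sense != "eq")) {
    sc <- sc + 1L
    slack_col[i] <- sc
    T[i, sc] <- if (sense[i] == "le") 1 else -1
  }
  ac <- Ntot
  for (i in art_rows) {
    ac <- ac + 1L
    art_col[i] <- ac
    T[i, ac] <- 1
  }
  basis <- ifelse(sense == "le", slack_col, art_col)

  pivot <- function(T, r, j) {
    T[r, ] <- T[r, ] / T[r, j]
    for (i in seq_len(nrow(T)))
      if (i != r && abs(T[i, j]) > 0) T[i, ] <- T[i, ] - T[i, j] * T[r, ]
    T
  }
  run_phase <- function(T, basis, cost, allowed) {
    for (it in seq_len(max_iter)) {
      cb <- cost[basis]
      red <- cost[allowed] - as.vector(cb %*% T[, allowed, drop = FALSE])
      enter_rel <- which(red < -tol)
      if (!length(enter_rel))
        return(list(T = T, basis = basis, status = "optimal"))
      j <- allowed[min(enter_rel)]             # Bland: smallest index
      col <- T[, j]
      cand <- which(col > tol)
      if (!length(cand)) return(list(T = T, basis = basis,
                                     status = "unbounded"))
      ratio <- T[cand, ncol(T)] / col[cand]
      best <- cand[ratio <= min(ratio) + tol]
      r <- best[which.min(basis[best])]        # Bland on leaving index
      T <- pivot(T, r, j)
      basis[r] <- j
      T[, ncol(T)] <- pmax(T[, ncol(T)], 0)    # clamp fp noise on rhs
    }
    list(T = T, basis = basis, status = "iteration-limit")
  }

  if (length(art_rows)) {
    cost1 <- c(rep(0, Ntot), rep(1, length(art_rows)))
    ph1 <- run_phase(T, basis, cost1, seq_len(Ntot2))
    T <- ph1$T; basis <- ph1$basis
    obj1 <- sum(cost1[basis] * T[, ncol(T)])
    if (ph1$status != "optimal" || obj1 > 1e-6)
      return(list(status = "infeasible", x = rep(NA_real_, N)))
    # drive remaining artificials out of the basis
    for (r in which(basis > Ntot)) {
      j <- which(abs(T[r, seq_len(Ntot)]) > tol)[1]
      if (is.na(j)) { T[r, ] <- 0; basis[r] <- basis[r] } else {
        T <- pivot(T, r, j)
        basis[r] <- j
      }
    }
  }
  cost2 <- c(cc, rep(0, Ntot2 - N))
  allowed <- seq_len(Ntot)
  live <- which(basis <= Ntot | rowSums(abs(T[, seq_len(Ntot), drop = FALSE])) > tol)
  ph2 <- run_phase(T[live, , drop = FALSE], basis[live], cost2, allowed)
  if (ph2$status == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, N)))
  if (ph2$status != "optimal")
    return(list(status = "infeasible", x = rep(NA_real_, N)))
  x <- rep(0, Ntot2)
  x[ph2$basis] <- ph2$T[, ncol(ph2$T)]
  list(status = "optimal", x = x[seq_len(N)])
}

#' Solve a bounded linear program
#'
#' Maximize (or minimize) `obj %*% v` subject to `A_eq %*% v = b_eq`,
#' `A_le %*% v <= b_le` and `lb <= v <= ub`. All bounds must be finite.
#'
#' @param obj objective coefficient vector.
#' @param A_eq,b_eq equality constraints (matrix may have 0 rows).
#' @param lb,ub variable bounds.
#' @param maximize direction.
#' @param A_le,b_le optional inequality constraints.
#' @return list with `status` (`"optimal"`/`"infeasible"`/`"unbounded"`),
#'   `objective`, and `x` (solution, named after `obj` names if present).
#' @keywords internal
solve_lp <- function(obj, A_eq, b_eq, lb, ub, maximize = TRUE,
                     A_le = NULL, b_le = NULL) {
  n <- length(obj)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  fail <- function(status) list(status = status, objective = NA_real_,
                                x = setNames(rep(NA_real_, n), names(obj)))
  if (any(lb > ub)) return(fail("infeasible"))
  # shift x = v - lb so x >= 0
  A <- diag(n); b <- ub - lb; sense <- rep("le", n)
  if (!is.null(A_le) && nrow(A_le)) {
    A <- rbind(A, A_le)
    b <- c(b, b_le - as.vector(A_le %*% lb))
    sense <- c(sense, rep("le", nrow(A_le)))
  }
  if (nrow(A_eq)) {
    A <- rbind(A, A_eq)
    b <- c(b, b_eq - as.vector(A_eq %*% lb))
    sense <- c(sense, rep("eq", nrow(A_eq)))
  }
  cc <- if (maximize) -obj else obj
  res <- simplex_core(cc, A, b, sense)
  if (res$status != "optimal") return(fail(res$status))
  v <- res$x + lb
  list(status = "optimal", objective = sum(obj * v),
       x = setNames(v, names(obj)))
}

#' Minimal-cardinality mixed-integer program for gap filling
#'
#' Minimize the number of switched-on candidates `y` subject to the flux
#' constraints of the LP above plus `-M*y_j <= v_j <= M*y_j` for candidate
#' columns. Solved by LP-relaxation branch-and-bound on the binaries.
#'
#' @param obj_rxn index of the flux that must reach `min_objective`.
#' @param A_eq steady-state matrix over all columns (model + candidates).
#' @param lb,ub bounds over all columns.
#' @param cand_cols indices of candidate columns (binaries attached).
#' @param min_objective required flux through `obj_rxn`.
#' @param M big-M flux cap.
#' @return list with `status`, `selected` (candidate column indices), or
#'   status `"infeasible"` when even the full candidate set cannot help.
#' @keywords internal
solve_min_card_milp <- function(obj_rxn, A_eq, lb, ub, cand_cols,
                                min_objective, M = 1000) {
  n <- ncol(A_eq); k <- length(cand_cols)
  nv <- n + k
  obj <- c(rep(0, n), rep(1, k))
  Aeq <- cbind(A_eq, matrix(0, nrow(A_eq), k))
  beq <- rep(0, nrow(A_eq))
  Ale <- matrix(0, 2 * k, nv); ble <- rep(0, 2 * k)
  for (i in seq_len(k)) {
    j <- cand_cols[i]
    Ale[2 * i - 1, j] <- 1;  Ale[2 * i - 1, n + i] <- -M
    Ale[2 * i, j] <- -1;     Ale[2 * i, n + i] <- -M
  }
  Ale <- rbind(Ale, c(replace(rep(0, n), obj_rxn, -1), rep(0, k)))
  ble <- c(ble, -min_objective)
  lbx <- c(lb, rep(0, k)); ubx <- c(ub, rep(1, k))

  relax <- function(fix0, fix1) {
    l <- lbx; u <- ubx
    l[n + fix1] <- 1; u[n + fix0] <- 0
    solve_lp(obj, Aeq, beq, l, u, maximize = FALSE, A_le = Ale, b_le = ble)
  }
  best <- list(card = Inf, sel = NULL)
  explore <- function(fix0, fix1) {
    r <- relax(fix0, fix1)
    if (r$status != "optimal" || r$objective >= best$card - 1e-6) return()
    y <- r$x[n + seq_len(k)]
    frac <- which(y > 1e-6 & y < 1 - 1e-6)
    if (!length(frac)) {
      best <<- list(card = round(r$objective), sel = which(y > 0.5))
      return()
    }
    b <- frac[which.max(pmin(y[frac], 1 - y[frac]))]
    explore(fix0, c(fix1, b))
    explore(c(fix0, b), fix1)
  }
  explore(integer(), integer())
  if (!is.finite(best$card))
    return(list(status = "infeasible", selected = integer()))
  list(status = "optimal", selected = cand_cols[best$sel])
}
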