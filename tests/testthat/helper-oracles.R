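# Independent oracles used to cross-check the implementation.

# Brute-force LP oracle: enumerate every candidate vertex of
# {v : S v = 0, lb <= v <= ub} by fixing each subset of variables at a
# bound and solving the equality system for the rest; the optimum of a
# bounded LP is attained at one of these points.
oracle_lp_vertex <- function(obj, S, lb, ub, maximize = TRUE) {
  n <- length(obj)
  best <- NULL
  subsets <- expand.grid(rep(list(c(0, 1, 2)), n))  # 0 free, 1 at lb, 2 at ub
  for (r in seq_len(nrow(subsets))) {
    pick <- as.integer(subsets[r, ])
    fixed <- which(pick > 0)
    free <- which(pick == 0)
    vfix <- ifelse(pick[fixed] == 1, lb[fixed], ub[fixed])
    if (length(free)) {
      A <- S[, free, drop = FALSE]
      rhs <- if (length(fixed))
        -as.vector(S[, fixed, drop = FALSE] %*% vfix) else rep(0, nrow(S))
      qrA <- qr(A)
      if (qrA$rank < length(free)) next          # not a unique vertex here
      vfree <- qr.coef(qrA, rhs)
      if (any(is.na(vfree))) next
      if (max(abs(A %*% vfree - rhs)) > 1e-7) next
      v <- numeric(n); v[fixed] <- vfix; v[free] <- vfree
    } else {
      v <- numeric(n); v[fixed] <- vfix
      if (max(abs(S %*% v)) > 1e-7) next
    }
    if (any(v < lb - 1e-7) || any(v > ub + 1e-7)) next
    z <- sum(obj * v)
    if (is.null(best) || (maximize && z > best) || (!maximize && z < best))
      best <- z
  }
  best  # NULL when infeasible
}

# Independent boolean-rule evaluator: translate the rule string into an R
# expression and evaluate it under a presence assignment.
oracle_eval_rule <- function(rule, present, genes) {
  expr <- gsub("\\b[Aa][Nn][Dd]\\b", "&", rule)
  expr <- gsub("\\b[Oo][Rr]\\b", "|", expr)
  env <- new.env()
  for (g in genes) assign(g, g %in% present, envir = env)
  eval(parse(text = expr), envir = env)
}

# Exhaustive minimal gap-fill: try candidate subsets in order of size.
oracle_gap_fill <- function(model, universal, min_objective) {
  uni <- as_model(universal)
  cand <- setdiff(uni$rxns$id, model$rxns$id)
  for (k in 0:length(cand)) {
    combs <- if (k == 0) list(character()) else
      utils::combn(cand, k, simplify = FALSE)
    for (set in combs) {
      m <- model
      for (r in set) m <- add_reactions(m, uni, r)
      sol <- fba(m)
      if (sol$status == "optimal" && sol$objective_value >= min_objective - 1e-9)
        return(set)
    }
  }
  NULL
}

# Exhaustive essentiality oracle: evaluate each rule with the independent
# evaluator, close disabled reactions, and optimize with the vertex oracle.
oracle_essential_genes <- function(model, cutoff = 0.25) {
  S <- as.matrix(stoich_matrix(model))
  obj <- replace(rep(0, n_rxns(model)),
                 match(model$objective$rxn, model$rxns$id), 1)
  wt <- oracle_lp_vertex(obj, S, model$rxns$lb, model$rxns$ub)
  ess <- character()
  for (g in model$genes) {
    present <- setdiff(model$genes, g)
    lb <- model$rxns$lb; ub <- model$rxns$ub
    for (k in seq_len(n_rxns(model))) {
      rule <- format_dnf(model$gene_rules[[k]])
      if (!nzchar(rule)) next
      if (!oracle_eval_rule(rule, present, model$genes)) {
        lb[k] <- 0; ub[k] <- 0
      }
    }
    ko <- oracle_lp_vertex(obj, S, lb, ub)
    if (is.null(ko)) ko <- 0
    if (ko / wt < cutoff - 1e-9) ess <- c(ess, g)  # strict, fp-tolerant
  }
  ess
}

expect_same_set <- function(a, b) testthat::expect_setequal(a, b)
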