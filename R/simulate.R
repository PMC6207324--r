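#' Flux balance analysis
#'
#' Solves the LP max/min c'v subject to steady state `S v = 0` and
#' `lb <= v <= ub`, with the objective taken from the model (or overridden).
#'
#' @param model a valid `metabolic_model` with an objective set.
#' @param objective_override optional reaction id to optimize instead.
#' @param sense `"max"` or `"min"`; defaults to the model objective sense.
#' @return list of class `flux_distribution`: `status`
#'   (`"optimal"`/`"infeasible"`), `objective_value`, `fluxes` (named vector).
#' @export
fba <- function(model, objective_override = NULL, sense = NULL) {
  obj_rxn <- if (!is.null(objective_override)) objective_override else
    model$objective$rxn
  if (is.null(obj_rxn) || is.na(obj_rxn))
    stop("model has no objective reaction")
  k <- rxn_idx(model, obj_rxn)
  if (is.na(k)) stop("objective reaction not in model: ", obj_rxn)
  if (is.null(sense)) sense <- model$objective$sense
  S <- as.matrix(stoich_matrix(model))
  obj <- setNames(replace(rep(0, n_rxns(model)), k, 1), model$rxns$id)
  res <- solve_lp(obj, S, rep(0, nrow(S)), model$rxns$lb, model$rxns$ub,
                  maximize = identical(sense, "max"))
  structure(list(status = res$status, objective_value = res$objective,
                 fluxes = res$x), class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status=%s objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

open_model_lp <- function(model) {
  list(S = as.matrix(stoich_matrix(model)), lb = model$rxns$lb,
       ub = model$rxns$ub, ids = model$rxns$id)
}

opt_flux <- function(env, j, maximize) {
  obj <- replace(rep(0, length(env$lb)), j, 1)
  solve_lp(obj, env$S, rep(0, nrow(env$S)), env$lb, env$ub,
           maximize = maximize)
}

#' Gap analysis of a metabolic network
#'
#' Reports (i) dead-end metabolites — never produced or never consumed,
#' reversibility-aware; (ii) blocked reactions — unable to carry flux in
#' either direction with exchanges as-is (flux variability); (iii) leaky
#' metabolites — producible with all exchange uptakes closed, a signature of
#' unbalanced reactions; (iv) metabolites consumable from nothing (mirror
#' test with exchange outputs closed); (v) connected components of the
#' metabolite-reaction bipartite graph.
#'
#' @param model a valid `metabolic_model`.
#' @param tol flux tolerance.
#' @return list of class `gap_report` with elements `dead_end_metabolites`,
#'   `blocked_reactions`, `leaky_metabolites`, `consumable_from_nothing`,
#'   `components` (list of character vectors of member ids).
#' @export
gap_report <- function(model, tol = 1e-6) {
  nm <- n_mets(model); nr <- n_rxns(model)
  producers <- consumers <- vector("list", nm)
  names(producers) <- names(consumers) <- model$mets$id
  for (k in seq_len(nr)) {
    rev <- model$rxns$lb[k] < 0 && model$rxns$ub[k] > 0
    s <- model$stoich[[k]]
    for (m in names(s)) {
      if (s[[m]] > 0 || rev) producers[[m]] <- c(producers[[m]], k)
      if (s[[m]] < 0 || rev) consumers[[m]] <- c(consumers[[m]], k)
    }
  }
  dead <- model$mets$id[lengths(producers) == 0 | lengths(consumers) == 0]

  env <- open_model_lp(model)
  blocked <- character()
  for (j in seq_len(nr)) {
    mx <- opt_flux(env, j, TRUE); mn <- opt_flux(env, j, FALSE)
    hi <- if (mx$status == "optimal") abs(mx$objective) else 0
    lo <- if (mn$status == "optimal") abs(mn$objective) else 0
    if (max(hi, lo) < tol) blocked <- c(blocked, model$rxns$id[j])
  }

  exch <- which(model$rxns$exchange)
  leak_test <- function(close_lb) {
    S <- env$S; lb <- env$lb; ub <- env$ub
    if (close_lb) lb[exch] <- pmax(lb[exch], 0) else ub[exch] <- pmin(ub[exch], 0)
    found <- character()
    for (i in seq_len(nm)) {
      # temporary sink (leak) or source (consumable): column +/- e_i
      col <- rep(0, nm); col[i] <- if (close_lb) -1 else 1
      S2 <- cbind(S, col)
      r <- solve_lp(c(rep(0, nr), 1), S2, rep(0, nm),
                    c(lb, 0), c(ub, 1000), maximize = TRUE)
      if (r$status == "optimal" && r$objective > tol)
        found <- c(found, model$mets$id[i])
    }
    found
  }
  leaky <- leak_test(TRUE)
  consumable <- leak_test(FALSE)

  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, nm + nr,
                            name = c(model$mets$id, model$rxns$id))
  edges <- character()
  for (k in seq_len(nr))
    for (m in names(model$stoich[[k]]))
      edges <- c(edges, m, model$rxns$id[k])
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  components <- split(igraph::V(g)$name, comp$membership)
  names(components) <- NULL

  structure(list(dead_end_metabolites = dead, blocked_reactions = blocked,
                 leaky_metabolites = leaky,
                 consumable_from_nothing = consumable,
                 components = components),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf(paste0("<gap_report> %d dead-end mets, %d blocked rxns, ",
                     "%d leaky, %d consumable-from-nothing, %d components\n"),
              length(x$dead_end_metabolites), length(x$blocked_reactions),
              length(x$leaky_metabolites), length(x$consumable_from_nothing),
              length(x$components)))
  invisible(x)
}

#' MILP gap filling against a universal reaction database
#'
#' Finds a minimal-cardinality set of candidate reactions from the universal
#' model that, added to `model`, lets the objective reach `min_objective`.
#' Binary switch variables gate candidate fluxes through big-M constraints;
#' the MILP is solved by branch-and-bound on the LP relaxation.
#'
#' @param model a `metabolic_model` whose objective is below `min_objective`.
#' @param universal a `universal_model` (see [build_universal_model()]) or a
#'   plain `metabolic_model` supplying candidate reactions. Reactions already
#'   in `model` are excluded from the candidate pool.
#' @param min_objective required objective flux.
#' @param M big-M flux cap for candidate reactions.
#' @return character vector of added reaction ids (possibly empty).
#' @export
gap_fill <- function(model, universal, min_objective, M = 1000) {
  uni <- as_model(universal)
  obj_rxn <- model$objective$rxn
  if (is.na(obj_rxn)) stop("model has no objective reaction")
  base <- fba(model)
  if (base$status == "optimal" && base$objective_value >= min_objective - 1e-9)
    return(character())
  cand_ids <- setdiff(uni$rxns$id, model$rxns$id)
  cand_ids <- cand_ids[vapply(cand_ids, function(r)
    length(uni$stoich[[rxn_idx(uni, r)]]) > 0, logical(1))]
  ext <- model
  for (r in cand_ids) ext <- add_reactions(ext, uni, r)
  S <- as.matrix(stoich_matrix(ext))
  cand_cols <- rxn_idx(ext, cand_ids)
  res <- solve_min_card_milp(rxn_idx(ext, obj_rxn), S, ext$rxns$lb,
                             ext$rxns$ub, cand_cols, min_objective, M = M)
  if (res$status != "optimal")
    stop("unfillable: objective cannot reach ", min_objective,
         " even with all candidate reactions")
  ext$rxns$id[res$selected]
}

#' Single-gene deletion essentiality screen
#'
#' Deletes each gene in turn, evaluates every GPR rule under the deletion
#' (a false rule closes the reaction to `[0, 0]`; reactions without rules are
#' untouched), reruns FBA and classifies the gene as essential when growth
#' drops by more than 75% (knockout/wild-type ratio strictly below 0.25).
#'
#' @param model a growing `metabolic_model` (wild-type objective > 1e-6).
#' @param essentiality_cutoff growth-ratio threshold (strict `<`).
#' @return data.frame of class `essentiality_result`: `gene`, `wt_growth`,
#'   `ko_growth`, `ratio`, `essential`.
#' @export
single_gene_deletion <- function(model, essentiality_cutoff = 0.25) {
  wt <- fba(model)
  if (wt$status != "optimal" || wt$objective_value <= 1e-6)
    stop("wild-type model does not grow; essentiality is undefined")
  res <- lapply(model$genes, function(g) {
    ko <- model
    present <- setdiff(model$genes, g)
    off <- vapply(seq_len(n_rxns(model)), function(k)
      !eval_dnf(model$gene_rules[[k]], present), logical(1))
    ko$rxns$lb[off] <- 0; ko$rxns$ub[off] <- 0
    sol <- fba(ko)
    kg <- if (sol$status == "optimal") max(sol$objective_value, 0) else 0
    data.frame(gene = g, wt_growth = wt$objective_value, ko_growth = kg,
               ratio = kg / wt$objective_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), wt_growth = numeric(),
                      ko_growth = numeric(), ratio = numeric())
  # strict "more than 75% reduction", with LP round-off guarded at 1e-9
  out$essential <- out$ratio < essentiality_cutoff - 1e-9
  class(out) <- c("essentiality_result", "data.frame")
  out
}

#' Growth screening over nutrient sources
#'
#' For each condition, opens uptake through the named exchange reaction
#' (lower bound `-uptake_bound`) on top of the model's fixed minimal-media
#' exchange bounds, runs FBA and calls growth when the objective exceeds
#' 1e-6. Sensitivity and specificity are computed against observed labels.
#'
#' @param model a valid `metabolic_model` whose exchange bounds encode the
#'   minimal medium.
#' @param conditions data.frame with columns `exchange` (reaction id),
#'   `uptake_bound` (positive uptake cap, default 10 if NA) and `observed`
#'   (logical: experimentally observed growth).
#' @return list of class `growth_screen`: `results` data.frame (condition
#'   predictions), `sensitivity`, `specificity`.
#' @export
growth_screen <- function(model, conditions) {
  if (!nrow(conditions)) stop("empty condition list")
  unk <- setdiff(conditions$exchange, model$rxns$id)
  if (length(unk))
    stop("unknown exchange reaction(s) in conditions: ",
         paste(unk, collapse = ", "))
  if (is.null(conditions$uptake_bound)) conditions$uptake_bound <- NA_real_
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    m <- model
    k <- rxn_idx(m, conditions$exchange[i])
    b <- conditions$uptake_bound[i]
    if (is.na(b)) b <- 10
    m$rxns$lb[k] <- -abs(b)
    sol <- fba(m)
    grows <- sol$status == "optimal" && sol$objective_value > 1e-6
    data.frame(exchange = conditions$exchange[i],
               predicted = grows, observed = conditions$observed[i],
               objective = if (sol$status == "optimal") sol$objective_value else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  tp <- sum(res$predicted & res$observed)
  fn <- sum(!res$predicted & res$observed)
  tn <- sum(!res$predicted & !res$observed)
  fp <- sum(res$predicted & !res$observed)
  structure(list(results = res,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "growth_screen")
}

# parsimonious refinement: fix the objective flux, minimize sum |v| so that
# reported trajectories are stable under degenerate optima.
pfba_fluxes <- function(env, obj_col, obj_value) {
  n <- length(env$lb)
  # split v = p - q, p,q >= 0
  S2 <- cbind(env$S, -env$S)
  Aeq <- rbind(S2, c(replace(rep(0, n), obj_col, 1),
                     replace(rep(0, n), obj_col, -1)))
  beq <- c(rep(0, nrow(env$S)), obj_value)
  # bounds: p - q within [lb, ub]: enforce via p <= max(ub,0), q <= max(-lb,0)
  # plus pairwise constraint p - q <= ub, -(p - q) <= -lb
  Ale <- rbind(cbind(diag(n), -diag(n)), cbind(-diag(n), diag(n)))
  ble <- c(env$ub, -env$lb)
  r <- solve_lp(rep(1, 2 * n), Aeq, beq,
                rep(0, 2 * n), c(pmax(env$ub, 0), pmax(-env$lb, 0)),
                maximize = FALSE, A_le = Ale, b_le = ble)
  if (r$status != "optimal") return(NULL)
  setNames(r$x[seq_len(n)] - r$x[n + seq_len(n)], env$ids)
}

#' Flux scanning with enforced objective function (FSEOF)
#'
#' Scans candidate amplification targets for overproduction: product flux is
#' enforced stepwise from its wild-type level towards `max_fraction` of its
#' theoretical maximum while biomass is maximized, and reactions whose
#' absolute flux increases monotonically with constant sign are flagged as
#' targets. At each level a secondary minimization of total absolute flux
#' stabilizes trajectories under degenerate optima. Direction codes:
#' 0 = irreversible reaction, otherwise the sign of the carried flux
#' (1 forward, -1 reverse).
#'
#' @param model a valid `metabolic_model`.
#' @param biomass_rxn biomass (growth) reaction id.
#' @param product_rxn product sink/exchange reaction id.
#' @param n_levels number of enforcement steps.
#' @param max_fraction fraction of the theoretical product maximum enforced
#'   at the last step.
#' @param tol monotonicity tolerance.
#' @return list of class `fseof_result`: `levels` (enforced product lower
#'   bounds), `fluxes` (reactions x levels matrix), `table` data.frame with
#'   `rxn`, `slope`, `direction`, `is_target`.
#' @export
fseof <- function(model, biomass_rxn, product_rxn, n_levels = 10,
                  max_fraction = 0.9, tol = 1e-6) {
  for (r in c(biomass_rxn, product_rxn))
    if (is.na(rxn_idx(model, r))) stop("unknown reaction id: ", r)
  vmax <- fba(model, objective_override = product_rxn, sense = "max")
  if (vmax$status != "optimal" || vmax$objective_value <= tol)
    stop("product unreachable: maximum product flux is not positive")
  base <- fba(model, objective_override = biomass_rxn, sense = "max")
  if (base$status != "optimal") stop("biomass optimization infeasible")
  v0 <- base$fluxes[[product_rxn]]
  top <- max_fraction * vmax$objective_value
  levels <- v0 + seq_len(n_levels) / n_levels * (top - v0)

  env <- open_model_lp(model)
  pcol <- rxn_idx(model, product_rxn)
  bcol <- rxn_idx(model, biomass_rxn)
  fl <- matrix(NA_real_, n_rxns(model), n_levels,
               dimnames = list(model$rxns$id, NULL))
  for (i in seq_along(levels)) {
    env_i <- env
    env_i$lb[pcol] <- max(env_i$lb[pcol], levels[i])
    sol <- opt_flux(env_i, bcol, TRUE)
    if (sol$status != "optimal")
      stop("biomass infeasible at enforced product level ", levels[i])
    v <- pfba_fluxes(env_i, bcol, sol$objective)
    if (is.null(v)) v <- sol$x
    fl[, i] <- v
  }
  irrev <- !(model$rxns$lb < 0 & model$rxns$ub > 0)
  tab <- lapply(seq_len(n_rxns(model)), function(k) {
    f <- fl[k, ]
    a <- abs(f)
    nondec <- all(diff(a) >= -tol)
    increasing <- a[n_levels] > a[1] + tol
    nz <- f[abs(f) > tol]
    sign_const <- length(nz) == 0 || all(sign(nz) == sign(nz[1]))
    dirn <- if (irrev[k]) 0L else
      as.integer(if (length(nz)) sign(nz[length(nz)]) else 1)
    data.frame(rxn = model$rxns$id[k],
               slope = unname(a[n_levels] - a[1]),
               direction = dirn,
               is_target = nondec && increasing && sign_const,
               stringsAsFactors = FALSE)
  })
  structure(list(levels = levels, fluxes = fl, table = do.call(rbind, tab)),
            class = "fseof_result")
}

#' @export
print.fseof_result <- function(x, ...) {
  tg <- x$table$rxn[x$table$is_target]
  cat(sprintf("<fseof_result> %d levels, %d targets: %s\n",
              length(x$levels), length(tg), paste(tg, collapse = ", ")))
  invisible(x)
}
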