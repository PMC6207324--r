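tm <- toy_models()

test_that("FBA matches conservation on the chain and closes with uptake", {
  sol <- fba(tm$toy_chain)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10, tolerance = 1e-6)
  S <- as.matrix(stoich_matrix(tm$toy_chain))
  expect_lt(max(abs(S %*% sol$fluxes)), 1e-6)

  closed <- tm$toy_chain
  closed$rxns$lb[rxn_idx(closed, "EX_A")] <- 0
  expect_equal(fba(closed)$objective_value, 0, tolerance = 1e-9)

  noobj <- tm$toy_chain
  noobj$objective$rxn <- NA_character_
  expect_error(fba(noobj), "objective")
})

test_that("FBA equals the brute-force vertex-enumeration oracle", {
  for (seed in 1:12) {
    m <- rand_network(seed)
    sol <- fba(m)
    S <- as.matrix(stoich_matrix(m))
    obj <- replace(rep(0, n_rxns(m)), rxn_idx(m, m$objective$rxn), 1)
    want <- oracle_lp_vertex(obj, S, m$rxns$lb, m$rxns$ub)
    expect_false(is.null(want))
    expect_equal(sol$objective_value, want, tolerance = 1e-6, info = seed)
  }
})

test_that("gap report finds dead ends, leaks, and components", {
  # met D produced by one reaction and never consumed
  m <- tm$toy_chain
  m <- add_metabolite(m, "D_c", "D", "c", formula = "C1")
  m <- add_reaction(m, "RD", c(A_c = -1, D_c = 1))
  gr <- gap_report(m)
  expect_true("D_c" %in% gr$dead_end_metabolites)
  expect_true("RD" %in% gr$blocked_reactions)

  # imbalanced duplication makes B leaky under closed exchanges
  gr2 <- gap_report(tm$toy_leaky)
  expect_equal(gr2$leaky_metabolites, "B_c")

  # mass-conserving fixtures never leak
  for (nm in c("toy_chain", "toy_branch", "toy_gpr")) {
    g <- gap_report(tm[[nm]])
    expect_length(g$leaky_metabolites, 0)
    expect_length(g$consumable_from_nothing, 0)
  }

  # two disjoint pathways give two components
  two <- merge_models(tm$toy_chain, {
    x <- new_model("x")
    x <- add_metabolite(x, "P_c", "P", "c")
    x <- add_metabolite(x, "Q_c", "Q", "c")
    add_reaction(x, "RPQ", c(P_c = -1, Q_c = 1))
  })
  expect_length(gap_report(two)$components, 2)

  # consumable-from-nothing mirror: 2B -> B destroys mass
  sink <- add_reaction(tm$toy_chain, "SHRINK", c(B_c = -1),
                       name = "2B to B net")
  expect_true("B_c" %in% gap_report(sink)$consumable_from_nothing)
})

test_that("every reaction touching a dead-end on its only side is blocked", {
  m <- tm$toy_chain
  m <- add_metabolite(m, "D_c", "D", "c")
  m <- add_reaction(m, "RD", c(A_c = -1, D_c = 1))
  gr <- gap_report(m)
  for (d in gr$dead_end_metabolites)
    for (k in seq_len(n_rxns(m)))
      if (d %in% names(m$stoich[[k]]))
        expect_true(m$rxns$id[k] %in% gr$blocked_reactions)
})

test_that("gap filling returns a minimal set matching exhaustive search", {
  got <- gap_fill(tm$toy_gapped, tm$toy_gapped_universal, 1)
  want <- oracle_gap_fill(tm$toy_gapped, tm$toy_gapped_universal, 1)
  expect_setequal(got, want)
  expect_equal(got, "R2")

  # already-growing model needs nothing
  expect_length(gap_fill(tm$toy_chain, tm$toy_gapped_universal, 1), 0)

  # unfillable: no candidate produces the biomass precursor
  poor <- remove_reactions(tm$toy_gapped_universal, "R2",
                           prune_orphans = TRUE)
  expect_error(gap_fill(tm$toy_gapped, poor, 1), "unfillable")
})

test_that("gap filling stays minimal with redundant long candidate paths", {
  # universal offering both a 1-step and a 2-step repair of the same gap
  uni <- tm$toy_gapped_universal
  uni <- add_metabolite(uni, "Z_c", "Z", "c")
  uni <- add_reaction(uni, "RZ1", c(B_c = -1, Z_c = 1))
  uni <- add_reaction(uni, "RZ2", c(Z_c = -1, C_c = 1))
  got <- gap_fill(tm$toy_gapped, uni, 1)
  want <- oracle_gap_fill(tm$toy_gapped, uni, 1)
  expect_equal(length(got), length(want))
  expect_equal(got, "R2")

  # with the 1-step repair removed, the MILP must pick the 2-step path
  uni2 <- remove_reactions(uni, "R2", prune_orphans = TRUE)
  got2 <- gap_fill(tm$toy_gapped, uni2, 1)
  expect_setequal(got2, c("RZ1", "RZ2"))
})

test_that("essentiality matches the exhaustive oracle; 0.25 is non-essential", {
  res <- single_gene_deletion(tm$toy_gpr)
  want <- oracle_essential_genes(tm$toy_gpr)
  expect_setequal(res$gene[res$essential], want)
  expect_setequal(res$gene[res$essential], "g1")

  # isozyme deletion leaves full growth
  expect_equal(res$ratio[res$gene == "g6"], 1)
  # boundary: exactly 75% reduction is not essential (strict rule)
  expect_equal(res$ratio[res$gene == "g2"], 0.25, tolerance = 1e-9)
  expect_false(res$essential[res$gene == "g2"])
  # transporter knockout kills growth
  expect_equal(res$ratio[res$gene == "g1"], 0)

  nogrow <- tm$toy_gpr
  nogrow$rxns$ub[rxn_idx(nogrow, "EX_A")] <- 0
  nogrow$rxns$lb[rxn_idx(nogrow, "EX_A")] <- 0
  expect_error(single_gene_deletion(nogrow), "grow")
})

test_that("growth screen opens one nutrient at a time and scores predictions", {
  m <- tm$toy_chain
  m <- add_metabolite(m, "N_e", "N", "e", formula = "C1")
  m <- add_reaction(m, "EX_N", c(N_e = -1), lb = 0, ub = 1000,
                    exchange = TRUE)   # closed by default; no path inward
  m$rxns$lb[rxn_idx(m, "EX_A")] <- 0   # variable nutrient, closed at baseline
  conditions <- data.frame(exchange = c("EX_A", "EX_N"),
                           uptake_bound = c(10, 10),
                           observed = c(TRUE, FALSE),
                           stringsAsFactors = FALSE)
  sc <- growth_screen(m, conditions)
  expect_equal(sc$results$predicted, c(TRUE, FALSE))
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$specificity, 1)

  # observed growth on a source with no path counts against sensitivity
  cond2 <- data.frame(exchange = c("EX_A", "EX_N"), uptake_bound = 10,
                      observed = c(TRUE, TRUE), stringsAsFactors = FALSE)
  sc2 <- growth_screen(m, cond2)
  expect_equal(sc2$sensitivity, 0.5)

  expect_error(growth_screen(m, conditions[0, ]), "empty")
  expect_error(growth_screen(m, data.frame(exchange = "EX_NOPE",
                                           uptake_bound = 10,
                                           observed = TRUE)), "EX_NOPE")
})

test_that("FSEOF flags exactly the product branch with monotone trajectories", {
  fs <- fseof(tm$toy_branch, "GROWTH", "EX_P")
  targets <- fs$table$rxn[fs$table$is_target]
  expect_setequal(targets, c("RP", "EX_P"))
  for (r in targets) {
    tr <- abs(fs$fluxes[r, ])
    expect_true(all(diff(tr) >= -1e-6))
    expect_gt(tr[length(tr)], tr[1])
  }
  # shared uptake stays constant: not a target
  expect_false(fs$table$is_target[fs$table$rxn == "EX_A"])
  expect_equal(abs(unname(fs$fluxes["EX_A", ])), rep(10, 10),
               tolerance = 1e-6)
  # biomass branch decreases: not a target
  expect_false(fs$table$is_target[fs$table$rxn == "RB"])
  # direction codes: 0 iff irreversible
  irrev <- !(tm$toy_branch$rxns$lb < 0 & tm$toy_branch$rxns$ub > 0)
  expect_equal(fs$table$direction == 0,
               unname(irrev[match(fs$table$rxn, tm$toy_branch$rxns$id)]))

  expect_error(fseof(tm$toy_chain, "GROWTH", "GROWTH2"), "unknown")
  blocked <- tm$toy_branch
  blocked$rxns$ub[rxn_idx(blocked, "EX_P")] <- 0
  expect_error(fseof(blocked, "GROWTH", "EX_P"), "unreachable")
})

test_that("FSEOF target set is invariant to reaction order and bound rescaling", {
  base <- fseof(tm$toy_branch, "GROWTH", "EX_P")
  tset <- sort(base$table$rxn[base$table$is_target])

  perm <- tm$toy_branch
  ord <- c(4, 2, 7, 1, 5, 3, 6)
  perm$rxns <- perm$rxns[ord, ]; rownames(perm$rxns) <- NULL
  perm$stoich <- perm$stoich[ord]
  perm$gene_rules <- perm$gene_rules[ord]
  perm$raw_rules <- perm$raw_rules[ord]
  perm$ec <- perm$ec[ord]
  perm$rxn_xrefs <- perm$rxn_xrefs[ord]
  perm$provenance <- perm$provenance[ord]
  fs2 <- fseof(perm, "GROWTH", "EX_P")
  expect_equal(sort(fs2$table$rxn[fs2$table$is_target]), tset)

  scaled <- tm$toy_branch
  scaled$rxns$lb <- scaled$rxns$lb * 2
  scaled$rxns$ub <- scaled$rxns$ub * 2
  fs3 <- fseof(scaled, "GROWTH", "EX_P")
  expect_equal(sort(fs3$table$rxn[fs3$table$is_target]), tset)
})
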