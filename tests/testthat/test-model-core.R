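test_that("validation flags bad bounds, unknown genes, and passes clean models", {
  tm <- toy_models()
  expect_identical(nrow(validate_model(tm$toy_chain)), 0L)

  m <- tm$toy_chain
  m$rxns$lb[3] <- 5; m$rxns$ub[3] <- 1
  v <- validate_model(m)
  expect_true(any(v$code == "bounds" & v$element == m$rxns$id[3]))

  m2 <- tm$toy_chain
  m2$gene_rules[[3]] <- list("gX")
  v2 <- validate_model(m2)
  expect_true(any(v2$code == "unknown-gene" &
                    grepl("gX", v2$message)))

  m3 <- remove_reactions(tm$toy_chain, "GROWTH")
  v3 <- validate_model(m3)
  expect_true(any(v3$code == "objective-missing"))
})

test_that("add_reactions copies reactions with required metabolites only", {
  tm <- toy_models()
  donor <- tm$toy_chain
  empty <- new_model("empty")
  m <- add_reactions(empty, donor, "R1")
  expect_equal(n_rxns(m), 1)
  expect_equal(n_mets(m), 2)

  # pre-existing metabolite is not duplicated
  m2 <- new_model("partial")
  m2 <- add_metabolite(m2, "A_c", "A", "c")
  m2 <- add_reactions(m2, donor, "R1")
  expect_equal(n_mets(m2), 2)

  # copied reactions get manual provenance
  expect_equal(m$provenance[[1]][[1]]$source, "manual")

  expect_error(add_reactions(empty, donor, "NOPE"), "NOPE")
  clash <- add_metabolite(new_model("clash"), "A_c", "A", "c")
  clash <- add_metabolite(clash, "B_c", "B", "c")
  clash <- add_reaction(clash, "R1", c(A_c = -2, B_c = 1))
  expect_error(add_reactions(clash, donor, "R1"), "stoichiometry")
})

test_that("remove_reactions prunes orphans only when asked and round-trips", {
  tm <- toy_models()
  m <- tm$toy_chain
  kept <- remove_reactions(m, "GROWTH", prune_orphans = FALSE)
  expect_true("B_c" %in% kept$mets$id)
  expect_true("B_c" %in% gap_report(kept)$dead_end_metabolites)

  pruned <- remove_reactions(remove_reactions(m, "GROWTH"), "R1",
                             prune_orphans = TRUE)
  expect_false("B_c" %in% pruned$mets$id)
  expect_error(remove_reactions(m, "NOPE"), "NOPE")

  # add then remove with pruning restores the original structure
  donor <- tm$toy_branch
  grown <- add_reactions(m, donor, c("RP", "EX_P"))
  back <- remove_reactions(grown, c("RP", "EX_P"), prune_orphans = TRUE)
  expect_setequal(back$rxns$id, m$rxns$id)
  expect_setequal(back$mets$id, m$mets$id)
})

test_that("gene rule parsing expands to DNF equivalent under all assignments", {
  expect_equal(parse_gene_rule("g1 and (g2 or g3)"),
               list(c("g1", "g2"), c("g1", "g3")))
  expect_equal(parse_gene_rule("g1 or g1"), list("g1"))
  expect_error(parse_gene_rule("g1 and or g2"), "position")
  expect_error(parse_gene_rule("g1 and (g2"), "\\)")
  expect_null(parse_gene_rule(""))

  rules <- c("g1", "g1 and g2", "g1 or (g2 and g3)",
             "(g1 or g2) and (g3 or g4)",
             "((g1 and g2) or g3) and (g4 or (g5 and g1))",
             "g1 AND g2 OR g3")
  genes <- sprintf("g%d", 1:5)
  for (rule in rules) {
    dnf <- parse_gene_rule(rule)
    for (mask in 0:(2^length(genes) - 1)) {
      present <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
      expect_identical(eval_dnf(dnf, present),
                       oracle_eval_rule(rule, present, genes),
                       info = paste(rule, "| present:",
                                    paste(present, collapse = ",")))
    }
  }
})

test_that("standardize_gene_rules canonicalizes, syncs genes, is idempotent", {
  m <- new_model("m")
  m <- add_metabolite(m, "A_c", "A", "c")
  m <- add_metabolite(m, "B_c", "B", "c")
  m <- add_reaction(m, "R1", c(A_c = -1, B_c = 1),
                    gene_rule = "gB and (gA or gC)")
  m$genes <- c(m$genes, "gZ")  # stale gene
  s1 <- standardize_gene_rules(m)
  expect_equal(s1$gene_rules[[1]], list(c("gA", "gB"), c("gB", "gC")))
  expect_setequal(s1$genes, c("gA", "gB", "gC"))
  expect_identical(standardize_gene_rules(s1)$gene_rules, s1$gene_rules)

  m$raw_rules[1] <- "gA and or gB"
  expect_error(standardize_gene_rules(m), "R1")
})

test_that("change_gene_association replaces, appends genes, clears on empty", {
  tm <- toy_models()
  m <- change_gene_association(tm$toy_gpr, "R1", "g9")
  expect_true("g9" %in% m$genes)
  expect_equal(m$gene_rules[[rxn_idx(m, "R1")]], list("g9"))
  m2 <- change_gene_association(m, "R1", "")
  expect_null(m2$gene_rules[[rxn_idx(m2, "R1")]])
  expect_error(change_gene_association(m, "NOPE", "g1"), "NOPE")
})

test_that("merge_models unions by id, OR-combines rules, widens bounds", {
  tm <- toy_models()
  a <- tm$toy_chain

  # idempotence
  aa <- merge_models(a, a)
  expect_equal(n_rxns(aa), n_rxns(a))
  expect_equal(n_mets(aa), n_mets(a))
  expect_identical(aa$gene_rules, a$gene_rules)

  # additivity on disjoint models
  b <- new_model("b")
  b <- add_metabolite(b, "X_c", "X", "c")
  b <- add_metabolite(b, "Y_c", "Y", "c")
  b <- add_reaction(b, "RX", c(X_c = -1, Y_c = 1))
  ab <- merge_models(a, b)
  expect_equal(n_rxns(ab), n_rxns(a) + 1)

  # OR-union of rules and widened bounds on shared reactions
  c1 <- change_gene_association(a, "R1", "g1")
  c2 <- change_gene_association(a, "R1", "g2")
  c2$rxns$lb[rxn_idx(c2, "R1")] <- -1000
  m <- merge_models(c1, c2)
  k <- rxn_idx(m, "R1")
  expect_equal(m$gene_rules[[k]], list("g1", "g2"))
  expect_equal(m$rxns$lb[k], -1000)

  # commutativity up to ordering
  m2 <- merge_models(c2, c1)
  expect_setequal(m$rxns$id, m2$rxns$id)
  expect_equal(m$gene_rules[[k]], m2$gene_rules[[rxn_idx(m2, "R1")]])

  conflict <- a
  conflict$stoich[[rxn_idx(conflict, "R1")]] <- c(A_c = -2, B_c = 1)
  expect_error(merge_models(a, conflict), "R1")
})
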