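fx1 <- generate_bundle(fixture_spec(seed = 1))
ph1 <- generate_proteome_and_hits(fx1, fixture_spec(seed = 1))
uni1 <- build_universal_model(fx1$bundle)

test_that("universal model preserves bundle counts and reversibility bounds", {
  b <- fx1$bundle
  expect_equal(n_rxns(uni1$model), nrow(b$reactions))
  expect_equal(length(uni1$met_ids), nrow(b$metabolites))
  expect_equal(nrow(uni1$enzymes), nrow(b$enzymes))
  rev_ids <- b$reactions$id[b$reactions$reversible == "1"]
  for (r in rev_ids) {
    k <- rxn_idx(uni1$model, r)
    expect_equal(unname(unlist(uni1$model$rxns[k, c("lb", "ub")])),
                 c(-1000, 1000))
  }
  irr <- setdiff(b$reactions$id, rev_ids)[1]
  expect_equal(uni1$model$rxns$lb[rxn_idx(uni1$model, irr)], 0)
  expect_equal(nrow(validate_model(uni1$model)[
    validate_model(uni1$model)$severity == "error", ]), 0)
})

test_that("bundle referential integrity is enforced", {
  b <- fx1$bundle
  b$enzymes$reactions[1] <- "R_UNKNOWN"
  expect_error(build_universal_model(b), "R_UNKNOWN")
  b2 <- fx1$bundle
  b2$reactions$equation[1] <- "GHOST => M1_1"
  expect_error(build_universal_model(b2), "GHOST")
  b3 <- fx1$bundle
  b3$sequences <- b3$sequences[-1, ]
  expect_error(build_universal_model(b3), "missing sequence")
})

test_that("homology thresholds gate enzyme support exactly at 100 bits / 45%", {
  enz1 <- uni1$enzymes$id[lengths(uni1$enzymes$subunits) == 0][1]
  rxns1 <- uni1$enzymes$reactions[[match(enz1, uni1$enzymes$id)]]
  hit <- function(bit, pos)
    data.frame(query_id = "q", subject_id = enz1, evalue = 1e-60,
               bit_score = bit, percent_positives = pos,
               percent_identity = pos, aln_length = 100L,
               stringsAsFactors = FALSE)
  expect_setequal(reconstruct_from_database(uni1, hit(120, 50))$rxns$id,
                  rxns1)
  expect_equal(n_rxns(reconstruct_from_database(uni1, hit(99.9, 80))), 0)
  expect_equal(n_rxns(reconstruct_from_database(uni1, hit(150, 44.9))), 0)
  expect_setequal(reconstruct_from_database(uni1, hit(100, 45))$rxns$id,
                  rxns1)
})

test_that("planted fixture is recovered exactly; decoys stay out", {
  draft <- reconstruct_from_database(uni1, ph1$hits)
  expect_setequal(draft$rxns$id, fx1$truth$planted_reactions)
  # no reaction lacks provenance
  expect_true(all(lengths(draft$provenance) > 0))
  # transport reactions span c and e
  tr <- intersect(draft$rxns$id, fx1$truth$transport)
  for (r in tr) {
    s <- draft$stoich[[rxn_idx(draft, r)]]
    comps <- draft$mets$comp[match(names(s), draft$mets$id)]
    expect_setequal(comps, c("e", "c"))
  }
})

test_that("raising thresholds never adds reactions", {
  base <- reconstruct_from_database(uni1, ph1$hits, 100, 45)$rxns$id
  for (mb in c(120, 150, 200))
    expect_true(all(reconstruct_from_database(uni1, ph1$hits, mb, 45)$rxns$id
                    %in% base))
  for (mp in c(60, 80, 99))
    expect_true(all(reconstruct_from_database(uni1, ph1$hits, 100, mp)$rxns$id
                    %in% base))
})

test_that("unknown hit subjects are ignored with a warning", {
  h <- ph1$hits
  h$subject_id[1] <- "NOT_AN_ENZYME"
  expect_warning(d <- reconstruct_from_database(uni1, h), "NOT_AN_ENZYME")
  expect_true(n_rxns(d) > 0)
})

test_that("spontaneous reactions join only when reactants are present", {
  uni <- uni1
  # build a tiny draft holding the substrates of the first spontaneous rxn
  sp <- fx1$truth$spontaneous[1]
  k <- rxn_idx(uni$model, sp)
  s <- uni$model$stoich[[k]]
  subs <- names(s)[s < 0]; prods <- names(s)[s > 0]
  draft <- new_model("d")
  for (m in subs) {
    km <- met_idx(uni$model, m)
    draft <- add_metabolite(draft, m, comp = uni$model$mets$comp[km],
                            db_id = uni$model$mets$db_id[km])
  }
  out <- add_spontaneous_reactions(draft, uni)
  expect_true(sp %in% out$rxns$id)
  expect_true(all(prods %in% out$mets$id))      # product created
  expect_null(out$gene_rules[[rxn_idx(out, sp)]])
  expect_true(out$rxns$spontaneous[rxn_idx(out, sp)])

  # idempotent
  out2 <- add_spontaneous_reactions(out, uni)
  expect_equal(n_rxns(out2), n_rxns(out))

  # absent substrate blocks addition
  draft2 <- new_model("d2")
  km <- met_idx(uni$model, subs[1])
  draft2 <- add_metabolite(draft2, subs[1], comp = uni$model$mets$comp[km],
                           db_id = uni$model$mets$db_id[km])
  out3 <- add_spontaneous_reactions(draft2, uni)
  expect_false(sp %in% out3$rxns$id)

  # reversible spontaneous: product side alone suffices
  draft4 <- new_model("d4")
  for (m in prods) {
    km <- met_idx(uni$model, m)
    draft4 <- add_metabolite(draft4, m, comp = uni$model$mets$comp[km],
                             db_id = uni$model$mets$db_id[km])
  }
  out4 <- add_spontaneous_reactions(draft4, uni)
  expect_true(sp %in% out4$rxns$id)

  # never adds a reaction with zero substrate overlap with the prior draft
  empty <- new_model("e")
  expect_equal(n_rxns(add_spontaneous_reactions(empty, uni)), 0)
})
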