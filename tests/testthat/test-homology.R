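mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query_id = r[[1]], subject_id = r[[2]],
               evalue = as.numeric(r[[3]]), bit_score = as.numeric(r[[4]]),
               percent_positives = 50, percent_identity = 50,
               aln_length = 100L, stringsAsFactors = FALSE)))
}

test_that("bidirectional best hits require reciprocity and thresholds", {
  fwd <- mk_hits(list("A", "a", 1e-60, 200), list("A", "b", 1e-40, 150),
                 list("B", "b", 1e-50, 180))
  rev <- mk_hits(list("a", "A", 1e-62, 210), list("b", "A", 1e-45, 160),
                 list("b", "B", 1e-30, 120))
  bbh <- bidirectional_best_hits(fwd, rev, min_bit = 100, max_eval = 1e-20)
  # exhaustive check over the toy table: only (A,a) is reciprocal-best
  expect_equal(bbh$query_gene, "A")
  expect_equal(bbh$template_gene, "a")

  # reciprocity violated: rev best of a is B
  rev2 <- mk_hits(list("a", "B", 1e-70, 250), list("a", "A", 1e-62, 210))
  expect_equal(nrow(bidirectional_best_hits(fwd, rev2)), 0)

  # thresholds are applied to both directions
  expect_equal(nrow(bidirectional_best_hits(fwd, rev, min_bit = 205)), 0)
})

test_that("best-hit ties break by e-value then lexicographic subject", {
  fwd <- mk_hits(list("A", "b", 1e-50, 200), list("A", "a", 1e-50, 200))
  rev <- mk_hits(list("a", "A", 1e-50, 200), list("b", "A", 1e-50, 200))
  bbh <- bidirectional_best_hits(fwd, rev, max_eval = 1)
  expect_equal(bbh$template_gene, "a")

  fwd2 <- mk_hits(list("A", "b", 1e-60, 200), list("A", "a", 1e-50, 200))
  bbh2 <- bidirectional_best_hits(fwd2, rev, max_eval = 1)
  expect_equal(bbh2$template_gene, "b")
})

test_that("template reconstruction rewrites rules and drops partial complexes", {
  tpl <- new_model("tpl")
  tpl <- add_metabolite(tpl, "A_c", "A", "c")
  tpl <- add_metabolite(tpl, "B_c", "B", "c")
  tpl <- add_metabolite(tpl, "C_c", "C", "c")
  tpl <- add_reaction(tpl, "R1", c(A_c = -1, B_c = 1),
                      gene_rule = "t1 or t2")
  tpl <- add_reaction(tpl, "R2", c(B_c = -1, C_c = 1),
                      gene_rule = "t1 and t3")
  tpl <- add_reaction(tpl, "R3", c(A_c = -1, C_c = 1))

  pairs <- data.frame(query_gene = "q1", template_gene = "t1",
                      stringsAsFactors = FALSE)
  draft <- reconstruct_from_template(tpl, pairs)
  expect_equal(draft$rxns$id, "R1")
  expect_equal(draft$gene_rules[[1]], list("q1"))  # t2 term dropped
  expect_equal(draft$provenance[[1]][[1]]$source, "template-homology")

  # empty mapping gives an empty draft
  none <- reconstruct_from_template(tpl, pairs[0, ])
  expect_equal(n_rxns(none), 0)

  # no-rule reactions only enter on request
  draft2 <- reconstruct_from_template(tpl, pairs, include_no_rule = TRUE)
  expect_setequal(draft2$rxns$id, c("R1", "R3"))
})

test_that("identity mapping reproduces the gene-associated subnetwork and
           reaction set grows monotonically with the pair set", {
  tm <- toy_models()
  tpl <- tm$toy_gpr
  idpairs <- data.frame(query_gene = tpl$genes, template_gene = tpl$genes,
                        stringsAsFactors = FALSE)
  draft <- reconstruct_from_template(tpl, idpairs)
  with_rule <- tpl$rxns$id[!vapply(tpl$gene_rules, is.null, logical(1))]
  expect_setequal(draft$rxns$id, with_rule)
  for (k in seq_len(n_rxns(draft))) {
    kt <- rxn_idx(tpl, draft$rxns$id[k])
    expect_identical(draft$gene_rules[[k]], tpl$gene_rules[[kt]])
  }

  prev <- character()
  for (n in seq_len(nrow(idpairs))) {
    cur <- reconstruct_from_template(tpl, idpairs[1:n, ])$rxns$id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})
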