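# hand-built two-namespace models for linking tests
mk_pair_models <- function() {
  a <- new_model("A")
  for (sp in list(c("GLC", "c"), c("G6P", "c"), c("F6P", "c"),
                  c("PROTON", "c")))
    a <- add_metabolite(a, paste0(sp[1], "_", sp[2]), sp[1], sp[2],
                        db_id = sp[1])
  a <- add_reaction(a, "RXN-1", c(GLC_c = -1, G6P_c = 1), gene_rule = "gA")
  a <- add_reaction(a, "RXN-2", c(G6P_c = -1, F6P_c = 1, PROTON_c = 1))
  a <- add_reaction(a, "RXN-3", c(GLC_c = -1, F6P_c = 1))

  b <- new_model("B")
  for (sp in list(c("C00031", "c"), c("C00668", "c"), c("C05345", "c"),
                  c("C00080", "c"), c("CX01", "c")))
    b <- add_metabolite(b, paste0(sp[1], "_", sp[2]), sp[1], sp[2],
                        db_id = sp[1])
  b <- add_reaction(b, "R00771", c(C00031_c = -1, C00668_c = 1),
                    gene_rule = "gB")
  b <- add_reaction(b, "R00772", c(C00668_c = -1, C05345_c = 1))  # no proton
  b <- add_reaction(b, "R09999", c(C00031_c = -1, CX01_c = 1))    # foreign
  list(a = a, b = b,
       rxn_xref = data.frame(a_id = "RXN-1", b_id = "R00771",
                             stringsAsFactors = FALSE),
       met_xref = data.frame(
         a_id = c("GLC", "G6P", "F6P", "PROTON"),
         b_id = c("C00031", "C00668", "C05345", "C00080"),
         proton = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE))
}

test_that("stage 1 links via explicit xrefs, stage 2 via proton-blind reactant match", {
  p <- mk_pair_models()
  mp <- link_cross_db_reactions(p$a, p$b, p$rxn_xref, p$met_xref)
  expect_equal(mp$pairs$origin[mp$pairs$b_id == "R00771"], "xref")
  expect_equal(mp$pairs$a_id[mp$pairs$b_id == "R00771"], "RXN-1")
  # R00772 (no proton) matches RXN-2 (extra proton) once protons are ignored
  expect_equal(mp$pairs$a_id[mp$pairs$b_id == "R00772"], "RXN-2")
  expect_equal(mp$pairs$origin[mp$pairs$b_id == "R00772"], "reactant-match")
  # R09999 has an untranslatable metabolite: unmapped
  expect_false("R09999" %in% mp$pairs$b_id)
  expect_equal(nrow(mp$ambiguous), 0)
})

test_that("stage 2 oracle: unique multiset equality over all A x B pairs", {
  p <- mk_pair_models()
  mp <- link_cross_db_reactions(p$a, p$b, p$rxn_xref[0, ], p$met_xref)
  tr <- setNames(p$met_xref$a_id, p$met_xref$b_id)
  protons <- c("PROTON", "C00080")
  key <- function(m, k, mirror = FALSE) {
    s <- m$stoich[[k]]
    db <- m$mets$db_id[match(names(s), m$mets$id)]
    db2 <- ifelse(db %in% names(tr), tr[db], db)
    keep <- !db2 %in% protons
    paste(sort(paste0(db2[keep], "=",
                      s[keep] * (if (mirror) -1 else 1))), collapse = "|")
  }
  for (kb in seq_len(n_rxns(p$b))) {
    hits <- character()
    for (ka in seq_len(n_rxns(p$a))) {
      if (key(p$b, kb) == key(p$a, ka) ||
          key(p$b, kb) == key(p$a, ka, mirror = TRUE))
        hits <- c(hits, p$a$rxns$id[ka])
    }
    b_id <- p$b$rxns$id[kb]
    tr_ok <- all(p$b$mets$db_id[match(names(p$b$stoich[[kb]]),
                                      p$b$mets$id)] %in%
                   c(names(tr), protons))
    in_map <- mp$pairs$a_id[mp$pairs$b_id == b_id]
    if (length(hits) == 1 && tr_ok) expect_equal(in_map, hits)
    else expect_length(in_map, 0)
  }
})

test_that("ambiguous stage-2 candidates are reported, never auto-assigned", {
  p <- mk_pair_models()
  a <- add_reaction(p$a, "RXN-1b", c(GLC_c = -1, G6P_c = 1))  # duplicate of RXN-1
  mp <- link_cross_db_reactions(a, p$b, p$rxn_xref[0, ], p$met_xref)
  expect_false("R00771" %in% mp$pairs$b_id)
  expect_true("R00771" %in% mp$ambiguous$b_id)
  expect_true(grepl("RXN-1", mp$ambiguous$candidates[1]))
})

test_that("combine keeps all of A, discards mapped B, translates the rest", {
  p <- mk_pair_models()
  mp <- link_cross_db_reactions(p$a, p$b, p$rxn_xref, p$met_xref)
  cmb <- combine_models(p$a, p$b, mp)
  st <- attr(cmb, "combine_stats")
  expect_equal(n_rxns(cmb),
               st$n_a + st$n_b - st$n_mapped - st$n_duplicates)
  expect_true(all(p$a$rxns$id %in% cmb$rxns$id))
  # mapped pair rules OR-merged: RXN-1 gains gB
  expect_equal(cmb$gene_rules[[rxn_idx(cmb, "RXN-1")]], list("gA", "gB"))
  # unmapped B reaction is retained with translated + foreign metabolites
  expect_true("R09999" %in% cmb$rxns$id)
  s <- cmb$stoich[[rxn_idx(cmb, "R09999")]]
  expect_true("GLC_c" %in% names(s))
  expect_true("CX01_c" %in% names(s))
  expect_true(cmb$mets$foreign[met_idx(cmb, "CX01_c")])
  expect_false(cmb$mets$foreign[met_idx(cmb, "GLC_c")])
  # combined model stays valid
  v <- validate_model(cmb)
  expect_equal(nrow(v[v$severity == "error", ]), 0)

  expect_error(combine_models(p$a, p$b, {
    bad <- mp; bad$pairs$a_id[1] <- "GHOST"; bad
  }), "GHOST")
})

test_that("self-combination under the identity mapping changes nothing", {
  p <- mk_pair_models()
  idmap <- structure(list(
    pairs = data.frame(a_id = p$a$rxns$id, b_id = p$a$rxns$id,
                       origin = "xref", stringsAsFactors = FALSE),
    met_map = setNames(unique(p$a$mets$db_id), unique(p$a$mets$db_id)),
    proton_dbids = character(),
    ambiguous = data.frame()), class = "reaction_mapping")
  cmb <- combine_models(p$a, p$a, idmap)
  expect_equal(n_rxns(cmb), n_rxns(p$a))
  expect_equal(n_mets(cmb), n_mets(p$a))
})

test_that("accounting identity holds on fixtures with withheld xrefs and
           stage 2 recovers every withheld pair", {
  spec <- fixture_spec(seed = 5)
  fx <- generate_bundle(spec)
  ua <- build_universal_model(fx$bundle)
  ub <- build_universal_model(fx$shadow)
  mp <- link_cross_db_reactions(ua$model, ub$model, fx$bundle$rxn_xref,
                                fx$bundle$met_xref)
  for (w in fx$truth$withheld_xrefs) {
    i <- which(mp$pairs$b_id == paste0("K", w))
    expect_equal(mp$pairs$a_id[i], w)
    expect_equal(mp$pairs$origin[i], "reactant-match")
  }
  expect_equal(nrow(mp$ambiguous), 0)
  cmb <- combine_models(ua$model, ub$model, mp)
  st <- attr(cmb, "combine_stats")
  expect_equal(n_rxns(cmb),
               st$n_a + st$n_b - st$n_mapped - st$n_duplicates)
  # every discarded B reaction has a mapping entry
  discarded <- setdiff(ub$model$rxns$id, cmb$rxns$id)
  expect_true(all(discarded %in% mp$pairs$b_id))
})
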