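test_that("KO assignment from annotation is one row per (gene, KO)", {
  a <- assign_kos_from_annotation(list(g1 = "K00001"))
  expect_equal(a$gene_id, "g1")
  expect_equal(a$ko_id, "K00001")
  expect_true(all(is.infinite(a$score)))

  a2 <- assign_kos_from_annotation(list(g1 = c("K00001", "K00002")))
  expect_equal(nrow(a2), 2)
  expect_equal(nrow(assign_kos_from_annotation(list())), 0)
})

test_that("KO assignment from HMM scores filters at the threshold per row", {
  sc <- data.frame(gene = c("g1", "g2", "g3", "g3"),
                   ko = c("K1", "K1", "K1", "K2"),
                   score = c(120, 80, 150, 101), stringsAsFactors = FALSE)
  a <- assign_kos_from_hmm_scores(sc, min_score = 100)
  # oracle: per-row filter
  exp <- sc[sc$score >= 100, ]
  expect_equal(nrow(a), nrow(exp))
  expect_setequal(paste(a$gene_id, a$ko_id), paste(exp$gene, exp$ko))
  expect_false("g2" %in% a$gene_id)
  expect_equal(sum(a$gene_id == "g3"), 2)     # multi-assignment allowed
  expect_true(all(a$source == "hmm"))
})

fxk <- generate_bundle(fixture_spec(seed = 3))
unik <- build_universal_model(fxk$shadow)

test_that("KO reconstruction includes exactly the assigned KO closure", {
  kt <- fxk$truth$ko_table
  take <- kt[1:3, ]
  ass <- assign_kos_from_annotation(setNames(as.list(take$ko),
                                             paste0("g", 1:3)))
  draft <- reconstruct_from_kos(ass, unik)
  expect_setequal(draft$rxns$id, take$shadow_rxn)
  for (i in 1:3) {
    k <- rxn_idx(draft, take$shadow_rxn[i])
    expect_equal(draft$gene_rules[[k]], list(paste0("g", i)))
  }

  # reaction with two KOs / two genes gets an OR rule
  two_ko <- kt$ko[kt$shadow_rxn == kt$shadow_rxn[1]]
  ass2 <- rbind(ass, data.frame(gene_id = "g9", ko_id = kt$ko[1],
                                score = Inf, source = "annotation",
                                stringsAsFactors = FALSE))
  draft2 <- reconstruct_from_kos(ass2, unik)
  k <- rxn_idx(draft2, kt$shadow_rxn[1])
  expect_equal(draft2$gene_rules[[k]], list("g1", "g9"))

  # unassigned KO reactions are absent; unknown KOs warn
  expect_false(kt$shadow_rxn[5] %in% draft$rxns$id)
  expect_warning(reconstruct_from_kos(
    data.frame(gene_id = "g1", ko_id = "KO_GHOST", score = Inf,
               source = "annotation", stringsAsFactors = FALSE), unik),
    "KO_GHOST")
})

test_that("clustering at 100% groups exact duplicates (hash oracle)", {
  set.seed(7)
  seqs <- c(replicate(4, paste(sample(c("A", "C", "D", "E"), 30,
                                      replace = TRUE), collapse = "")))
  recs <- data.frame(id = sprintf("s%d", 1:6),
                     sequence = c(seqs[1], seqs[1], seqs[2], seqs[3],
                                  seqs[3], seqs[4]),
                     stringsAsFactors = FALSE)
  cl <- cluster_sequences(recs, 100)
  got <- lapply(cl, `[[`, "members")
  oracle <- split(recs$id, recs$sequence)
  expect_equal(length(got), length(oracle))
  for (grp in oracle)
    expect_true(any(vapply(got, function(g) setequal(g, grp), logical(1))))
})

test_that("identity cutoffs split AAAA/AAAT as hand-computed (75%)", {
  recs <- data.frame(id = c("a", "b"), sequence = c("AAAA", "AAAT"),
                     stringsAsFactors = FALSE)
  expect_equal(sequence_identity("AAAA", "AAAT"), 0.75)
  expect_length(cluster_sequences(recs, 50), 1)
  expect_length(cluster_sequences(recs, 90), 2)
  expect_length(cluster_sequences(recs[1, , drop = FALSE], 100), 1)
  expect_length(cluster_sequences(recs[0, ], 100), 0)
})

test_that("cluster count is monotone non-increasing as the cutoff drops", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T", "W"), 40, replace = TRUE),
                collapse = "")
  recs <- data.frame(
    id = sprintf("v%d", 1:8),
    sequence = vapply(1:8, function(i) {
      ch <- strsplit(base, "")[[1]]
      j <- sample(40, i * 3)
      ch[j] <- sample(c("K", "R", "M", "N"), length(j), replace = TRUE)
      paste(ch, collapse = "")
    }, ""), stringsAsFactors = FALSE)
  counts <- vapply(c(100, 90, 50),
                   function(ct) length(suppressWarnings(
                     cluster_sequences(recs, ct))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("KO training pipeline orchestrates cluster/align/build with stubs", {
  seqs <- list(
    KO1 = data.frame(id = c("p1", "p2"),
                     sequence = c("MKVAAAAAA", "MKVAAAAAT"),
                     stringsAsFactors = FALSE),
    KO2 = data.frame(id = "p3", sequence = "MMMM", stringsAsFactors = FALSE))
  out_dir <- withr::local_tempdir()
  man <- build_ko_training_sets(seqs, cutoff = 90, out_dir = out_dir)
  expect_equal(man$ko, c("KO1", "KO2"))
  expect_true(file.exists(man$faa[1]))
  expect_true(file.exists(man$msa[1]))
  expect_true(file.exists(man$hmm[1]))
  # single-sequence KO skips alignment and is flagged
  expect_true(man$single_sequence[2])
  expect_true(is.na(man$msa[2]))

  failing <- stub_runner()
  failing$align <- function(fasta, msa) stop("boom")
  expect_error(build_ko_training_sets(seqs, 90, withr::local_tempdir(),
                                      runner = failing),
               "stage 'align'")
})
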