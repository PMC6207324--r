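# KEGG Orthology (KO)-based reconstruction.
#
# A KEGG-style bundle is a database bundle whose enzymes.tsv rows are KO
# groups (the KO -> reaction map). KO assignment comes either from curated
# genome annotation or from HMM bit-score tables; the cluster -> align ->
# hmmbuild training pipeline is exposed behind a runner contract so external
# tools (MAFFT, HMMER3) or test stubs can fill the stages.

#' KO assignments from a curated annotation table
#'
#' @param table named list (or data.frame with columns `gene`, `ko`) mapping
#'   genes to one or more KO ids.
#' @return data.frame with columns `gene_id`, `ko_id`, `score` (`Inf` for
#'   curated annotation), `source` (`"annotation"`).
#' @export
assign_kos_from_annotation <- function(table) {
  if (is.data.frame(table)) table <- split(table$ko, table$gene)
  rows <- lapply(names(table), function(g) {
    kos <- unique(as.character(unlist(table[[g]])))
    if (!length(kos)) return(NULL)
    data.frame(gene_id = g, ko_id = kos, score = Inf,
               source = "annotation", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), ko_id = character(),
                      score = numeric(), source = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' KO assignments from HMM bit-score tables
#'
#' Every (gene, KO) pair whose score reaches `min_score` is assigned;
#' multi-assignment of a gene to several KOs is allowed.
#'
#' @param scores data.frame with columns `gene`, `ko`, `score`, or a numeric
#'   matrix (genes x KOs).
#' @param min_score HMM bit-score acceptance threshold (default 100).
#' @return data.frame as in [assign_kos_from_annotation()] with
#'   source `"hmm"`.
#' @export
assign_kos_from_hmm_scores <- function(scores, min_score = 100) {
  if (is.matrix(scores)) {
    idx <- which(!is.na(scores), arr.ind = TRUE)
    scores <- data.frame(gene = rownames(scores)[idx[, 1]],
                         ko = colnames(scores)[idx[, 2]],
                         score = scores[idx], stringsAsFactors = FALSE)
  }
  keep <- scores$score >= min_score
  out <- data.frame(gene_id = scores$gene[keep], ko_id = scores$ko[keep],
                    score = scores$score[keep], source = "hmm",
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$ko_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Draft reconstruction from KO assignments
#'
#' A database reaction enters the draft iff at least one of its KOs is
#' assigned to a query gene; its gene rule is the OR over all genes assigned
#' to any of its KOs. Provenance is `kegg-annotation` or `kegg-hmm`
#' according to the assignment source.
#'
#' @param assignments KO assignment data.frame.
#' @param universal a `universal_model` built from a KEGG-style bundle
#'   (enzyme index rows are KOs).
#' @return a draft `metabolic_model`.
#' @export
reconstruct_from_kos <- function(assignments, universal) {
  enz <- universal$enzymes
  unknown <- setdiff(unique(assignments$ko_id), enz$id)
  if (length(unknown))
    warning("ignoring assignment(s) to unknown KO(s): ",
            paste(unknown, collapse = ", "))
  assignments <- assignments[assignments$ko_id %in% enz$id, , drop = FALSE]
  uni <- universal$model
  draft <- new_model("draft_ko", "KO annotation draft")
  rxn_genes <- list(); rxn_src <- list(); rxn_score <- list()
  for (i in seq_len(nrow(enz))) {
    a <- assignments[assignments$ko_id == enz$id[i], , drop = FALSE]
    if (!nrow(a)) next
    for (r in enz$reactions[[i]]) {
      rxn_genes[[r]] <- union(rxn_genes[[r]], a$gene_id)
      rxn_src[[r]] <- union(rxn_src[[r]], a$source)
      sc <- a$score[is.finite(a$score)]
      if (length(sc)) rxn_score[[r]] <- max(c(rxn_score[[r]], sc))
    }
  }
  for (r in sort(names(rxn_genes))) {
    k <- rxn_idx(uni, r)
    s <- uni$stoich[[k]]
    for (m in setdiff(names(s), draft$mets$id)) {
      km <- met_idx(uni, m)
      draft <- add_metabolite(draft, m, uni$mets$name[km], uni$mets$comp[km],
                              uni$mets$db_id[km], uni$mets$formula[km],
                              uni$mets$charge[km], uni$met_xrefs[[km]])
    }
    src <- if ("annotation" %in% rxn_src[[r]]) "kegg-annotation" else
      "kegg-hmm"
    draft <- add_reaction(draft, r, s, uni$rxns$name[k], uni$rxns$lb[k],
                          uni$rxns$ub[k],
                          canonical_dnf(lapply(sort(rxn_genes[[r]]),
                                               identity)),
                          uni$rxns$subsystem[k], uni$ec[[k]],
                          uni$rxn_xrefs[[k]], uni$rxns$spontaneous[k],
                          uni$rxns$transport[k], uni$rxns$exchange[k],
                          list(evidence(src, genes = sort(rxn_genes[[r]]),
                                        score = rxn_score[[r]])))
  }
  draft
}

#' Global-alignment sequence identity
#'
#' Needleman-Wunsch with match = 1, mismatch = 0, linear gap penalty -1;
#' identity is matches divided by alignment columns.
#'
#' @param a,b amino-acid strings.
#' @return identity in \[0, 1\].
#' @export
sequence_identity <- function(a, b) {
  alphabet <- unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
  sm <- matrix(0, length(alphabet), length(alphabet),
               dimnames = list(alphabet, alphabet))
  diag(sm) <- 1
  pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = sm,
                                      gapOpening = 0, gapExtension = 1,
                                      type = "global")
  ncols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  Biostrings::nmatch(pa) / ncols
}

#' Greedy incremental sequence clustering
#'
#' Longest-first greedy clustering in the CD-HIT style: each sequence joins
#' the first existing cluster whose representative it matches at
#' global-alignment identity >= `cutoff`, otherwise it founds a new cluster.
#' Deterministic given the input.
#'
#' @param records data.frame with `id`, `sequence` columns.
#' @param cutoff percent identity cutoff; the conventional redundancy levels
#'   are 100, 90 and 50 (other values are allowed with a warning).
#' @return list of clusters, each a list with `representative`, `members`
#'   (character vector of ids, representative included), `cutoff`.
#' @export
cluster_sequences <- function(records, cutoff = 90) {
  if (!cutoff %in% c(100, 90, 50))
    warning("non-standard redundancy cutoff: ", cutoff)
  if (!nrow(records)) return(list())
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  reps <- integer()
  clusters <- list()
  for (i in seq_len(nrow(records))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      idy <- sequence_identity(records$sequence[reps[ci]],
                               records$sequence[i])
      if (idy * 100 >= cutoff) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, records$id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      clusters[[length(clusters) + 1L]] <-
        list(representative = records$id[i], members = records$id[i],
             cutoff = cutoff)
    }
  }
  clusters
}

#' Stub training-pipeline runner
#'
#' Fills the align/hmmbuild runner contract without external tools: each
#' stage writes a deterministic placeholder file, so orchestration and file
#' manifests are fully testable.
#'
#' @return list with functions `align(fasta_path, msa_path)` and
#'   `hmmbuild(msa_path, hmm_path)`.
#' @export
stub_runner <- function() {
  list(
    align = function(fasta, msa) {
      writeLines(c("# stub msa", readLines(fasta)), msa); msa
    },
    hmmbuild = function(msa, hmm) {
      writeLines(c("# stub hmm", basename(msa)), hmm); hmm
    }
  )
}

#' External training-pipeline runner
#'
#' Uses `mafft` and `hmmbuild` binaries found on the PATH. Provided for
#' production use; tests rely on [stub_runner()].
#'
#' @return runner list as in [stub_runner()].
#' @export
external_runner <- function() {
  list(
    align = function(fasta, msa) {
      status <- system2("mafft", c("--auto", shQuote(fasta)),
                        stdout = msa, stderr = FALSE)
      if (status != 0) stop("mafft failed on ", fasta)
      msa
    },
    hmmbuild = function(msa, hmm) {
      status <- system2("hmmbuild", c(shQuote(hmm), shQuote(msa)),
                        stdout = FALSE, stderr = FALSE)
      if (status != 0) stop("hmmbuild failed on ", msa)
      hmm
    }
  )
}

#' Build per-KO HMM training sets
#'
#' For every KO: cluster its member sequences at the redundancy cutoff,
#' write the cluster representatives as FASTA, then run the align and
#' hmmbuild stages through the runner. KOs with fewer than two unique
#' sequences skip the alignment stage and are flagged single-sequence.
#'
#' @param sequences_by_ko named list: KO id -> data.frame(`id`, `sequence`).
#' @param cutoff redundancy cutoff passed to [cluster_sequences()].
#' @param out_dir output directory.
#' @param runner runner contract (default [stub_runner()]).
#' @return data.frame manifest: `ko`, `n_clusters`, `single_sequence`,
#'   `faa`, `msa`, `hmm` (paths; `NA` for skipped stages).
#' @export
build_ko_training_sets <- function(sequences_by_ko, cutoff = 90,
                                   out_dir = tempfile("kotrain"),
                                   runner = stub_runner()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(sequences_by_ko), function(ko) {
    recs <- sequences_by_ko[[ko]]
    cl <- cluster_sequences(recs, cutoff)
    reps <- vapply(cl, `[[`, "", "representative")
    faa <- file.path(out_dir, paste0(ko, ".faa"))
    write_fasta(recs[recs$id %in% reps, , drop = FALSE], faa)
    single <- length(unique(recs$sequence)) < 2
    if (single)
      return(data.frame(ko = ko, n_clusters = length(cl),
                        single_sequence = TRUE, faa = faa,
                        msa = NA_character_, hmm = NA_character_,
                        stringsAsFactors = FALSE))
    msa <- file.path(out_dir, paste0(ko, ".msa"))
    tryCatch(runner$align(faa, msa), error = function(e)
      stop("KO ", ko, ": stage 'align' failed: ", conditionMessage(e),
           call. = FALSE))
    hmm <- file.path(out_dir, paste0(ko, ".hmm"))
    tryCatch(runner$hmmbuild(msa, hmm), error = function(e)
      stop("KO ", ko, ": stage 'hmmbuild' failed: ", conditionMessage(e),
           call. = FALSE))
    data.frame(ko = ko, n_clusters = length(cl), single_sequence = FALSE,
               faa = faa, msa = msa, hmm = hmm, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
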