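#' Bidirectional best hits
#'
#' Infers ortholog pairs from forward (query proteome vs template proteome)
#' and reverse alignment hit tables. A pair (q, t) is reported iff t is q's
#' best forward hit and q is t's best reverse hit, with both hits passing the
#' bit-score and e-value thresholds. "Best" is the highest bit score; ties
#' are broken by lower e-value, then lexicographically smaller subject id.
#' Multiple HSPs for the same query/subject pair are collapsed to the best
#' one before ranking.
#'
#' @param fwd,rev alignment hit data.frames (see [read_alignment_table()]).
#' @param min_bit minimum bit score for both directions.
#' @param max_eval maximum e-value for both directions.
#' @return data.frame with columns `query_gene`, `template_gene`,
#'   `fwd_bit_score`, `rev_bit_score`.
#' @export
bidirectional_best_hits <- function(fwd, rev, min_bit = 100,
                                    max_eval = 1e-30) {
  best_per_query <- function(hits) {
    hits <- hits[hits$bit_score >= min_bit & hits$evalue <= max_eval, ,
                 drop = FALSE]
    if (!nrow(hits)) return(hits)
    # collapse HSPs: keep best row per (query, subject)
    hits <- hits[order(hits$query_id, hits$subject_id, -hits$bit_score,
                       hits$evalue), , drop = FALSE]
    hits <- hits[!duplicated(hits[c("query_id", "subject_id")]), ,
                 drop = FALSE]
    hits <- hits[order(hits$query_id, -hits$bit_score, hits$evalue,
                       hits$subject_id), , drop = FALSE]
    hits[!duplicated(hits$query_id), , drop = FALSE]
  }
  bf <- best_per_query(fwd)
  br <- best_per_query(rev)
  if (!nrow(bf) || !nrow(br))
    return(data.frame(query_gene = character(), template_gene = character(),
                      fwd_bit_score = numeric(), rev_bit_score = numeric(),
                      stringsAsFactors = FALSE))
  rev_best <- setNames(br$subject_id, br$query_id)
  keep <- !is.na(rev_best[bf$subject_id]) &
    rev_best[bf$subject_id] == bf$query_id
  out <- bf[keep, , drop = FALSE]
  data.frame(query_gene = out$query_id, template_gene = out$subject_id,
             fwd_bit_score = out$bit_score,
             rev_bit_score = br$bit_score[match(out$subject_id, br$query_id)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Draft reconstruction from a template model by orthology
#'
#' Rewrites every template gene rule through the ortholog map: template genes
#' are replaced by their paired query genes, DNF terms containing any
#' unmapped template gene (e.g. an incomplete complex) are dropped, and
#' reactions whose rewritten rule is empty are excluded. Reactions without
#' gene rules are excluded unless `include_no_rule` is set.
#'
#' @param template a `metabolic_model` used as reconstruction template.
#' @param pairs ortholog pairs as from [bidirectional_best_hits()].
#' @param include_no_rule also copy reactions that have no gene association.
#' @return a draft `metabolic_model` with `template-homology` provenance.
#' @export
reconstruct_from_template <- function(template, pairs,
                                      include_no_rule = FALSE) {
  map <- split(pairs$query_gene, pairs$template_gene)
  draft <- new_model(paste0(template$id, "_draft"),
                     paste("homology draft of", template$name))
  draft$comps <- template$comps
  for (k in seq_len(n_rxns(template))) {
    dnf <- template$gene_rules[[k]]
    if (is.null(dnf)) {
      if (!include_no_rule) next
      new_dnf <- NULL
    } else {
      new_terms <- list()
      for (term in dnf) {
        if (!all(term %in% names(map))) next  # partial complex: drop
        # each subunit may map to several query genes; AND over one query
        # gene per subunit, expanded over alternatives
        alt <- lapply(term, function(t) map[[t]])
        grid <- Reduce(function(acc, a)
          unlist(lapply(acc, function(x) lapply(a, function(y) c(x, y))),
                 recursive = FALSE),
          alt, accumulate = FALSE, right = FALSE,
          init = list(character()))
        new_terms <- c(new_terms, grid)
      }
      if (!length(new_terms)) next
      new_dnf <- canonical_dnf(new_terms)
    }
    s <- template$stoich[[k]]
    for (m in setdiff(names(s), draft$mets$id)) {
      km <- met_idx(template, m)
      draft <- add_metabolite(draft, m, template$mets$name[km],
                              template$mets$comp[km], template$mets$db_id[km],
                              template$mets$formula[km],
                              template$mets$charge[km],
                              template$met_xrefs[[km]])
    }
    draft <- add_reaction(draft, template$rxns$id[k], s,
                          template$rxns$name[k], template$rxns$lb[k],
                          template$rxns$ub[k], new_dnf,
                          template$rxns$subsystem[k], template$ec[[k]],
                          template$rxn_xrefs[[k]],
                          template$rxns$spontaneous[k],
                          template$rxns$transport[k],
                          template$rxns$exchange[k],
                          list(evidence("template-homology",
                                        genes = unlist(new_dnf))))
  }
  draft
}
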