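# Cross-database reaction linking and model combination.
#
# Namespace A (MetaCyc-style) wins all conflicts; B (KEGG-style) reactions
# that map onto A counterparts are discarded with their gene rules OR-merged
# into the A copy, and unmapped B content is translated into the A namespace
# wherever the metabolite cross-references allow.

stoich_key <- function(model, k, proton_dbids = character(), mirror = FALSE) {
  s <- model$stoich[[k]]
  idx <- met_idx(model, names(s))
  db <- ifelse(is.na(model$mets$db_id[idx]), names(s),
               model$mets$db_id[idx])
  keep <- !db %in% proton_dbids
  if (!any(keep)) return("")
  coef <- unname(s[keep]) * (if (mirror) -1 else 1)
  lab <- paste0(db[keep], "@", model$mets$comp[idx][keep])
  o <- order(lab)
  paste(paste0(lab[o], "=", num_str(coef[o])), collapse = "|")
}

#' Link reactions across two database namespaces
#'
#' Stage 1 pairs reactions through the explicit reaction cross-reference
#' table. Stage 2 attempts reactant matching for every still-unmapped B
#' reaction: its metabolites are translated through the metabolite
#' cross-references and the translated substrate/product multisets (with
#' coefficients, direction-agnostic, protons ignored) are compared against
#' every unmapped A reaction. A unique match becomes a pair of origin
#' `reactant-match`; ambiguous matches (two or more candidates) are skipped
#' and reported, never auto-assigned.
#'
#' @param modelA,modelB `metabolic_model`s in the A (preferred) and B
#'   namespaces; metabolites carry database ids in `db_id`.
#' @param rxn_xref data.frame, columns `a_id`, `b_id`.
#' @param met_xref data.frame, columns `a_id`, `b_id` and optional logical
#'   `proton` marking proton-class metabolites.
#' @return list of class `reaction_mapping`: `pairs` (data.frame `a_id`,
#'   `b_id`, `origin`), `met_map` (named vector, B db id -> A db id),
#'   `proton_dbids`, `ambiguous` (data.frame `b_id`, `candidates`).
#' @export
link_cross_db_reactions <- function(modelA, modelB, rxn_xref, met_xref) {
  if (is.null(met_xref$proton)) met_xref$proton <- FALSE
  met_xref$proton <- as.logical(met_xref$proton)
  proton_dbids <- unique(c(met_xref$a_id[met_xref$proton],
                           met_xref$b_id[met_xref$proton]))
  # unique-translation map B -> A
  tr <- split(met_xref$a_id, met_xref$b_id)
  met_map <- vapply(tr, function(v)
    if (length(unique(v)) == 1) v[[1]] else NA_character_, character(1))
  met_map <- met_map[!is.na(met_map)]

  pairs <- data.frame(a_id = character(), b_id = character(),
                      origin = character(), stringsAsFactors = FALSE)
  if (!is.null(rxn_xref) && nrow(rxn_xref)) {
    st1 <- rxn_xref[rxn_xref$a_id %in% modelA$rxns$id &
                    rxn_xref$b_id %in% modelB$rxns$id, , drop = FALSE]
    st1 <- st1[!duplicated(st1$b_id), , drop = FALSE]
    if (nrow(st1))
      pairs <- data.frame(a_id = st1$a_id, b_id = st1$b_id, origin = "xref",
                          stringsAsFactors = FALSE)
  }

  unmapped_a <- setdiff(modelA$rxns$id, pairs$a_id)
  keysA_f <- vapply(rxn_idx(modelA, unmapped_a), function(k)
    stoich_key(modelA, k, proton_dbids, FALSE), character(1))
  keysA_r <- vapply(rxn_idx(modelA, unmapped_a), function(k)
    stoich_key(modelA, k, proton_dbids, TRUE), character(1))

  ambiguous <- data.frame(b_id = character(), candidates = character(),
                          stringsAsFactors = FALSE)
  for (b in setdiff(modelB$rxns$id, pairs$b_id)) {
    k <- rxn_idx(modelB, b)
    s <- modelB$stoich[[k]]
    idx <- met_idx(modelB, names(s))
    db <- ifelse(is.na(modelB$mets$db_id[idx]), names(s),
                 modelB$mets$db_id[idx])
    nonproton <- !db %in% proton_dbids
    if (!all(db[nonproton] %in% names(met_map))) next
    tdb <- ifelse(nonproton, met_map[db], db)
    keep <- nonproton
    if (!any(keep)) next
    lab <- paste0(tdb[keep], "@", modelB$mets$comp[idx][keep])
    coef <- unname(s[keep])
    o <- order(lab)
    key <- paste(paste0(lab[o], "=", num_str(coef[o])), collapse = "|")
    cand <- unmapped_a[keysA_f == key | keysA_r == key]
    if (length(cand) == 1) {
      pairs <- rbind(pairs, data.frame(a_id = cand, b_id = b,
                                       origin = "reactant-match",
                                       stringsAsFactors = FALSE))
      drop <- unmapped_a != cand
      unmapped_a <- unmapped_a[drop]
      keysA_f <- keysA_f[drop]; keysA_r <- keysA_r[drop]
    } else if (length(cand) >= 2) {
      ambiguous <- rbind(ambiguous, data.frame(
        b_id = b, candidates = paste(cand, collapse = ";"),
        stringsAsFactors = FALSE))
    }
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, met_map = met_map,
                 proton_dbids = proton_dbids, ambiguous = ambiguous),
            class = "reaction_mapping")
}

#' Combine two draft models across namespaces
#'
#' Keeps all of model A. Every mapped B reaction is discarded with its gene
#' rule OR-merged (and provenance concatenated) into its A counterpart.
#' Unmapped B reactions are retained after translating their metabolites to
#' the A namespace wherever the metabolite map allows (untranslatable
#' metabolites keep their B ids, flagged foreign); a retained B reaction
#' whose translated stoichiometry duplicates an A reaction is merged into it
#' instead of added.
#'
#' @param modelA,modelB `metabolic_model`s.
#' @param mapping a `reaction_mapping` from [link_cross_db_reactions()].
#' @return combined `metabolic_model`; attribute `combine_stats` records the
#'   accounting (`n_a`, `n_b`, `n_mapped`, `n_duplicates`).
#' @export
combine_models <- function(modelA, modelB, mapping) {
  bad <- c(setdiff(mapping$pairs$a_id, modelA$rxns$id),
           setdiff(mapping$pairs$b_id, modelB$rxns$id))
  if (length(bad))
    stop("mapping cites reaction(s) absent from the models: ",
         paste(bad, collapse = ", "))
  out <- modelA
  merge_into <- function(out, a_id, kb) {
    ka <- rxn_idx(out, a_id)
    out$gene_rules[ka] <- list(or_dnf(out$gene_rules[[ka]],
                                      modelB$gene_rules[[kb]]))
    out$provenance[[ka]] <- c(out$provenance[[ka]], modelB$provenance[[kb]])
    out$genes <- sort(union(out$genes, unlist(modelB$gene_rules[[kb]])))
    out
  }
  for (i in seq_len(nrow(mapping$pairs)))
    out <- merge_into(out, mapping$pairs$a_id[i],
                      rxn_idx(modelB, mapping$pairs$b_id[i]))

  n_dup <- 0L
  keysA <- vapply(seq_len(n_rxns(modelA)), function(k)
    stoich_key(modelA, k, character(), FALSE), character(1))
  for (b in setdiff(modelB$rxns$id, mapping$pairs$b_id)) {
    kb <- rxn_idx(modelB, b)
    s <- modelB$stoich[[kb]]
    idx <- met_idx(modelB, names(s))
    db <- ifelse(is.na(modelB$mets$db_id[idx]), names(s),
                 modelB$mets$db_id[idx])
    translatable <- db %in% names(mapping$met_map)
    new_db <- ifelse(translatable, mapping$met_map[db], db)
    comp <- modelB$mets$comp[idx]
    new_id <- ifelse(translatable, paste0(new_db, "_", comp), names(s))
    s2 <- setNames(unname(s), new_id)
    # post-translation duplicate of an A reaction?
    lab <- paste0(new_db, "@", comp)
    o <- order(lab)
    key <- paste(paste0(lab[o], "=", num_str(unname(s)[o])), collapse = "|")
    hit <- modelA$rxns$id[keysA == key]
    if (length(hit)) {
      out <- merge_into(out, hit[1], kb)
      n_dup <- n_dup + 1L
      next
    }
    for (j in which(!new_id %in% out$mets$id)) {
      out <- add_metabolite(out, new_id[j], modelB$mets$name[idx[j]],
                            comp[j], db_id = new_db[j],
                            formula = modelB$mets$formula[idx[j]],
                            charge = modelB$mets$charge[idx[j]],
                            xrefs = modelB$met_xrefs[[idx[j]]],
                            foreign = !translatable[j])
    }
    out <- add_reaction(out, b, s2, modelB$rxns$name[kb],
                        modelB$rxns$lb[kb], modelB$rxns$ub[kb],
                        modelB$gene_rules[[kb]], modelB$rxns$subsystem[kb],
                        modelB$ec[[kb]], modelB$rxn_xrefs[[kb]],
                        modelB$rxns$spontaneous[kb],
                        modelB$rxns$transport[kb],
                        modelB$rxns$exchange[kb], modelB$provenance[[kb]])
  }
  out$genes <- sort(union(out$genes, modelB$genes))
  attr(out, "combine_stats") <- list(n_a = n_rxns(modelA),
                                     n_b = n_rxns(modelB),
                                     n_mapped = nrow(mapping$pairs),
                                     n_duplicates = n_dup)
  out
}
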