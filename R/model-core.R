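#' Create an empty metabolic model
#'
#' A `metabolic_model` is a struct-of-arrays container for a constraint-based
#' model: compartments, metabolites, reactions with stoichiometry, flux bounds
#' (mmol/gDW/h), gene-protein-reaction (GPR) rules in disjunctive normal form,
#' annotations, provenance and an objective.
#'
#' Reversibility is not stored: a reaction is reversible iff `lb < 0 & ub > 0`.
#' GPR rules are stored canonically as a list of character vectors, one vector
#' per OR term (isozyme), genes within a vector AND-ed (complex subunits).
#'
#' @param id model identifier.
#' @param name human-readable name.
#' @return an object of class `metabolic_model`.
#' @export
new_model <- function(id = "model", name = "") {
  structure(list(
    id = id, name = name,
    comps = c(c = "cytosol"),
    mets = data.frame(id = character(), name = character(), comp = character(),
                      db_id = character(), formula = character(),
                      charge = numeric(), foreign = logical(),
                      stringsAsFactors = FALSE),
    met_xrefs = list(),
    rxns = data.frame(id = character(), name = character(),
                      subsystem = character(), lb = numeric(), ub = numeric(),
                      spontaneous = logical(), transport = logical(),
                      exchange = logical(), stringsAsFactors = FALSE),
    stoich = list(),
    gene_rules = list(),
    raw_rules = character(),
    ec = list(),
    rxn_xrefs = list(),
    provenance = list(),
    genes = character(),
    objective = list(rxn = NA_character_, sense = "max")
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %s%s\n", x$id,
              if (nzchar(x$name)) paste0(" (", x$name, ")") else ""))
  cat(sprintf("  %d reactions, %d metabolites, %d genes, %d compartments\n",
              nrow(x$rxns), nrow(x$mets), length(x$genes), length(x$comps)))
  cat(sprintf("  objective: %s (%s)\n", x$objective$rxn, x$objective$sense))
  invisible(x)
}

#' Number of reactions / metabolites / genes
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_rxns <- function(model) nrow(model$rxns)

#' @rdname n_rxns
#' @export
n_mets <- function(model) nrow(model$mets)

#' @rdname n_rxns
#' @export
n_genes <- function(model) length(model$genes)

met_idx <- function(model, ids) match(ids, model$mets$id)
rxn_idx <- function(model, ids) match(ids, model$rxns$id)

#' Add a compartment (no-op if present)
#' @param model a `metabolic_model`.
#' @param id compartment id (e.g. `"c"`).
#' @param name compartment name; defaults to the id.
#' @return the modified model.
#' @export
add_compartment <- function(model, id, name = id) {
  if (!id %in% names(model$comps)) {
    model$comps[[id]] <- name
    model$comps <- model$comps[order(names(model$comps))]
  }
  model
}

#' Add a metabolite to a model
#'
#' @param model a `metabolic_model`.
#' @param id unique metabolite id.
#' @param name display name.
#' @param comp compartment id (created if absent).
#' @param db_id optional database (compartment-free) identifier.
#' @param formula optional elemental formula.
#' @param charge optional integer charge.
#' @param xrefs named list of character vectors (namespace -> foreign ids).
#' @param foreign flag for metabolites kept in a foreign namespace.
#' @return the modified model.
#' @export
add_metabolite <- function(model, id, name = id, comp = "c",
                           db_id = NA_character_, formula = NA_character_,
                           charge = NA_real_, xrefs = list(), foreign = FALSE) {
  if (id %in% model$mets$id) stop("duplicate metabolite id: ", id)
  model <- add_compartment(model, comp)
  model$mets <- rbind(model$mets, data.frame(
    id = id, name = name, comp = comp, db_id = db_id, formula = formula,
    charge = charge, foreign = foreign, stringsAsFactors = FALSE))
  model$met_xrefs[[length(model$met_xrefs) + 1L]] <- xrefs
  model
}

#' Add a reaction to a model
#'
#' Metabolites referenced by `stoich` must already exist. Genes referenced by
#' the rule are appended to the model gene list.
#'
#' @param model a `metabolic_model`.
#' @param id unique reaction id.
#' @param stoich named numeric vector, metabolite id -> signed coefficient
#'   (negative = substrate). Zero coefficients are dropped.
#' @param name display name.
#' @param lb,ub flux bounds.
#' @param gene_rule DNF rule (list of character vectors), a rule string, or
#'   `NULL` for no gene association.
#' @param subsystem optional subsystem name.
#' @param ec character vector of EC numbers.
#' @param xrefs named list of character vectors.
#' @param spontaneous,transport,exchange reaction flags.
#' @param provenance list of evidence entries (see [evidence()]).
#' @return the modified model.
#' @export
add_reaction <- function(model, id, stoich, name = id, lb = 0, ub = 1000,
                         gene_rule = NULL, subsystem = NA_character_,
                         ec = character(), xrefs = list(),
                         spontaneous = FALSE, transport = FALSE,
                         exchange = FALSE, provenance = list()) {
  if (id %in% model$rxns$id) stop("duplicate reaction id: ", id)
  stoich <- stoich[stoich != 0]
  stoich <- stoich[order(names(stoich))]
  missing_mets <- setdiff(names(stoich), model$mets$id)
  if (length(missing_mets))
    stop("reaction ", id, " references unknown metabolites: ",
         paste(missing_mets, collapse = ", "))
  if (is.character(gene_rule)) {
    raw <- gene_rule
    gene_rule <- parse_gene_rule(gene_rule)
  } else raw <- NA_character_
  gene_rule <- canonical_dnf(gene_rule)
  model$rxns <- rbind(model$rxns, data.frame(
    id = id, name = name, subsystem = subsystem, lb = lb, ub = ub,
    spontaneous = spontaneous, transport = transport, exchange = exchange,
    stringsAsFactors = FALSE))
  k <- nrow(model$rxns)
  model$stoich[[k]] <- stoich
  model$gene_rules[k] <- list(gene_rule)
  model$raw_rules[k] <- raw
  model$ec[[k]] <- ec
  model$rxn_xrefs[[k]] <- xrefs
  model$provenance[[k]] <- provenance
  model$genes <- sort(union(model$genes, unlist(gene_rule)))
  model
}

#' Construct an evidence entry
#'
#' Provenance records why a reaction is in a model. `source` is one of
#' `template-homology`, `metacyc-db`, `kegg-annotation`, `kegg-hmm`,
#' `spontaneous`, `manual`.
#'
#' @param source evidence source keyword.
#' @param genes genes supporting the call.
#' @param score optional numeric score (e.g. best bit score).
#' @return a list of class `gem_evidence`.
#' @export
evidence <- function(source, genes = character(), score = NULL) {
  valid <- c("template-homology", "metacyc-db", "kegg-annotation",
             "kegg-hmm", "spontaneous", "manual")
  if (!source %in% valid)
    stop("invalid evidence source: ", source)
  structure(list(source = source, genes = genes, score = score),
            class = "gem_evidence")
}

#' Set the model objective
#' @param model a `metabolic_model`.
#' @param rxn reaction id to optimize.
#' @param sense `"max"` or `"min"`.
#' @return the modified model.
#' @export
set_objective <- function(model, rxn, sense = "max") {
  sense <- match.arg(sense, c("max", "min"))
  model$objective <- list(rxn = rxn, sense = sense)
  model
}

#' Stoichiometric matrix
#' @param model a `metabolic_model`.
#' @return sparse `Matrix` (metabolites x reactions) with dimnames.
#' @export
stoich_matrix <- function(model) {
  nm <- n_mets(model); nr <- n_rxns(model)
  i <- integer(); j <- integer(); x <- numeric()
  for (k in seq_len(nr)) {
    s <- model$stoich[[k]]
    if (!length(s)) next
    i <- c(i, met_idx(model, names(s)))
    j <- c(j, rep.int(k, length(s)))
    x <- c(x, unname(s))
  }
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(nm, nr),
                       dimnames = list(model$mets$id, model$rxns$id))
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: unique ids per namespace, bounds ordered,
#' stoichiometry referencing known metabolites and free of zero coefficients,
#' metabolite compartments declared, gene rules referencing listed genes,
#' objective reaction present, and orphan genes (in the gene list but in no
#' rule). Validation never throws; it reports.
#'
#' @param model a `metabolic_model`.
#' @return data.frame with columns `severity` (`"error"`/`"warning"`),
#'   `code`, `element`, `message`. Zero rows iff the model is valid.
#' @export
validate_model <- function(model) {
  v <- list()
  flag <- function(severity, code, element, message)
    v[[length(v) + 1L]] <<- data.frame(severity = severity, code = code,
                                       element = element, message = message,
                                       stringsAsFactors = FALSE)
  for (nsp in c("mets", "rxns")) {
    dup <- unique(model[[nsp]]$id[duplicated(model[[nsp]]$id)])
    for (d in dup) flag("error", "duplicate-id", d,
                        paste0("duplicate ", nsp, " id ", d))
  }
  dup <- unique(model$genes[duplicated(model$genes)])
  for (d in dup) flag("error", "duplicate-id", d, paste0("duplicate gene id ", d))
  bad <- model$mets$id[!model$mets$comp %in% names(model$comps)]
  for (d in bad) flag("error", "unknown-compartment", d,
                      paste0("metabolite ", d, " in undeclared compartment"))
  for (k in seq_len(n_rxns(model))) {
    rid <- model$rxns$id[k]
    if (model$rxns$lb[k] > model$rxns$ub[k])
      flag("error", "bounds", rid,
           paste0("reaction ", rid, " has lb > ub"))
    s <- model$stoich[[k]]
    if (any(s == 0))
      flag("error", "zero-coefficient", rid,
           paste0("reaction ", rid, " stores zero coefficients"))
    unk <- setdiff(names(s), model$mets$id)
    for (m in unk) flag("error", "unknown-metabolite", rid,
                        paste0("reaction ", rid, " references unknown metabolite ", m))
    gr <- model$gene_rules[[k]]
    if (!is.null(gr)) {
      if (any(lengths(gr) == 0))
        flag("error", "empty-conjunction", rid,
             paste0("reaction ", rid, " has an empty AND term"))
      unkg <- setdiff(unlist(gr), model$genes)
      for (g in unkg) flag("error", "unknown-gene", rid,
                           paste0("reaction ", rid, " rule references unknown gene ", g))
    }
  }
  if (!is.na(model$objective$rxn) &&
      !model$objective$rxn %in% model$rxns$id)
    flag("error", "objective-missing", model$objective$rxn,
         paste0("objective reaction ", model$objective$rxn, " not in model"))
  used <- unique(unlist(model$gene_rules))
  for (g in setdiff(model$genes, used))
    flag("warning", "orphan-gene", g,
         paste0("gene ", g, " appears in no gene rule"))
  xdup <- vapply(model$met_xrefs, function(x)
    any(vapply(x, function(ids) anyDuplicated(ids) > 0, logical(1))), logical(1))
  for (d in model$mets$id[xdup])
    flag("error", "duplicate-xref", d,
         paste0("metabolite ", d, " has duplicate xref ids"))
  if (length(v)) do.call(rbind, v) else
    data.frame(severity = character(), code = character(),
               element = character(), message = character(),
               stringsAsFactors = FALSE)
}

#' Copy reactions from a donor model
#'
#' Moves reactions (with any metabolites, compartments and genes they need)
#' from `donor` into `model`. Pre-existing ids are not duplicated; a clash on
#' a reaction id with differing stoichiometry is an error, never a silent
#' overwrite. Added reactions get `manual` provenance.
#'
#' @param model target `metabolic_model`.
#' @param donor donor `metabolic_model`.
#' @param rxn_ids reaction ids to copy from the donor.
#' @return the modified model.
#' @export
add_reactions <- function(model, donor, rxn_ids) {
  unk <- setdiff(rxn_ids, donor$rxns$id)
  if (length(unk)) stop("unknown reaction id(s) in donor: ",
                        paste(unk, collapse = ", "))
  for (rid in rxn_ids) {
    k <- rxn_idx(donor, rid)
    s <- donor$stoich[[k]]
    if (rid %in% model$rxns$id) {
      ke <- rxn_idx(model, rid)
      if (!same_stoich(model$stoich[[ke]], s))
        stop("reaction id collision with differing stoichiometry: ", rid)
      next
    }
    for (m in setdiff(names(s), model$mets$id)) {
      km <- met_idx(donor, m)
      model <- add_metabolite(model, m, donor$mets$name[km],
                              donor$mets$comp[km], donor$mets$db_id[km],
                              donor$mets$formula[km], donor$mets$charge[km],
                              donor$met_xrefs[[km]], donor$mets$foreign[km])
    }
    model <- add_reaction(model, rid, s, donor$rxns$name[k],
                          donor$rxns$lb[k], donor$rxns$ub[k],
                          donor$gene_rules[[k]], donor$rxns$subsystem[k],
                          donor$ec[[k]], donor$rxn_xrefs[[k]],
                          donor$rxns$spontaneous[k], donor$rxns$transport[k],
                          donor$rxns$exchange[k],
                          list(evidence("manual",
                                        genes = unlist(donor$gene_rules[[k]]))))
  }
  model
}

same_stoich <- function(a, b) {
  a <- a[order(names(a))]; b <- b[order(names(b))]
  identical(names(a), names(b)) && isTRUE(all.equal(unname(a), unname(b)))
}

#' Remove reactions from a model
#'
#' @param model a `metabolic_model`.
#' @param rxn_ids reaction ids to remove.
#' @param prune_orphans also drop metabolites and genes no longer referenced.
#' @return the modified model.
#' @export
remove_reactions <- function(model, rxn_ids, prune_orphans = FALSE) {
  unk <- setdiff(rxn_ids, model$rxns$id)
  if (length(unk)) stop("unknown reaction id(s): ", paste(unk, collapse = ", "))
  keep <- !model$rxns$id %in% rxn_ids
  model$rxns <- model$rxns[keep, , drop = FALSE]
  rownames(model$rxns) <- NULL
  model$stoich <- model$stoich[keep]
  model$gene_rules <- model$gene_rules[keep]
  model$raw_rules <- model$raw_rules[keep]
  model$ec <- model$ec[keep]
  model$rxn_xrefs <- model$rxn_xrefs[keep]
  model$provenance <- model$provenance[keep]
  if (prune_orphans) {
    used_m <- unique(unlist(lapply(model$stoich, names)))
    keep_m <- model$mets$id %in% used_m
    model$mets <- model$mets[keep_m, , drop = FALSE]
    rownames(model$mets) <- NULL
    model$met_xrefs <- model$met_xrefs[keep_m]
    model$genes <- sort(unique(unlist(model$gene_rules)))
    if (is.null(model$genes)) model$genes <- character()
  }
  model
}

#' Merge two models sharing a namespace
#'
#' Union of reactions, metabolites and genes keyed by id. Reactions present in
#' both with identical stoichiometry have their gene rules OR-combined,
#' provenance concatenated and bounds widened to the union interval. The same
#' reaction id with different stoichiometry is an error.
#'
#' @param a,b `metabolic_model` objects using the same identifier namespace.
#' @return the merged `metabolic_model`.
#' @export
merge_models <- function(a, b) {
  shared <- intersect(a$rxns$id, b$rxns$id)
  bad <- shared[!vapply(shared, function(r)
    same_stoich(a$stoich[[rxn_idx(a, r)]], b$stoich[[rxn_idx(b, r)]]),
    logical(1))]
  if (length(bad))
    stop("conflicting stoichiometry for shared reaction(s): ",
         paste(bad, collapse = ", "))
  out <- a
  for (r in shared) {
    ka <- rxn_idx(out, r); kb <- rxn_idx(b, r)
    out$gene_rules[ka] <- list(or_dnf(out$gene_rules[[ka]], b$gene_rules[[kb]]))
    out$provenance[[ka]] <- c(out$provenance[[ka]], b$provenance[[kb]])
    out$rxns$lb[ka] <- min(out$rxns$lb[ka], b$rxns$lb[kb])
    out$rxns$ub[ka] <- max(out$rxns$ub[ka], b$rxns$ub[kb])
    out$genes <- sort(union(out$genes, unlist(b$gene_rules[[kb]])))
  }
  for (r in setdiff(b$rxns$id, shared)) {
    k <- rxn_idx(b, r)
    for (m in setdiff(names(b$stoich[[k]]), out$mets$id)) {
      km <- met_idx(b, m)
      out <- add_metabolite(out, m, b$mets$name[km], b$mets$comp[km],
                            b$mets$db_id[km], b$mets$formula[km],
                            b$mets$charge[km], b$met_xrefs[[km]],
                            b$mets$foreign[km])
    }
    out <- add_reaction(out, r, b$stoich[[k]], b$rxns$name[k],
                        b$rxns$lb[k], b$rxns$ub[k], b$gene_rules[[k]],
                        b$rxns$subsystem[k], b$ec[[k]], b$rxn_xrefs[[k]],
                        b$rxns$spontaneous[k], b$rxns$transport[k],
                        b$rxns$exchange[k], b$provenance[[k]])
  }
  out$genes <- sort(union(out$genes, b$genes))
  out
}
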