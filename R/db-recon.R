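# Pathway-database bundle parsing and de novo draft reconstruction.
#
# A bundle directory is a canonical TSV/FASTA rendering of pathway-database
# content (reactions, metabolites, enzymes with sequences, pathways,
# spontaneous/transport flags, cross-references). Semicolons separate list
# fields; "-" marks an absent subunit list (single-sequence enzyme).

split_list <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "-" | x == "", "", x), ";",
                  fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
}

#' Parse a reaction equation string
#'
#' Grammar: `coef met[comp] + ... => ...` (irreversible) or `<=>`
#' (reversible); unit coefficients and `[comp]` tags may be omitted
#' (compartment-free database reactions).
#'
#' @param eq equation string.
#' @return list with named numeric vectors `lhs`, `rhs` (names
#'   `met` or `met[comp]` as written) and `reversible` flag.
#' @export
parse_equation <- function(eq) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else
    if (grepl("=>", eq, fixed = TRUE)) "=>" else
      stop("equation lacks an arrow ('=>' or '<=>'): ", eq)
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  parse_side <- function(s) {
    s <- trimws(s)
    if (!nzchar(s)) return(setNames(numeric(), character()))
    terms <- trimws(strsplit(s, " + ", fixed = TRUE)[[1]])
    out <- numeric()
    for (t in terms) {
      m <- regmatches(t, regexec("^([0-9.]+)\\s+(.+)$", t))[[1]]
      if (length(m)) {
        coef <- as.numeric(m[2]); met <- m[3]
      } else {
        coef <- 1; met <- t
      }
      out[met] <- (if (met %in% names(out)) out[[met]] else 0) + coef
    }
    out
  }
  list(lhs = parse_side(sides[1]), rhs = parse_side(sides[2]),
       reversible = arrow == "<=>")
}

#' Read a pathway-database bundle directory
#'
#' Expects `reactions.tsv`, `metabolites.tsv`, `enzymes.tsv`,
#' `pathways.tsv`, `protseq.fsa` and optional `rxn_xref.tsv` /
#' `met_xref.tsv`, and checks referential integrity: equations only
#' reference declared metabolites, enzymes only declared reactions, and a
#' sequence exists for every enzyme or subunit id.
#'
#' @param dir bundle directory.
#' @return list of class `database_bundle`.
#' @export
read_bundle <- function(dir) {
  need <- c("reactions.tsv", "metabolites.tsv", "enzymes.tsv",
            "pathways.tsv", "protseq.fsa")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("bundle ", dir, " is missing ", f)
  rxns <- read_tsv_file(file.path(dir, "reactions.tsv"))
  mets <- read_tsv_file(file.path(dir, "metabolites.tsv"))
  enz <- read_tsv_file(file.path(dir, "enzymes.tsv"))
  pws <- read_tsv_file(file.path(dir, "pathways.tsv"))
  seqs <- read_fasta(file.path(dir, "protseq.fsa"))
  read_xref <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_tsv_file(p) else NULL
  }
  bundle <- structure(list(
    reactions = rxns, metabolites = mets, enzymes = enz, pathways = pws,
    sequences = seqs,
    rxn_xref = read_xref("rxn_xref.tsv"),
    met_xref = read_xref("met_xref.tsv")), class = "database_bundle")
  validate_bundle(bundle)
  bundle
}

validate_bundle <- function(bundle) {
  met_ids <- bundle$metabolites$id
  for (i in seq_len(nrow(bundle$reactions))) {
    pq <- parse_equation(bundle$reactions$equation[i])
    used <- sub("\\[[^]]*\\]$", "", c(names(pq$lhs), names(pq$rhs)))
    bad <- setdiff(used, met_ids)
    if (length(bad))
      stop("reactions.tsv: reaction ", bundle$reactions$id[i],
           " references undeclared metabolite(s): ",
           paste(bad, collapse = ", "))
  }
  enz_rxns <- split_list(bundle$enzymes$reactions)
  bad <- setdiff(unlist(enz_rxns), bundle$reactions$id)
  if (length(bad))
    stop("enzymes.tsv: unknown reaction id(s): ", paste(bad, collapse = ", "))
  subunits <- split_list(bundle$enzymes$subunits)
  seq_needed <- unique(c(bundle$enzymes$id[lengths(subunits) == 0],
                         unlist(subunits)))
  bad <- setdiff(seq_needed, bundle$sequences$id)
  if (length(bad))
    stop("protseq.fsa: missing sequence for enzyme/subunit id(s): ",
         paste(bad, collapse = ", "))
  invisible(bundle)
}

#' Build the universal model from a database bundle
#'
#' The universal model expresses the whole database as one
#' `metabolic_model`: one reaction per bundle reaction with bounds derived
#' from the curated reversibility flag ([-1000, 1000] reversible, [0, 1000]
#' irreversible), metabolites in compartment `c` (transport reactions place
#' their external side in `e`), plus an enzyme index and the spontaneous and
#' transport reaction sets.
#'
#' @param bundle a `database_bundle`.
#' @return list of class `universal_model` with elements `model`, `enzymes`
#'   (data.frame with list columns `reactions`, `subunits`), `spontaneous`,
#'   `transport` (reaction id vectors), `met_ids` (bundle metabolite ids).
#' @export
build_universal_model <- function(bundle) {
  validate_bundle(bundle)
  model <- new_model("universal", "universal database model")
  mtab <- bundle$metabolites
  met_xref_of <- function(x) {
    refs <- split_list(x)[[1]]
    if (!length(refs)) return(list())
    ns <- sub(":.*", "", refs); id <- sub("^[^:]*:", "", refs)
    split(id, ns)
  }
  placed <- new.env(parent = emptyenv())
  place_met <- function(model, base, comp) {
    mid <- paste0(base, "_", comp)
    if (!is.null(placed[[mid]])) return(model)
    placed[[mid]] <- TRUE
    k <- match(base, mtab$id)
    fml <- mtab$formula[k]; chg <- mtab$charge[k]
    model <- add_metabolite(model, mid, mtab$name[k], comp, db_id = base,
                            formula = if (!is.na(fml) && nzchar(fml)) fml else
                              NA_character_,
                            charge = if (!is.na(chg) && nzchar(chg))
                              as.numeric(chg) else NA_real_,
                            xrefs = met_xref_of(mtab$xrefs[k]))
    model
  }
  flagged <- function(col) as.logical(as.integer(bundle$reactions[[col]]))
  spont <- bundle$reactions$id[flagged("spontaneous")]
  trans <- bundle$reactions$id[flagged("transport")]
  rx_ids <- if (!is.null(bundle$rxn_xref))
    split(bundle$rxn_xref[[2]], bundle$rxn_xref[[1]]) else list()
  for (i in seq_len(nrow(bundle$reactions))) {
    r <- bundle$reactions[i, ]
    pq <- parse_equation(r$equation)
    term_met <- function(tok) {
      comp <- if (grepl("\\[[^]]*\\]$", tok))
        sub(".*\\[([^]]*)\\]$", "\\1", tok) else "c"
      list(base = sub("\\[[^]]*\\]$", "", tok), comp = comp)
    }
    s <- numeric()
    for (side in c(-1, 1)) {
      v <- if (side < 0) pq$lhs else pq$rhs
      for (tok in names(v)) {
        tm <- term_met(tok)
        model <- place_met(model, tm$base, tm$comp)
        mid <- paste0(tm$base, "_", tm$comp)
        s[mid] <- (if (mid %in% names(s)) s[[mid]] else 0) + side * v[[tok]]
      }
    }
    rev <- as.logical(as.integer(r$reversible))
    model <- add_reaction(model, r$id, s, name = r$name,
                          lb = if (rev) -1000 else 0, ub = 1000,
                          subsystem = NA_character_,
                          ec = split_list(r$ec)[[1]],
                          xrefs = if (!is.null(bundle$rxn_xref) &&
                                      r$id %in% names(rx_ids))
                            list(xref = rx_ids[[r$id]]) else list(),
                          spontaneous = r$id %in% spont,
                          transport = r$id %in% trans)
  }
  enzymes <- data.frame(id = bundle$enzymes$id, stringsAsFactors = FALSE)
  enzymes$reactions <- split_list(bundle$enzymes$reactions)
  enzymes$subunits <- split_list(bundle$enzymes$subunits)
  structure(list(model = model, enzymes = enzymes, spontaneous = spont,
                 transport = trans, met_ids = mtab$id),
            class = "universal_model")
}

#' Coerce to a plain metabolic model
#' @param x object to coerce.
#' @return a `metabolic_model`.
#' @export
as_model <- function(x) UseMethod("as_model")

#' @export
as_model.metabolic_model <- function(x) x

#' @export
as_model.universal_model <- function(x) x$model

#' @export
print.universal_model <- function(x, ...) {
  cat(sprintf(paste0("<universal_model> %d reactions, %d metabolites, ",
                     "%d enzymes (%d spontaneous, %d transport rxns)\n"),
              n_rxns(x$model), length(x$met_ids), nrow(x$enzymes),
              length(x$spontaneous), length(x$transport)))
  invisible(x)
}

#' De novo draft reconstruction from a universal database model
#'
#' An enzyme is supported when at least one alignment hit against it (or
#' against at least one of its subunits) passes both cut-offs on the same
#' HSP: bit score >= `min_bit` and percent positives >= `min_positives`
#' (defaults 100 and 45). All reactions catalyzed by supported enzymes are
#' copied into the draft — transport reactions included, with the external
#' side in compartment `e`. The gene rule of a draft reaction is an OR over
#' its supporting enzymes: a complex contributes an AND term of the best
#' matching query gene per matched subunit; a single-sequence enzyme
#' contributes one single-gene term per matching query.
#'
#' @param universal a `universal_model`.
#' @param hits alignment hit data.frame (query proteome vs database
#'   sequences). Hits to unknown subjects are ignored with a warning.
#' @param min_bit bit-score cut-off.
#' @param min_positives percent-positives cut-off.
#' @return a draft `metabolic_model` with `metacyc-db` provenance.
#' @export
reconstruct_from_database <- function(universal, hits, min_bit = 100,
                                      min_positives = 45) {
  enz <- universal$enzymes
  subj_of <- list()
  for (i in seq_len(nrow(enz))) {
    subs <- enz$subunits[[i]]
    keys <- if (length(subs)) subs else enz$id[i]
    for (kk in keys) subj_of[[kk]] <- c(subj_of[[kk]], i)
  }
  unknown <- setdiff(unique(hits$subject_id), names(subj_of))
  if (length(unknown))
    warning("ignoring hit(s) to unknown subject(s): ",
            paste(unknown, collapse = ", "))
  ok <- hits$bit_score >= min_bit & hits$percent_positives >= min_positives &
    hits$subject_id %in% names(subj_of)
  hits <- hits[ok, , drop = FALSE]

  uni <- universal$model
  draft <- new_model("draft_db", "database homology draft")
  rxn_rules <- list(); rxn_score <- list(); rxn_genes <- list()
  for (i in seq_len(nrow(enz))) {
    subs <- enz$subunits[[i]]
    if (length(subs)) {
      score <- -Inf
      matched <- character()
      for (su in subs) {
        h <- hits[hits$subject_id == su, , drop = FALSE]
        if (!nrow(h)) next
        h <- h[order(-h$bit_score, h$query_id), , drop = FALSE]
        matched <- c(matched, h$query_id[1])
        score <- max(score, h$bit_score[1])
      }
      if (!length(matched)) next
      enz_terms <- list(sort(unique(matched)))
    } else {
      h <- hits[hits$subject_id == enz$id[i], , drop = FALSE]
      if (!nrow(h)) next
      enz_terms <- lapply(sort(unique(h$query_id)), identity)
      score <- max(h$bit_score)
    }
    for (r in enz$reactions[[i]]) {
      rxn_rules[[r]] <- c(rxn_rules[[r]], enz_terms)
      rxn_score[[r]] <- max(c(rxn_score[[r]], score))
      rxn_genes[[r]] <- union(rxn_genes[[r]], unlist(enz_terms))
    }
  }
  for (r in sort(names(rxn_rules))) {
    k <- rxn_idx(uni, r)
    s <- uni$stoich[[k]]
    for (m in setdiff(names(s), draft$mets$id)) {
      km <- met_idx(uni, m)
      draft <- add_metabolite(draft, m, uni$mets$name[km], uni$mets$comp[km],
                              uni$mets$db_id[km], uni$mets$formula[km],
                              uni$mets$charge[km], uni$met_xrefs[[km]])
    }
    draft <- add_reaction(draft, r, s, uni$rxns$name[k], uni$rxns$lb[k],
                          uni$rxns$ub[k], canonical_dnf(rxn_rules[[r]]),
                          uni$rxns$subsystem[k], uni$ec[[k]],
                          uni$rxn_xrefs[[k]], uni$rxns$spontaneous[k],
                          uni$rxns$transport[k], uni$rxns$exchange[k],
                          list(evidence("metacyc-db",
                                        genes = sort(rxn_genes[[r]]),
                                        score = rxn_score[[r]])))
  }
  draft
}

#' Add spontaneous reactions connected to a draft
#'
#' A spontaneous (non-enzymatic) database reaction is added iff all
#' substrates of at least one of its directions (both directions are tested
#' when it is reversible) are already present in the draft. Products missing
#' from the draft are created. Added reactions carry no gene rule and
#' `spontaneous` provenance. Idempotent.
#'
#' @param draft a draft `metabolic_model` whose metabolites use universal
#'   ids.
#' @param universal a `universal_model`.
#' @return the extended draft.
#' @export
add_spontaneous_reactions <- function(draft, universal) {
  uni <- universal$model
  for (r in universal$spontaneous) {
    if (r %in% draft$rxns$id) next
    k <- rxn_idx(uni, r)
    s <- uni$stoich[[k]]
    subs <- names(s)[s < 0]; prods <- names(s)[s > 0]
    rev <- uni$rxns$lb[k] < 0 && uni$rxns$ub[k] > 0
    fwd_ok <- length(subs) > 0 && all(subs %in% draft$mets$id)
    rev_ok <- rev && length(prods) > 0 && all(prods %in% draft$mets$id)
    if (!fwd_ok && !rev_ok) next
    for (m in setdiff(names(s), draft$mets$id)) {
      km <- met_idx(uni, m)
      draft <- add_metabolite(draft, m, uni$mets$name[km], uni$mets$comp[km],
                              uni$mets$db_id[km], uni$mets$formula[km],
                              uni$mets$charge[km], uni$met_xrefs[[km]])
    }
    draft <- add_reaction(draft, r, s, uni$rxns$name[k], uni$rxns$lb[k],
                          uni$rxns$ub[k], NULL, uni$rxns$subsystem[k],
                          uni$ec[[k]], uni$rxn_xrefs[[k]],
                          spontaneous = TRUE,
                          provenance = list(evidence("spontaneous")))
  }
  draft
}
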