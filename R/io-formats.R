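# Model and sequence I/O.
#
# SBML L3V1 + FBC v2 is the exchange format; YAML is the canonical,
# diff-friendly serialization (collections sorted by id, fixed scalar
# formatting, so byte-identical files <=> semantically equal models);
# flat text is a one-line-per-reaction format for quick inspection and
# version diffs.

num_str <- function(x, digits = 10) {
  s <- vapply(x, function(v) trimws(formatC(v, digits = digits,
                                            format = "g")), character(1))
  sub("^\\+", "", s)
}

sbml_escape <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "")[[1]]
    paste(vapply(chars, function(ch)
      if (grepl("^[A-Za-z0-9_]$", ch)) ch else
        sprintf("__%d__", utf8ToInt(ch)), character(1)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

sbml_unescape <- function(x) {
  vapply(x, function(s) {
    m <- gregexpr("__([0-9]+)__", s)[[1]]
    if (m[1] == -1) return(s)
    parts <- regmatches(s, gregexpr("__([0-9]+)__", s))[[1]]
    for (p in unique(parts))
      s <- gsub(p, intToUtf8(as.integer(gsub("_", "", p))), s, fixed = TRUE)
    s
  }, character(1), USE.NAMES = FALSE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
GF_NS <- "https://gemforge.invalid/annotation"

#' Write a model as SBML L3V1 with FBC v2
#'
#' Gene associations are serialized as FBC gene-product associations
#' (`fbc:and` within an OR term, `fbc:or` across terms), bounds as shared
#' parameters, the objective as the active FBC objective, and cross
#' references as MIRIAM-style identifiers.org URIs in an RDF annotation.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS, "xmlns:gf" = GF_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sbml_escape(model$id),
                             name = model$name, "fbc:strict" = "false")
  loc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cid in names(model$comps))
    xml2::xml_add_child(loc, "compartment", id = sbml_escape(cid),
                        name = model$comps[[cid]], constant = "true")

  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub, 0)))
  bnames <- paste0("bnd_", sbml_escape(num_str(bounds, 15)))
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bounds))
    xml2::xml_add_child(lop, "parameter", id = bnames[i],
                        value = num_str(bounds[i], 15), constant = "true")
  bname_of <- function(v) bnames[match(v, bounds)]

  add_xref_annotation <- function(node, xrefs, extra = character()) {
    uris <- extra
    for (ns in sort(names(xrefs)))
      uris <- c(uris, paste0("https://identifiers.org/", ns, "/",
                             sort(xrefs[[ns]])))
    if (!length(uris)) return(invisible())
    lis <- paste0('<rdf:li rdf:resource="', uris, '"/>', collapse = "")
    frag <- xml2::read_xml(paste0(
      '<annotation><rdf:RDF',
      ' xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
      ' xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">',
      '<rdf:Description><bqbiol:is><rdf:Bag>', lis,
      '</rdf:Bag></bqbiol:is></rdf:Description></rdf:RDF></annotation>'))
    xml2::xml_add_child(node, frag)
  }

  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (k in seq_len(n_mets(model))) {
    m <- model$mets[k, ]
    attrs <- c(id = paste0("M_", sbml_escape(m$id)), name = m$name,
               compartment = sbml_escape(m$comp), constant = "false",
               hasOnlySubstanceUnits = "false", boundaryCondition = "false")
    if (!is.na(m$formula)) attrs <- c(attrs, "fbc:chemicalFormula" = m$formula)
    if (!is.na(m$charge)) attrs <- c(attrs, "fbc:charge" =
                                       num_str(m$charge, 15))
    if (!is.na(m$db_id)) attrs <- c(attrs, "gf:dbId" = m$db_id)
    if (isTRUE(m$foreign)) attrs <- c(attrs, "gf:foreign" = "true")
    sp <- xml2::xml_add_child(los, "species")
    xml2::xml_set_attrs(sp, attrs)
    add_xref_annotation(sp, model$met_xrefs[[k]])
  }

  logp <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
  for (g in model$genes)
    xml2::xml_add_child(logp, "fbc:geneProduct",
                        "fbc:id" = paste0("G_", sbml_escape(g)),
                        "fbc:label" = g)

  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  for (k in seq_len(n_rxns(model))) {
    r <- model$rxns[k, ]
    attrs <- c(id = paste0("R_", sbml_escape(r$id)), name = r$name,
               reversible = tolower(as.character(r$lb < 0 && r$ub > 0)),
               fast = "false",
               "fbc:lowerFluxBound" = bname_of(r$lb),
               "fbc:upperFluxBound" = bname_of(r$ub))
    if (!is.na(r$subsystem)) attrs <- c(attrs, "gf:subsystem" = r$subsystem)
    for (fl in c("spontaneous", "transport", "exchange"))
      if (isTRUE(r[[fl]]))
        attrs <- c(attrs, setNames("true", paste0("gf:", fl)))
    rx <- xml2::xml_add_child(lor, "reaction")
    xml2::xml_set_attrs(rx, attrs)
    ecu <- if (length(model$ec[[k]]))
      paste0("https://identifiers.org/ec-code/", sort(model$ec[[k]]))
    else character()
    add_xref_annotation(rx, model$rxn_xrefs[[k]], extra = ecu)
    s <- model$stoich[[k]]
    subs <- s[s < 0]; prods <- s[s > 0]
    if (length(subs)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (m in sort(names(subs)))
        xml2::xml_add_child(lre, "speciesReference",
                            species = paste0("M_", sbml_escape(m)),
                            stoichiometry = num_str(-subs[[m]], 15),
                            constant = "true")
    }
    if (length(prods)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (m in sort(names(prods)))
        xml2::xml_add_child(lpr, "speciesReference",
                            species = paste0("M_", sbml_escape(m)),
                            stoichiometry = num_str(prods[[m]], 15),
                            constant = "true")
    }
    dnf <- model$gene_rules[[k]]
    if (!is.null(dnf)) {
      gpa <- xml2::xml_add_child(rx, "fbc:geneProductAssociation")
      add_term <- function(parent, term) {
        if (length(term) == 1)
          xml2::xml_add_child(parent, "fbc:geneProductRef",
                              "fbc:geneProduct" = paste0("G_", sbml_escape(term)))
        else {
          andn <- xml2::xml_add_child(parent, "fbc:and")
          for (g in term)
            xml2::xml_add_child(andn, "fbc:geneProductRef",
                                "fbc:geneProduct" = paste0("G_", sbml_escape(g)))
        }
      }
      if (length(dnf) == 1) add_term(gpa, dnf[[1]])
      else {
        orn <- xml2::xml_add_child(gpa, "fbc:or")
        for (term in dnf) add_term(orn, term)
      }
    }
  }

  if (!is.na(model$objective$rxn)) {
    loo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives",
                               "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(loo, "fbc:objective", "fbc:id" = "obj",
      "fbc:type" = if (model$objective$sense == "max") "maximize" else "minimize")
    lof <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lof, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_escape(model$objective$rxn)),
      "fbc:coefficient" = "1")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

strip_prefix <- function(x, p) sbml_unescape(sub(paste0("^", p), "", x))

#' Read an SBML L3V1 FBC v2 model
#'
#' @param path SBML file. Must declare the FBC v2 namespace; anything else is
#'   rejected with an error naming the offending element.
#' @return a `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  nss <- unlist(xml2::xml_ns(doc))
  if (!FBC_NS %in% nss)
    stop("FBC v2 required: SBML file ", path,
         " does not declare the fbc version 2 namespace")
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("malformed SBML: root element is <", xml2::xml_name(root), ">")
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mnode, "xml_missing")) stop("malformed SBML: no <model> element")
  av <- function(node, a) xml2::xml_attr(node, a)
  model <- new_model(sbml_unescape(av(mnode, "id")),
                     av(mnode, "name") %||% "")
  model$comps <- character()
  for (cn in xml2::xml_find_all(mnode, "./s:listOfCompartments/s:compartment", ns))
    model$comps[[sbml_unescape(av(cn, "id"))]] <-
      av(cn, "name") %||% sbml_unescape(av(cn, "id"))
  model$comps <- model$comps[order(names(model$comps))]

  params <- new.env(parent = emptyenv())
  for (pn in xml2::xml_find_all(mnode, "./s:listOfParameters/s:parameter", ns))
    assign(av(pn, "id"), as.numeric(av(pn, "value")), envir = params)

  parse_uris <- function(node) {
    lis <- xml2::xml_find_all(node,
      ".//*[local-name()='li']")
    uris <- xml2::xml_attr(lis, "resource")
    uris <- uris[!is.na(uris)]
    xrefs <- list(); ec <- character()
    for (u in grep("identifiers\\.org/", uris, value = TRUE)) {
      rest <- sub(".*identifiers\\.org/", "", u)
      nsname <- sub("/.*", "", rest); id <- sub("^[^/]*/", "", rest)
      if (nsname == "ec-code") ec <- c(ec, id)
      else xrefs[[nsname]] <- c(xrefs[[nsname]], id)
    }
    list(xrefs = xrefs, ec = ec)
  }

  for (sn in xml2::xml_find_all(mnode, "./s:listOfSpecies/s:species", ns)) {
    ch <- av(sn, "charge")  # fbc:charge resolves via attr name w/o ns in xml2
    an <- parse_uris(sn)
    model <- add_metabolite(model,
      id = strip_prefix(av(sn, "id"), "M_"),
      name = av(sn, "name") %||% strip_prefix(av(sn, "id"), "M_"),
      comp = sbml_unescape(av(sn, "compartment")),
      db_id = av(sn, "dbId") %||% NA_character_,
      formula = av(sn, "chemicalFormula") %||% NA_character_,
      charge = if (is.na(ch)) NA_real_ else as.numeric(ch),
      xrefs = an$xrefs,
      foreign = identical(av(sn, "foreign"), "true"))
  }
  model$comps <- model$comps[order(names(model$comps))]

  genes <- character()
  for (gn in xml2::xml_find_all(mnode,
      "./fbc:listOfGeneProducts/fbc:geneProduct", ns))
    genes <- c(genes, av(gn, "label") %||%
                 strip_prefix(xml2::xml_attr(gn, "id"), "G_"))

  parse_assoc <- function(node) {
    # returns DNF
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(list(strip_prefix(xml2::xml_attr(node, "geneProduct"), "G_")))
    kids <- xml2::xml_children(node)
    sub <- lapply(kids, parse_assoc)
    if (nm == "or") return(unlist(sub, recursive = FALSE))
    if (nm == "and") {
      out <- list(character())
      for (d in sub)
        out <- unlist(lapply(out, function(a)
          lapply(d, function(b) c(a, b))), recursive = FALSE)
      return(out)
    }
    stop("malformed SBML: unexpected element <", nm,
         "> in gene product association")
  }

  for (rn in xml2::xml_find_all(mnode, "./s:listOfReactions/s:reaction", ns)) {
    rid <- strip_prefix(av(rn, "id"), "R_")
    lbp <- av(rn, "lowerFluxBound"); ubp <- av(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp))
      stop("FBC v2 required: reaction ", rid, " lacks fbc flux bounds")
    lb <- get(lbp, envir = params); ub <- get(ubp, envir = params)
    s <- numeric()
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns))
      s[strip_prefix(av(sr, "species"), "M_")] <-
        -as.numeric(av(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns))
      s[strip_prefix(av(sr, "species"), "M_")] <-
        as.numeric(av(sr, "stoichiometry"))
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    dnf <- if (!inherits(gpa, "xml_missing"))
      canonical_dnf(parse_assoc(xml2::xml_child(gpa))) else NULL
    an <- parse_uris(rn)
    model <- add_reaction(model, rid, s,
      name = av(rn, "name") %||% rid, lb = lb, ub = ub, gene_rule = dnf,
      subsystem = av(rn, "subsystem") %||% NA_character_,
      ec = an$ec, xrefs = an$xrefs,
      spontaneous = identical(av(rn, "spontaneous"), "true"),
      transport = identical(av(rn, "transport"), "true"),
      exchange = identical(av(rn, "exchange"), "true"))
  }
  model$genes <- sort(union(model$genes, genes))

  fo <- xml2::xml_find_first(mnode,
    "./fbc:listOfObjectives/fbc:objective", ns)
  if (!inherits(fo, "xml_missing")) {
    fr <- xml2::xml_find_first(fo,
      "./fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
    model$objective <- list(
      rxn = strip_prefix(xml2::xml_attr(fr, "reaction"), "R_"),
      sense = if (identical(xml2::xml_attr(fo, "type"), "minimize"))
        "min" else "max")
  }
  model
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

yq <- function(s) {
  s <- gsub("\\\\", "\\\\\\\\", s)
  s <- gsub('"', '\\\\"', s)
  paste0('"', s, '"')
}

#' Write a model as canonical YAML
#'
#' Collections are sorted by id and scalar formatting is fixed (numbers at 10
#' significant digits), so two YAML files are byte-identical exactly when the
#' models are semantically equal — the property that makes the format
#' diff-friendly for tracking model versions.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_yaml_model <- function(model, path) {
  out <- character()
  emit <- function(...) out <<- c(out, sprintf(...))
  emit("metadata:")
  emit("  id: %s", yq(model$id))
  emit("  name: %s", yq(model$name))
  emit("compartments:")
  for (cid in sort(names(model$comps)))
    emit("  %s: %s", yq(cid), yq(model$comps[[cid]]))
  emit_xrefs <- function(xrefs, indent) {
    if (!length(xrefs)) return(invisible())
    emit("%sxrefs:", indent)
    for (nsn in sort(names(xrefs)))
      emit("%s  %s: [%s]", indent, yq(nsn),
           paste(yq(sort(xrefs[[nsn]])), collapse = ", "))
  }
  emit("metabolites:")
  for (k in order(model$mets$id)) {
    m <- model$mets[k, ]
    emit("  - id: %s", yq(m$id))
    emit("    name: %s", yq(m$name))
    emit("    compartment: %s", yq(m$comp))
    if (!is.na(m$db_id)) emit("    db_id: %s", yq(m$db_id))
    if (!is.na(m$formula)) emit("    formula: %s", yq(m$formula))
    if (!is.na(m$charge)) emit("    charge: %s", num_str(m$charge))
    if (isTRUE(m$foreign)) emit("    foreign: true")
    emit_xrefs(model$met_xrefs[[k]], "    ")
  }
  emit("reactions:")
  for (k in order(model$rxns$id)) {
    r <- model$rxns[k, ]
    emit("  - id: %s", yq(r$id))
    emit("    name: %s", yq(r$name))
    if (!is.na(r$subsystem)) emit("    subsystem: %s", yq(r$subsystem))
    emit("    lower_bound: %s", num_str(r$lb))
    emit("    upper_bound: %s", num_str(r$ub))
    emit("    stoichiometry:")
    s <- model$stoich[[k]]
    for (m in sort(names(s)))
      emit("      %s: %s", yq(m), num_str(s[[m]]))
    dnf <- model$gene_rules[[k]]
    if (!is.null(dnf)) emit("    gene_rule: %s", yq(format_dnf(dnf)))
    if (length(model$ec[[k]]))
      emit("    ec: [%s]", paste(yq(sort(model$ec[[k]])), collapse = ", "))
    emit_xrefs(model$rxn_xrefs[[k]], "    ")
    flags <- c("spontaneous", "transport", "exchange")
    on <- flags[vapply(flags, function(f) isTRUE(r[[f]]), logical(1))]
    if (length(on)) emit("    flags: [%s]", paste(on, collapse = ", "))
    prov <- model$provenance[[k]]
    if (length(prov)) {
      emit("    provenance:")
      for (ev in prov) {
        emit("      - source: %s", yq(ev$source))
        if (length(ev$genes))
          emit("        genes: [%s]", paste(yq(sort(ev$genes)), collapse = ", "))
        if (!is.null(ev$score)) emit("        score: %s", num_str(ev$score))
      }
    }
  }
  emit("genes:")
  for (g in sort(model$genes)) emit("  - %s", yq(g))
  emit("objective:")
  emit("  reaction: %s",
       if (is.na(model$objective$rxn)) "null" else yq(model$objective$rxn))
  emit("  sense: %s", yq(model$objective$sense))
  writeLines(out, path)
  invisible(path)
}

#' Read a model from canonical YAML
#' @param path YAML file written by [write_yaml_model()].
#' @return a `metabolic_model`.
#' @export
read_yaml_model <- function(path) {
  y <- yaml::read_yaml(path)
  model <- new_model(y$metadata$id, y$metadata$name %||% "")
  model$comps <- character()
  for (cid in names(y$compartments)) model$comps[[cid]] <- y$compartments[[cid]]
  model$comps <- model$comps[order(names(model$comps))]
  fix_xrefs <- function(x) lapply(x, function(v) as.character(unlist(v)))
  for (m in y$metabolites)
    model <- add_metabolite(model, m$id, m$name %||% m$id,
                            m$compartment %||% "c", m$db_id %||% NA_character_,
                            m$formula %||% NA_character_,
                            if (is.null(m$charge)) NA_real_ else as.numeric(m$charge),
                            fix_xrefs(m$xrefs %||% list()),
                            isTRUE(m$foreign))
  for (r in y$reactions) {
    prov <- lapply(r$provenance %||% list(), function(p)
      evidence(p$source, as.character(unlist(p$genes)), p$score))
    flags <- as.character(unlist(r$flags %||% list()))
    model <- add_reaction(model, r$id,
                          setNames(as.numeric(unlist(r$stoichiometry)),
                                   names(r$stoichiometry)),
                          name = r$name %||% r$id,
                          lb = as.numeric(r$lower_bound),
                          ub = as.numeric(r$upper_bound),
                          gene_rule = r$gene_rule,
                          subsystem = r$subsystem %||% NA_character_,
                          ec = as.character(unlist(r$ec %||% list())),
                          xrefs = fix_xrefs(r$xrefs %||% list()),
                          spontaneous = "spontaneous" %in% flags,
                          transport = "transport" %in% flags,
                          exchange = "exchange" %in% flags,
                          provenance = prov)
  }
  model$genes <- sort(union(model$genes, as.character(unlist(y$genes))))
  model$objective <- list(rxn = y$objective$reaction %||% NA_character_,
                          sense = y$objective$sense %||% "max")
  model
}

#' Write a model as tab-separated flat text
#'
#' One line per reaction: id, equation, gene rule, subsystem, lb, ub.
#' Equations use `coef met[comp]` terms joined by `+`, with `<=>` for
#' reversible and `=>` for irreversible reactions; unit coefficients are
#' omitted. Exchange reactions appear with an empty side.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flat_text <- function(model, path) {
  fmt_side <- function(s) {
    if (!length(s)) return("")
    s <- s[order(names(s))]
    paste(vapply(names(s), function(m) {
      k <- met_idx(model, m)
      lbl <- paste0(model$mets$db_id[k] %||% m, "[", model$mets$comp[k], "]")
      if (isTRUE(all.equal(s[[m]], 1))) lbl else paste(num_str(s[[m]]), lbl)
    }, ""), collapse = " + ")
  }
  lines <- vapply(seq_len(n_rxns(model)), function(k) {
    r <- model$rxns[k, ]
    s <- model$stoich[[k]]
    arrow <- if (r$lb < 0 && r$ub > 0) "<=>" else "=>"
    eq <- trimws(paste(fmt_side(-s[s < 0]), arrow, fmt_side(s[s > 0])))
    paste(r$id, eq, format_dnf(model$gene_rules[[k]]),
          ifelse(is.na(r$subsystem), "", r$subsystem),
          num_str(r$lb), num_str(r$ub), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein FASTA file
#' @param path FASTA file.
#' @return data.frame with columns `id` (first whitespace token of the
#'   header) and `sequence` (upper-cased).
#' @export
read_fasta <- function(path) {
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) stop("cannot read FASTA ", path, ": ",
                                            conditionMessage(e)))
  if (!length(seqs)) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, "", 1)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  data.frame(id = ids, sequence = toupper(as.character(seqs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write protein records as FASTA
#' @param records data.frame with `id` and `sequence` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    writeLines(gsub("(.{60})", "\\1\n", records$sequence[i]), con)
  }
  invisible(path)
}

#' Read a BLAST-style tabular alignment file
#'
#' Dialect `blast6+ppos`: tab-separated columns `qseqid sseqid evalue
#' bitscore ppos pident length`.
#'
#' @param path alignment table file.
#' @param dialect only `"blast6+ppos"` is supported.
#' @return data.frame of alignment hits with columns `query_id`,
#'   `subject_id`, `evalue`, `bit_score`, `percent_positives`,
#'   `percent_identity`, `aln_length`, in file order.
#' @export
read_alignment_table <- function(path, dialect = "blast6+ppos") {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bit_score = numeric(),
                      percent_positives = numeric(),
                      percent_identity = numeric(), aln_length = integer(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 7)
  if (length(bad))
    stop("alignment table ", path, ": expected 7 tab-separated columns, got ",
         length(parts[[bad[1]]]), " at line ", bad[1])
  m <- do.call(rbind, parts)
  data.frame(query_id = m[, 1], subject_id = m[, 2],
             evalue = as.numeric(m[, 3]), bit_score = as.numeric(m[, 4]),
             percent_positives = as.numeric(m[, 5]),
             percent_identity = as.numeric(m[, 6]),
             aln_length = as.integer(m[, 7]), stringsAsFactors = FALSE)
}

#' Write alignment hits in the blast6+ppos dialect
#' @param hits data.frame as returned by [read_alignment_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s\t%d",
                   hits$query_id, hits$subject_id, num_str(hits$evalue),
                   num_str(hits$bit_score), num_str(hits$percent_positives),
                   num_str(hits$percent_identity), hits$aln_length)
  writeLines(lines, path)
  invisible(path)
}
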