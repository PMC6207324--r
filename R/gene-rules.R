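#' Parse a gene association rule string
#'
#' Grammar: identifiers, `and`, `or` (case-insensitive) and parentheses.
#' The parsed boolean expression is expanded to disjunctive normal form:
#' a list of character vectors, one per OR term (isozyme alternative),
#' genes within a term AND-ed (complex subunits).
#'
#' @param s rule string; `""`/`NA` yield `NULL` (no gene association).
#' @return canonical DNF (list of character vectors) or `NULL`.
#' @export
#' @examples
#' parse_gene_rule("g1 and (g2 or g3)")
parse_gene_rule <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- tokenize_rule(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$src <- s
  dnf <- parse_or(st)
  if (st$pos <= nrow(st$toks))
    rule_error(st, "unexpected token")
  canonical_dnf(dnf)
}

tokenize_rule <- function(s) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, s)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(s, gregexpr(pat, s))[[1]],
             pos = as.integer(m), stringsAsFactors = FALSE)
}

rule_error <- function(st, what) {
  pos <- if (st$pos <= nrow(st$toks)) st$toks$pos[st$pos] else nchar(st$src) + 1L
  stop(sprintf("cannot parse gene rule at position %d (%s): %s",
               pos, what, st$src), call. = FALSE)
}

peek_tok <- function(st)
  if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA_character_

parse_or <- function(st) {
  terms <- parse_and(st)
  while (!is.na(t <- peek_tok(st)) && tolower(t) == "or") {
    st$pos <- st$pos + 1L
    terms <- c(terms, parse_and(st))
  }
  terms
}

parse_and <- function(st) {
  dnf <- parse_atom(st)
  while (!is.na(t <- peek_tok(st)) && tolower(t) == "and") {
    st$pos <- st$pos + 1L
    rhs <- parse_atom(st)
    # distribute: (A or B) and (C or D) -> AC, AD, BC, BD
    dnf <- unlist(lapply(dnf, function(a)
      lapply(rhs, function(b) c(a, b))), recursive = FALSE)
  }
  dnf
}

parse_atom <- function(st) {
  t <- peek_tok(st)
  if (is.na(t)) rule_error(st, "unexpected end of rule")
  if (t == "(") {
    st$pos <- st$pos + 1L
    dnf <- parse_or(st)
    if (!identical(peek_tok(st), ")")) rule_error(st, "expected ')'")
    st$pos <- st$pos + 1L
    return(dnf)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    rule_error(st, paste0("expected gene id, got '", t, "'"))
  st$pos <- st$pos + 1L
  list(t)
}

#' Canonicalize a DNF gene rule
#'
#' Sorts and dedupes genes within each AND term, then sorts and dedupes the
#' terms. `NULL` and empty rules stay `NULL`.
#'
#' @param dnf list of character vectors.
#' @return canonical DNF or `NULL`.
#' @export
canonical_dnf <- function(dnf) {
  if (is.null(dnf) || !length(dnf)) return(NULL)
  if (is.character(dnf)) dnf <- list(dnf)
  dnf <- lapply(dnf, function(t) sort(unique(t)))
  if (any(lengths(dnf) == 0)) stop("empty AND term in gene rule")
  keys <- vapply(dnf, paste, "", collapse = "\r")
  dnf[order(keys)][!duplicated(sort(keys))]
}

#' OR-combine two DNF rules
#' @param a,b canonical DNF rules (or `NULL`).
#' @return canonical union DNF.
#' @export
or_dnf <- function(a, b) canonical_dnf(c(a, b))

#' Evaluate a DNF rule under a gene presence assignment
#' @param dnf DNF rule; `NULL` evaluates `TRUE` (no gene dependency).
#' @param present character vector of genes that are present/active.
#' @return logical.
#' @export
eval_dnf <- function(dnf, present) {
  if (is.null(dnf)) return(TRUE)
  any(vapply(dnf, function(term) all(term %in% present), logical(1)))
}

#' Format a DNF rule as a string
#' @param dnf DNF rule or `NULL`.
#' @return rule string (`""` for `NULL`).
#' @export
format_dnf <- function(dnf) {
  if (is.null(dnf)) return("")
  terms <- vapply(dnf, function(t) {
    s <- paste(t, collapse = " and ")
    if (length(t) > 1 && length(dnf) > 1) paste0("(", s, ")") else s
  }, "")
  paste(terms, collapse = " or ")
}

#' Standardize all gene rules of a model
#'
#' Re-parses any raw rule strings, stores every rule as canonical DNF and
#' resets the model gene list to exactly the union of genes referenced by the
#' rules. Idempotent.
#'
#' @param model a `metabolic_model`.
#' @return the modified model.
#' @export
standardize_gene_rules <- function(model) {
  for (k in seq_len(n_rxns(model))) {
    raw <- model$raw_rules[k]
    dnf <- if (!is.na(raw)) {
      tryCatch(parse_gene_rule(raw), error = function(e)
        stop("reaction ", model$rxns$id[k], ": ", conditionMessage(e),
             call. = FALSE))
    } else model$gene_rules[[k]]
    model$gene_rules[k] <- list(canonical_dnf(dnf))
  }
  model$genes <- sort(unique(unlist(model$gene_rules)))
  if (is.null(model$genes)) model$genes <- character()
  model
}

#' Replace the gene association of one reaction
#'
#' @param model a `metabolic_model`.
#' @param rxn_id reaction whose rule is replaced.
#' @param rule_string new rule (`""` removes the gene association).
#' @return the modified model.
#' @export
change_gene_association <- function(model, rxn_id, rule_string) {
  k <- rxn_idx(model, rxn_id)
  if (is.na(k)) stop("unknown reaction id: ", rxn_id)
  dnf <- parse_gene_rule(rule_string)
  model$gene_rules[k] <- list(dnf)
  model$raw_rules[k] <- if (nzchar(trimws(rule_string))) rule_string else NA_character_
  model$genes <- sort(union(model$genes, unlist(dnf)))
  model
}
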