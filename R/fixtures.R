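# Deterministic synthetic fixtures.
#
# The generators emulate the inputs of database-driven reconstruction — a
# pathway-database bundle (chains of isomerase-like, elementally balanced
# reactions with enzymes, spontaneous condensations and transporters), a
# shadow namespace copy with partially withheld cross-references, and a
# query proteome with planted orthologs — so the whole pipeline is testable
# without any database download. Everything is a pure function of
# (spec, seed).

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

#' Fixture specification
#'
#' @param seed RNG seed; all generation is a pure function of the spec.
#' @param n_pathways number of linear pathways (chains).
#' @param reactions_per_pathway chain length.
#' @param n_decoys decoy enzymes whose sequences match no planted query.
#' @param planted_fraction fraction of chain enzymes with a planted query
#'   ortholog in the proteome.
#' @param noise substitution rate applied to planted query sequences.
#' @param withhold_xref_fraction fraction of reaction cross-references
#'   withheld from the shadow namespace tables (exercises reactant
#'   matching).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_pathways = 6, reactions_per_pathway = 4,
                         n_decoys = 5, planted_fraction = 0.6, noise = 0,
                         withhold_xref_fraction = 0.25) {
  stopifnot(n_pathways >= 1, reactions_per_pathway >= 1, n_decoys >= 0,
            planted_fraction >= 0, planted_fraction <= 1,
            noise >= 0, noise <= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic database bundle pair with ground truth
#'
#' Builds the primary bundle (A namespace), a shadow copy in a renamed B
#' namespace (`K` prefix) with a fraction of reaction cross-references
#' withheld and systematic extra protons on some withheld reactions, a KO
#' index over the shadow bundle, and the planted ground truth used by the
#' recovery tests.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture_bundle`: `bundle`, `shadow`
#'   (`database_bundle`s), `truth` (planted enzymes/reactions, withheld
#'   pairs, KO tables, spontaneous ids).
#' @export
generate_bundle <- function(spec) with_seed(spec$seed, {
  P <- spec$n_pathways; R <- spec$reactions_per_pathway
  mets <- list(); rxns <- list(); enzymes <- list(); pathways <- list()
  seqs <- list()
  formula_of <- character()
  for (p in seq_len(P)) {
    fml <- sprintf("C%dH%dO%d", sample(3:9, 1), sample(4:14, 1),
                   sample(2:7, 1))
    for (j in 0:R) {
      id <- sprintf("M%d_%d", p, j)
      mets[[id]] <- data.frame(id = id, name = paste0("metabolite ", id),
                               formula = fml, charge = sample(-1:1, 1),
                               stringsAsFactors = FALSE)
      formula_of[id] <- fml
    }
    prxns <- character()
    for (j in seq_len(R)) {
      id <- sprintf("R%d_%d", p, j)
      rev <- stats::runif(1) < 0.3
      rxns[[id]] <- data.frame(
        id = id, name = paste0("reaction ", id),
        equation = sprintf("M%d_%d %s M%d_%d", p, j - 1,
                           if (rev) "<=>" else "=>", p, j),
        reversible = as.integer(rev), ec = sprintf("%d.%d.1.1", p, j),
        pathways = sprintf("PWY%d", p), spontaneous = 0L, transport = 0L,
        balanced = 1L, stringsAsFactors = FALSE)
      prxns <- c(prxns, id)
    }
    pathways[[p]] <- data.frame(id = sprintf("PWY%d", p),
                                name = paste0("pathway ", p),
                                reactions = paste(prxns, collapse = ";"),
                                stringsAsFactors = FALSE)
  }
  # proton (never on A-side equations; the shadow namespace adds it)
  mets[["PROTON"]] <- data.frame(id = "PROTON", name = "proton",
                                 formula = "H", charge = 1,
                                 stringsAsFactors = FALSE)
  # spontaneous condensations: Mx_1 + My_1 <=> SPMx (formula sums)
  spont_ids <- character()
  if (P >= 2) {
    for (sidx in seq_len(min(2, P - 1))) {
      a <- sprintf("M%d_1", sidx); b <- sprintf("M%d_1", sidx + 1)
      prod <- sprintf("SP%d", sidx)
      mets[[prod]] <- data.frame(id = prod, name = paste0("condensate ", prod),
                                 formula = paste0(formula_of[a],
                                                  formula_of[b]),
                                 charge = 0, stringsAsFactors = FALSE)
      id <- sprintf("RSP%d", sidx)
      rxns[[id]] <- data.frame(id = id, name = paste0("spontaneous ", id),
                               equation = sprintf("%s + %s <=> %s", a, b, prod),
                               reversible = 1L, ec = "", pathways = "",
                               spontaneous = 1L, transport = 0L,
                               balanced = 1L, stringsAsFactors = FALSE)
      spont_ids <- c(spont_ids, id)
    }
  }
  # transporters for the chain heads of the first two pathways
  transport_ids <- character()
  for (t in seq_len(min(2, P))) {
    id <- sprintf("RT%d", t)
    rxns[[id]] <- data.frame(id = id, name = paste0("transport ", id),
                             equation = sprintf("M%d_0[e] => M%d_0[c]", t, t),
                             reversible = 0L, ec = "", pathways = "",
                             spontaneous = 0L, transport = 1L, balanced = 1L,
                             stringsAsFactors = FALSE)
    transport_ids <- c(transport_ids, id)
  }
  # enzymes: one per enzymatic reaction; every third is a two-subunit complex
  enzymatic <- setdiff(names(rxns), spont_ids)
  enz_rows <- list(); truth_rows <- list()
  for (i in seq_along(enzymatic)) {
    eid <- sprintf("E%03d", i)
    complexq <- i %% 3 == 0
    if (complexq) {
      subs <- paste0(eid, c("_s1", "_s2"))
      for (su in subs) seqs[[su]] <- random_protein(sample(70:110, 1))
    } else {
      subs <- character()
      seqs[[eid]] <- random_protein(sample(70:110, 1))
    }
    enz_rows[[i]] <- data.frame(id = eid, reactions = enzymatic[i],
                                subunits = if (length(subs))
                                  paste(subs, collapse = ";") else "-",
                                stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(enzyme = eid, reaction = enzymatic[i],
                                  is_complex = complexq,
                                  stringsAsFactors = FALSE)
  }
  # decoy enzymes on a dedicated decoy chain
  n_dec <- spec$n_decoys
  if (n_dec > 0) {
    fml <- "C2H6O"
    for (j in 0:n_dec) {
      id <- sprintf("MD_%d", j)
      mets[[id]] <- data.frame(id = id, name = paste0("decoy met ", id),
                               formula = fml, charge = 0,
                               stringsAsFactors = FALSE)
    }
    for (j in seq_len(n_dec)) {
      id <- sprintf("RD_%d", j)
      rxns[[id]] <- data.frame(id = id, name = paste0("decoy reaction ", id),
                               equation = sprintf("MD_%d => MD_%d", j - 1, j),
                               reversible = 0L, ec = "", pathways = "",
                               spontaneous = 0L, transport = 0L, balanced = 1L,
                               stringsAsFactors = FALSE)
      eid <- sprintf("DEC%03d", j)
      seqs[[eid]] <- random_protein(sample(70:110, 1))
      enz_rows[[length(enz_rows) + 1L]] <-
        data.frame(id = eid, reactions = id, subunits = "-",
                   stringsAsFactors = FALSE)
    }
  }
  met_df <- do.call(rbind, mets); rownames(met_df) <- NULL
  met_df$xrefs <- paste0("shadow:K", met_df$id)
  rxn_df <- do.call(rbind, rxns); rownames(rxn_df) <- NULL
  enz_df <- do.call(rbind, enz_rows); rownames(enz_df) <- NULL
  pwy_df <- do.call(rbind, pathways); rownames(pwy_df) <- NULL
  seq_df <- data.frame(id = names(seqs), sequence = unlist(seqs),
                       stringsAsFactors = FALSE, row.names = NULL)

  # shadow namespace: rename met/rxn ids with a K prefix; withhold a
  # fraction of reaction xrefs; add an extra proton to the withheld
  # reactions' product side (systematic namespace disagreement)
  rename <- function(x) paste0("K", x)
  sh_met <- met_df; sh_met$id <- rename(sh_met$id)
  sh_met$name <- paste0("shadow ", sh_met$name)
  sh_met$xrefs <- ""
  sh_rxn <- rxn_df
  sh_rxn$id <- rename(sh_rxn$id)
  retok <- function(eq) {
    # rename bare met tokens inside an equation, preserving coef/comp tags
    parts <- strsplit(eq, " ", fixed = TRUE)[[1]]
    arrowed <- parts %in% c("=>", "<=>", "+")
    isnum <- grepl("^[0-9.]+$", parts)
    parts[!arrowed & !isnum] <- sub("^([^\\[]+)", "K\\1",
                                    parts[!arrowed & !isnum])
    paste(parts, collapse = " ")
  }
  sh_rxn$equation <- vapply(sh_rxn$equation, retok, "", USE.NAMES = FALSE)
  n_withhold <- floor(spec$withhold_xref_fraction * nrow(rxn_df))
  chain_rxns <- grep("^R[0-9]+_", rxn_df$id, value = TRUE)
  withheld <- sort(sample(chain_rxns, min(n_withhold, length(chain_rxns))))
  for (w in withheld) {
    i <- match(paste0("K", w), sh_rxn$id)
    sh_rxn$equation[i] <- paste(sh_rxn$equation[i], "+", "KPROTON")
  }
  rxn_xref <- data.frame(a_id = rxn_df$id,
                         b_id = rename(rxn_df$id),
                         stringsAsFactors = FALSE)
  rxn_xref <- rxn_xref[!rxn_xref$a_id %in% withheld, , drop = FALSE]
  met_xref <- data.frame(a_id = met_df$id, b_id = rename(met_df$id),
                         proton = met_df$id == "PROTON",
                         stringsAsFactors = FALSE)
  # KO index over the shadow bundle: one KO per shadow chain/transport rxn
  kos <- grep("^K(R[0-9]+_|RT)", sh_rxn$id, value = TRUE)
  ko_df <- data.frame(id = sprintf("KO%03d", seq_along(kos)),
                      reactions = kos, subunits = "-",
                      stringsAsFactors = FALSE)
  ko_seq <- data.frame(id = ko_df$id,
                       sequence = vapply(seq_len(nrow(ko_df)), function(i)
                         random_protein(60), ""),
                       stringsAsFactors = FALSE)

  bundle <- structure(list(reactions = rxn_df, metabolites = met_df,
                           enzymes = enz_df, pathways = pwy_df,
                           sequences = seq_df, rxn_xref = rxn_xref,
                           met_xref = met_xref), class = "database_bundle")
  sh_pwy <- pwy_df
  sh_pwy$reactions <- vapply(strsplit(sh_pwy$reactions, ";"), function(v)
    paste(rename(v), collapse = ";"), "")
  shadow <- structure(list(reactions = sh_rxn, metabolites = sh_met,
                           enzymes = ko_df, pathways = sh_pwy,
                           sequences = ko_seq, rxn_xref = NULL,
                           met_xref = NULL), class = "database_bundle")
  validate_bundle(bundle); validate_bundle(shadow)

  enz_truth <- do.call(rbind, truth_rows)
  n_plant <- round(spec$planted_fraction * nrow(enz_truth))
  planted <- sort(sample(enz_truth$enzyme, n_plant))
  structure(list(bundle = bundle, shadow = shadow,
                 truth = list(
                   enzyme_reactions = enz_truth,
                   planted_enzymes = planted,
                   planted_reactions =
                     sort(unique(enz_truth$reaction[enz_truth$enzyme %in% planted])),
                   withheld_xrefs = withheld,
                   spontaneous = spont_ids,
                   transport = transport_ids,
                   ko_table = data.frame(ko = ko_df$id,
                                         shadow_rxn = ko_df$reactions,
                                         a_rxn = substring(ko_df$reactions, 2),
                                         stringsAsFactors = FALSE))),
            class = "fixture_bundle")
})

mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(chars)) < rate
  chars[hit] <- vapply(chars[hit], function(ch)
    sample(setdiff(AA20, ch), 1), "")
  paste(chars, collapse = "")
}

#' Generate a query proteome with planted orthologs and its hit table
#'
#' Planted queries are (optionally mutated) copies of the sequences of the
#' planted enzymes/subunits; decoy queries are short random sequences. The
#' hit table is computed with the internal global aligner using the
#' bit-score proxy 2 x matches and percent positives = percent identity, so
#' decoy hits fall below the (100 bit, 45%) cut-offs by construction.
#'
#' @param fx a `fixture_bundle` from [generate_bundle()].
#' @param spec the same [fixture_spec()].
#' @return list: `proteome` (data.frame `id`, `sequence`), `hits`
#'   (alignment-hit data.frame), `gene_of_subject` (named vector
#'   subject id -> planted query id).
#' @export
generate_proteome_and_hits <- function(fx, spec) with_seed(spec$seed + 1L, {
  enz <- fx$bundle$enzymes
  seqs <- setNames(fx$bundle$sequences$sequence, fx$bundle$sequences$id)
  prot <- list(); hit_rows <- list(); gene_of <- character()
  for (eid in fx$truth$planted_enzymes) {
    i <- match(eid, enz$id)
    subjects <- split_list(enz$subunits[i])[[1]]
    if (!length(subjects)) subjects <- eid
    for (su in subjects) {
      q <- paste0("q_", su)
      qseq <- mutate_sequence(seqs[[su]], spec$noise)
      prot[[q]] <- qseq
      gene_of[su] <- q
      idy <- sequence_identity(qseq, seqs[[su]])
      ncol_aln <- max(nchar(qseq), nchar(seqs[[su]]))
      matches <- round(idy * ncol_aln)
      hit_rows[[length(hit_rows) + 1L]] <- data.frame(
        query_id = q, subject_id = su, evalue = 2^-(2 * matches),
        bit_score = 2 * matches, percent_positives = 100 * idy,
        percent_identity = 100 * idy, aln_length = ncol_aln,
        stringsAsFactors = FALSE)
    }
  }
  decoy_enz <- grep("^DEC", enz$id, value = TRUE)
  for (j in seq_along(decoy_enz)) {
    q <- sprintf("qdec%02d", j)
    qseq <- random_protein(35)
    prot[[q]] <- qseq
    su <- decoy_enz[j]
    idy <- sequence_identity(qseq, seqs[[su]])
    ncol_aln <- max(nchar(qseq), nchar(seqs[[su]]))
    matches <- round(idy * ncol_aln)
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = q, subject_id = su, evalue = 2^-(2 * matches),
      bit_score = 2 * matches, percent_positives = 100 * idy,
      percent_identity = 100 * idy, aln_length = ncol_aln,
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)
  if (is.null(hits))
    hits <- data.frame(query_id = character(), subject_id = character(),
                       evalue = numeric(), bit_score = numeric(),
                       percent_positives = numeric(),
                       percent_identity = numeric(), aln_length = integer(),
                       stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(proteome = data.frame(id = names(prot),
                             sequence = unlist(prot),
                             stringsAsFactors = FALSE, row.names = NULL),
       hits = hits, gene_of_subject = gene_of)
})

#' Generate KO annotation and HMM score tables for the fixture
#'
#' Splits the planted queries between the two KO evidence routes: the first
#' half get curated annotation rows, the second half high HMM bit scores
#' (500); unplanted chain enzymes contribute a few annotation-only genes
#' (KO-unique content) and decoys get sub-threshold scores (50).
#'
#' @param fx a `fixture_bundle`.
#' @param ph result of [generate_proteome_and_hits()].
#' @param spec the [fixture_spec()].
#' @return list: `annotation` (data.frame `gene`, `ko`), `hmm_scores`
#'   (data.frame `gene`, `ko`, `score`), `ko_truth` (KO -> expected shadow
#'   reactions for the assigned genes).
#' @export
generate_ko_tables <- function(fx, ph, spec) with_seed(spec$seed + 2L, {
  kt <- fx$truth$ko_table
  enzt <- fx$truth$enzyme_reactions
  planted <- fx$truth$planted_enzymes
  # KO of a chain reaction catalyzed by a planted enzyme
  planted_rxns <- enzt$reaction[enzt$enzyme %in% planted]
  kt_planted <- kt[kt$a_rxn %in% planted_rxns, , drop = FALSE]
  gene_for_rxn <- function(r) {
    eid <- enzt$enzyme[match(r, enzt$reaction)]
    subs <- split_list(fx$bundle$enzymes$subunits[
      match(eid, fx$bundle$enzymes$id)])[[1]]
    paste0("q_", if (length(subs)) subs[1] else eid)
  }
  if (nrow(kt_planted)) {
    genes <- vapply(kt_planted$a_rxn, gene_for_rxn, "")
    half <- seq_len(ceiling(nrow(kt_planted) / 2))
    ann <- data.frame(gene = genes[half], ko = kt_planted$ko[half],
                      stringsAsFactors = FALSE)
    rest <- setdiff(seq_len(nrow(kt_planted)), half)
    hmm <- data.frame(gene = genes[rest], ko = kt_planted$ko[rest],
                      score = 500, stringsAsFactors = FALSE)
  } else {
    ann <- data.frame(gene = character(), ko = character(),
                      stringsAsFactors = FALSE)
    hmm <- data.frame(gene = character(), ko = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  # KO-unique content: annotate up to 2 unplanted chain reactions
  unplanted <- kt[!kt$a_rxn %in% planted_rxns &
                  grepl("^R[0-9]+_", kt$a_rxn), , drop = FALSE]
  if (nrow(unplanted)) {
    take <- utils::head(seq_len(nrow(unplanted)), 2)
    ann <- rbind(ann, data.frame(gene = paste0("gko_", unplanted$a_rxn[take]),
                                 ko = unplanted$ko[take],
                                 stringsAsFactors = FALSE))
  }
  # sub-threshold decoy scores
  if (nrow(kt))
    hmm <- rbind(hmm, data.frame(gene = "qdec01",
                                 ko = kt$ko[nrow(kt)], score = 50,
                                 stringsAsFactors = FALSE))
  rownames(ann) <- rownames(hmm) <- NULL
  list(annotation = ann, hmm_scores = hmm,
       ko_truth = kt[kt$ko %in% c(ann$ko, hmm$ko[hmm$score >= 100]), ,
                     drop = FALSE])
})

#' Write a database bundle to a directory
#' @param bundle a `database_bundle`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wr(bundle$reactions, "reactions.tsv")
  wr(bundle$metabolites, "metabolites.tsv")
  wr(bundle$enzymes, "enzymes.tsv")
  wr(bundle$pathways, "pathways.tsv")
  write_fasta(bundle$sequences, file.path(dir, "protseq.fsa"))
  if (!is.null(bundle$rxn_xref)) wr(bundle$rxn_xref, "rxn_xref.tsv")
  if (!is.null(bundle$met_xref)) wr(bundle$met_xref, "met_xref.tsv")
  invisible(dir)
}

#' Named toy models with documented optima and truth sets
#'
#' * `toy_chain` — linear uptake-to-biomass chain; FBA optimum equals the
#'   uptake bound (10).
#' * `toy_branch` — branch point between a biomass precursor and a product
#'   `P`; the FSEOF targets are exactly the product branch
#'   (`RP`, `EX_P`).
#' * `toy_gapped` — chain with reaction `R2` removed; growth requires gap
#'   filling from `toy_gapped_universal` (which also offers the irrelevant
#'   `R9`).
#' * `toy_leaky` — chain plus the imbalanced duplication `BAD: B -> 2 B`;
#'   `B_c` is leaky under closed exchanges.
#' * `toy_gpr` — branched chain with isozymes, a complex and a
#'   reduced-capacity backup path; deleting `g2` leaves exactly 25% of
#'   wild-type growth (ratio 0.25, non-essential under the strict rule) and
#'   only `g1` is essential.
#'
#' @return named list of `metabolic_model`s (plus `toy_gapped_universal`).
#' @export
toy_models <- function() {
  chain <- function(id) {
    m <- new_model(id)
    m <- add_metabolite(m, "A_e", "A", "e", db_id = "A", formula = "C1")
    m <- add_metabolite(m, "A_c", "A", "c", db_id = "A", formula = "C1")
    m <- add_metabolite(m, "B_c", "B", "c", db_id = "B", formula = "C1")
    m <- add_reaction(m, "EX_A", c(A_e = -1), lb = -10, ub = 1000,
                      exchange = TRUE)
    m <- add_reaction(m, "T_A", c(A_e = -1, A_c = 1), transport = TRUE)
    m <- add_reaction(m, "R1", c(A_c = -1, B_c = 1))
    m <- add_reaction(m, "GROWTH", c(B_c = -1), exchange = TRUE)
    set_objective(m, "GROWTH")
  }
  toy_chain <- chain("toy_chain")

  toy_branch <- new_model("toy_branch")
  for (spec in list(c("A_e", "e"), c("A_c", "c"), c("B_c", "c"),
                    c("BM_c", "c"), c("P_c", "c")))
    toy_branch <- add_metabolite(toy_branch, spec[1],
                                 sub("_.$", "", spec[1]), spec[2],
                                 db_id = sub("_.$", "", spec[1]),
                                 formula = "C1")
  toy_branch <- add_reaction(toy_branch, "EX_A", c(A_e = -1), lb = -10,
                             ub = 1000, exchange = TRUE)
  toy_branch <- add_reaction(toy_branch, "T_A", c(A_e = -1, A_c = 1),
                             transport = TRUE)
  toy_branch <- add_reaction(toy_branch, "R1", c(A_c = -1, B_c = 1))
  toy_branch <- add_reaction(toy_branch, "RB", c(B_c = -1, BM_c = 1))
  toy_branch <- add_reaction(toy_branch, "GROWTH", c(BM_c = -1),
                             exchange = TRUE)
  toy_branch <- add_reaction(toy_branch, "RP", c(B_c = -1, P_c = 1))
  toy_branch <- add_reaction(toy_branch, "EX_P", c(P_c = -1),
                             exchange = TRUE)
  toy_branch <- set_objective(toy_branch, "GROWTH")

  toy_gapped <- new_model("toy_gapped")
  for (spec in list(c("A_e", "e"), c("A_c", "c"), c("B_c", "c"),
                    c("C_c", "c")))
    toy_gapped <- add_metabolite(toy_gapped, spec[1],
                                 sub("_.$", "", spec[1]), spec[2],
                                 formula = "C1")
  toy_gapped <- add_reaction(toy_gapped, "EX_A", c(A_e = -1), lb = -10,
                             ub = 1000, exchange = TRUE)
  toy_gapped <- add_reaction(toy_gapped, "T_A", c(A_e = -1, A_c = 1))
  toy_gapped <- add_reaction(toy_gapped, "R1", c(A_c = -1, B_c = 1))
  # R2 (B -> C) is the planted gap
  toy_gapped <- add_reaction(toy_gapped, "GROWTH", c(C_c = -1),
                             exchange = TRUE)
  toy_gapped <- set_objective(toy_gapped, "GROWTH")

  toy_gapped_universal <- new_model("toy_gapped_universal")
  for (spec in list(c("B_c", "c"), c("C_c", "c"), c("D_c", "c"),
                    c("E_c", "c")))
    toy_gapped_universal <- add_metabolite(toy_gapped_universal, spec[1],
                                           sub("_.$", "", spec[1]), spec[2],
                                           formula = "C1")
  toy_gapped_universal <- add_reaction(toy_gapped_universal, "R2",
                                       c(B_c = -1, C_c = 1))
  toy_gapped_universal <- add_reaction(toy_gapped_universal, "R9",
                                       c(D_c = -1, E_c = 1))

  toy_leaky <- chain("toy_leaky")
  # imbalanced duplication B -> 2 B; net stoichiometry +1 B
  toy_leaky <- add_reaction(toy_leaky, "BAD", c(B_c = 1))

  toy_gpr <- new_model("toy_gpr")
  for (spec in list(c("A_e", "e"), c("A_c", "c"), c("B_c", "c"),
                    c("C_c", "c"), c("BM_c", "c")))
    toy_gpr <- add_metabolite(toy_gpr, spec[1], sub("_.$", "", spec[1]),
                              spec[2], formula = "C1")
  toy_gpr <- add_reaction(toy_gpr, "EX_A", c(A_e = -1), lb = -10, ub = 1000,
                          exchange = TRUE)
  toy_gpr <- add_reaction(toy_gpr, "T_A", c(A_e = -1, A_c = 1),
                          gene_rule = "g1")
  toy_gpr <- add_reaction(toy_gpr, "R1", c(A_c = -1, B_c = 1),
                          gene_rule = "g2")
  toy_gpr <- add_reaction(toy_gpr, "R1b", c(A_c = -1, B_c = 1), ub = 2.5,
                          gene_rule = "g10")
  toy_gpr <- add_reaction(toy_gpr, "R2", c(B_c = -1, C_c = 1),
                          gene_rule = "g4 and g5")
  toy_gpr <- add_reaction(toy_gpr, "R3", c(B_c = -1, C_c = 1),
                          gene_rule = "g6")
  toy_gpr <- add_reaction(toy_gpr, "R4", c(C_c = -1, BM_c = 1),
                          gene_rule = "(g7 and g8) or g9")
  toy_gpr <- add_reaction(toy_gpr, "GROWTH", c(BM_c = -1), exchange = TRUE)
  toy_gpr <- set_objective(toy_gpr, "GROWTH")

  list(toy_chain = toy_chain, toy_branch = toy_branch,
       toy_gapped = toy_gapped, toy_gapped_universal = toy_gapped_universal,
       toy_leaky = toy_leaky, toy_gpr = toy_gpr)
}
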