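# Random model and network generators for property tests.

rand_model <- function(seed) {
  set.seed(seed)
  m <- new_model(sprintf("rand%d", seed), "random test model")
  nmet <- sample(3:7, 1)
  comps <- c("c", "e")
  for (i in seq_len(nmet))
    m <- add_metabolite(m, sprintf("m%02d_%s", i, comps[1 + (i %% 2)]),
                        name = sprintf("met %d", i),
                        comp = comps[1 + (i %% 2)],
                        db_id = if (stats::runif(1) < 0.5)
                          sprintf("m%02d", i) else NA_character_,
                        formula = if (stats::runif(1) < 0.5)
                          sprintf("C%dH%d", i, 2 * i) else NA_character_,
                        charge = if (stats::runif(1) < 0.5)
                          sample(-2:2, 1) else NA_real_,
                        xrefs = if (stats::runif(1) < 0.5)
                          list(kegg = sprintf("C%05d", i)) else list())
  nrxn <- sample(2:7, 1)
  genes <- sprintf("g%d", 1:6)
  for (j in seq_len(nrxn)) {
    k <- sample(nmet, sample(1:min(3, nmet), 1))
    s <- setNames(round(stats::runif(length(k), -3, 3), 2), m$mets$id[k])
    s <- s[s != 0]
    if (!length(s)) s <- setNames(1, m$mets$id[k[1]])
    bb <- sample(list(c(-1000, 1000), c(0, 1000), c(-5, 10)), 1)[[1]]
    rule <- if (stats::runif(1) < 0.6) {
      ts <- replicate(sample(1:2, 1),
                      paste(sample(genes, sample(1:2, 1)),
                            collapse = " and "))
      paste(sprintf("(%s)", ts), collapse = " or ")
    } else NULL
    m <- add_reaction(m, sprintf("r%02d", j), s,
                      name = sprintf("reaction %d", j),
                      lb = bb[1], ub = bb[2], gene_rule = rule,
                      subsystem = if (stats::runif(1) < 0.5)
                        sample(c("glycolysis", "TCA cycle"), 1) else
                          NA_character_,
                      ec = if (stats::runif(1) < 0.3)
                        sprintf("%d.1.1.%d", j, j) else character(),
                      xrefs = if (stats::runif(1) < 0.4)
                        list(metacyc = sprintf("RXN-%d", j)) else list(),
                      spontaneous = stats::runif(1) < 0.1,
                      transport = stats::runif(1) < 0.1,
                      exchange = stats::runif(1) < 0.2)
  }
  set_objective(m, m$rxns$id[1])
}

# small random flux network with an uptake, internal conversions and a sink
rand_network <- function(seed, max_rxns = 6) {
  set.seed(seed)
  nm <- sample(2:4, 1)
  nr <- sample(3:max_rxns, 1)
  mets <- sprintf("x%d_c", seq_len(nm))
  m <- new_model(sprintf("net%d", seed))
  for (mm in mets) m <- add_metabolite(m, mm, mm, "c")
  m <- add_reaction(m, "up", setNames(1, mets[1]), lb = 0,
                    ub = sample(5:15, 1))
  for (j in seq_len(nr - 2)) {
    from <- sample(nm, 1); to <- sample(setdiff(seq_len(nm), from), 1)
    coef <- sample(c(1, 1, 2), 1)
    rev <- stats::runif(1) < 0.4
    m <- add_reaction(m, sprintf("v%d", j),
                      setNames(c(-1, coef), c(mets[from], mets[to])),
                      lb = if (rev) -1000 else 0, ub = 1000)
  }
  m <- add_reaction(m, "sink", setNames(-1, mets[nm]), lb = 0, ub = 1000)
  set_objective(m, "sink")
}
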