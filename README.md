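# gemforge

Constraint-based metabolic modelling toolbox for R: semi-automated
reconstruction of genome-scale metabolic models (GEMs) from pathway-database
content and protein homology, curation utilities, and simulation by flux
balance analysis.

A GEM is a stoichiometric network `S` (metabolites x reactions) with flux
bounds `lb <= v <= ub` and boolean gene–protein–reaction (GPR) rules. The
core analyses solve linear programs of the form

```
max  c'v   s.t.   S v = 0,   lb <= v <= ub
```

(flux balance analysis, FBA), plus derived procedures: flux-variability gap
analysis, minimal-cardinality MILP gap filling, single-gene essentiality
(knockout ratio strictly below 0.25 of wild-type growth = essential, i.e.
more than 75% reduction), growth screening over nutrient sources, and flux
scanning with enforced objective function (FSEOF) for overproduction target
discovery.

Reconstruction follows three complementary routes:

1. **Template homology** — bidirectional best BLASTP hits map template genes
   onto query genes; template GPR rules are rewritten through the ortholog
   map (`bidirectional_best_hits`, `reconstruct_from_template`).
2. **Database homology** — enzymes of a pathway-database bundle
   (MetaCyc-style TSV/FASTA directory) are supported when an alignment hit
   passes bit score >= 100 and percent positives >= 45; their reactions,
   including curated transport reactions, form the draft
   (`build_universal_model`, `reconstruct_from_database`,
   `add_spontaneous_reactions`).
3. **KEGG Orthology** — KO assignments from curated annotation or HMM
   bit-score tables select reactions through the KO-reaction map
   (`assign_kos_from_annotation`, `assign_kos_from_hmm_scores`,
   `reconstruct_from_kos`), with the CD-HIT-style cluster/align/hmmbuild
   training pipeline behind a pluggable runner.

Drafts are merged (`merge_models`) and unified across database namespaces by
explicit cross-references plus proton-blind reactant matching
(`link_cross_db_reactions`, `combine_models`). Models are read and written
as SBML L3V1 FBC v2, canonical diff-friendly YAML, and tab-separated flat
text.

## Worked example

```r
library(gemforge)

tm <- toy_models()
fba(tm$toy_chain)
#> <flux_distribution> status=optimal objective=10

# the chain is gapped: gap filling picks the one missing reaction
gap_fill(tm$toy_gapped, tm$toy_gapped_universal, min_objective = 1)
#> [1] "R2"

# essentiality under the strict >75%-reduction rule
single_gene_deletion(tm$toy_gpr)
#>   gene wt_growth ko_growth ratio essential
#> 1   g1        10       0.0  0.00      TRUE
#> 2  g10        10      10.0  1.00     FALSE
#> 3   g2        10       2.5  0.25     FALSE
#> ...

# FSEOF on a branched network flags exactly the product branch
fseof(tm$toy_branch, "GROWTH", "EX_P")
#> <fseof_result> 10 levels, 2 targets: RP, EX_P
```

An end-to-end reconstruction on synthetic inputs (database bundle, shadow
namespace, planted proteome):

```r
res <- run_pipeline(run_config(seed = 1))
res$log
#>                 stage reactions metabolites genes ...
#> 1            recon-db        16          24    20
#> 2 recon-ko-annotation        10          16    10
#> ...
#> 6         spontaneous        19          27    22
```

The same stages are scriptable from a shell via
`Rscript inst/cli/gemforge.R <subcommand>` (subcommands `fixtures`,
`recon-db`, `recon-ko`, `recon-template`, `merge`, `combine`, `spontaneous`,
`gapreport`, `gapfill`, `fba`, `essentiality`, `growth-screen`, `fseof`,
`convert`, `pipeline`).

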