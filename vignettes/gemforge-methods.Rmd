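---
title: "Models and methods in gemforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gemforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemforge)
```

# The model

A genome-scale metabolic model (GEM) in gemforge is a stoichiometric matrix
`S` over metabolites and reactions, flux bounds in mmol/gDW/h, and boolean
gene–protein–reaction (GPR) rules. Two representation choices differ from
the common MATLAB-toolbox layout and are deliberate:

* **Reversibility is derived, never stored.** A reaction is reversible iff
  `lb < 0 & ub > 0`. Storing a separate flag invites inconsistency between
  flag and bounds; every consumer here (FBA, gap analysis, FSEOF direction
  codes, flat-text arrows) derives it from the same place. Database
  reactions get the conventional big-M caps: `[-1000, 1000]` reversible,
  `[0, 1000]` irreversible.
* **GPR rules are canonical DNF.** A rule is a sorted list of sorted AND
  terms: OR terms are isozymes, genes within a term complex subunits. The
  original string is kept alongside for provenance. The payoff is that the
  operations that actually consume rules — essentiality evaluation,
  OR-merging during model combination, ortholog rewriting — become set
  operations; equivalence of parsed and original rules is property-tested
  against truth-table enumeration.

Stoichiometric coefficients are doubles with a fixed canonical
serialization (10 significant digits, trailing zeros trimmed). That policy,
not exact rational arithmetic, is what delivers the contract that matters
here: writing the same model twice — or after any permutation of element
order — produces byte-identical YAML, and coefficients like 1/3 survive a
round trip to within 1e-9.

# Serialization

SBML L3V1 with the FBC v2 package is the interchange format: bounds as
shared parameters, GPRs as `fbc:or`/`fbc:and` association trees, the
objective as the active FBC objective, and cross references as
identifiers.org URIs inside an RDF annotation. YAML is the canonical
format: all collections sorted by id, fixed scalar formatting, so
byte-identical files correspond exactly to semantically equal models —
which is what makes model changes reviewable as plain diffs under version
control. Flat text serializes one reaction per line
(`2 A[c] <=> B[c]`-style equations) for quick inspection.

# Reconstruction routes

**Template homology.** Bidirectional best hits (BBH) between query and
template proteomes: the best hit is the highest bit score, ties broken by
lower e-value and then lexicographically smaller subject id, so results
never depend on input order. Multiple HSPs per pair collapse to the best
one. Template GPRs are rewritten through the ortholog map; an AND term
survives only if *every* subunit is mapped — a partial complex is dropped
rather than invented. Reactions whose rewritten rule is empty are excluded
(reactions without rules only on request). Defaults (bit >= 100,
e <= 1e-30) are user-overridable; they are this package's own choice of a
conservative orthology proxy.

**Database homology.** An enzyme of the universal database model is
supported when one alignment hit passes *both* cut-offs on the same HSP:
bit score >= 100 and percent positives >= 45 (the `ppos` column of the
alignment table; the denominator is alignment columns of that HSP). For
complexes, at least one supported subunit suffices to include the enzyme
(permissive draft building), and the AND term contains the best-matching
query per matched subunit; single-sequence enzymes contribute one
single-gene OR term per matching query. Drafts live in a single cytosolic
compartment `c`, with transport reactions spanning `e`/`c`; sub-cellular
localization is out of scope. Spontaneous reactions carry no enzyme
association, so homology can never recover them; they are added afterwards
iff all substrates of at least one direction (both directions for
reversible reactions) are already present — the addition is idempotent and
never creates an island.

**KEGG Orthology.** KO assignments come from curated annotation (score
`Inf`) or HMM bit-score tables filtered at `min_score` (default 100 bits —
the upstream method publishes no threshold, so this is an explicit,
overridable package default). A reaction enters the draft iff any of its
KOs is assigned; its rule is the OR of all assigned genes. The training-set
pipeline (cluster at 100/90/50% redundancy, align, build HMM) implements
greedy longest-first clustering internally — identity is
Needleman–Wunsch with match 1, mismatch 0, linear gap −1, matches over
alignment columns — and delegates the align/build stages to a runner
contract so external MAFFT/HMMER binaries or deterministic stubs can fill
them. Exact CD-HIT equivalence is not claimed; the clustering invariants
(exact-duplicate partition at 100%, monotone cluster counts) are tested.

# Cross-database combination

Linking two namespaces is two-staged: explicit reaction cross-references
first, then reactant matching for everything still unmapped — metabolites
are translated through the metabolite cross-reference table and
substrate/product multisets are compared with coefficients,
direction-agnostically, ignoring proton-class metabolites (databases
disagree systematically about explicit protons). Matching is
coefficient-strict by choice: a looser set-only comparison would conflate
stoichiometric variants. Ambiguous candidates (two or more equal A-side
reactions) are never auto-assigned; they are reported for curation, since a
silent misassignment is strictly worse than an unmapped reaction. In the
combined model the A namespace wins all conflicts: mapped B reactions are
discarded with their gene rules OR-merged into the A copy, unmapped B
reactions are translated metabolite-by-metabolite (untranslatable ones stay
in the B namespace, flagged foreign), and the reaction count obeys
`|A| + |B| − |mapped| − |duplicates|` as an accounting identity.

# Simulation

All analyses reduce to bounded LPs. No LP package suitable for degenerate
stoichiometric systems is available to this package, so the solver is an
internal dense two-phase primal simplex with Bland's anti-cycling rule —
the model sizes involved (tens to a few hundred columns) make robustness,
not speed, the binding constraint. The flux tolerance is 1e-6 everywhere.
FBA correctness is property-tested against brute-force vertex enumeration
on random networks.

* **Gap analysis** reports dead-end metabolites (reversibility-aware
  stoichiometric scan), blocked reactions (flux variability), leaky
  metabolites (producible with all exchange uptakes closed — a temporary
  sink per metabolite, positive optimum means some reaction creates mass),
  the mirrored consumable-from-nothing test (exchange outputs closed,
  temporary source), and bipartite connected components.
* **Gap filling** is a minimal-cardinality MILP: binary `y_j` per candidate
  with `−M y_j <= v_j <= M y_j` (M = 1000), minimize `Σ y_j` subject to the
  objective reaching its floor. Solved by LP-relaxation branch-and-bound;
  minimality is tested against exhaustive subset search.
* **Essentiality** evaluates each DNF rule under the deletion; a false rule
  closes the reaction to `[0, 0]`, reactions without rules are untouched. A
  gene is essential when growth drops by more than 75% — the ratio test is
  strict (`< 0.25`) with a 1e-9 guard so LP round-off cannot flip a
  knockout sitting exactly on the boundary.
* **Growth screening** opens one variable nutrient exchange at a time
  (lower bound `−uptake_bound`, default 10) on top of the model's fixed
  minimal-medium exchange bounds; growth means objective > 1e-6.
  Sensitivity and specificity are scored against observed labels. The
  minimal medium is the model's own exchange state, passed in rather than
  hard-coded.
* **FSEOF** enforces product flux stepwise from its wild-type level toward
  90% of its theoretical maximum over 10 levels (both user-settable),
  maximizing biomass at each level. Because biomass optima are routinely
  degenerate, a secondary minimization of total absolute flux (split
  variables) pins each level to a unique parsimonious distribution —
  without it, target calls would depend on solver pivoting. A reaction is a
  target iff its absolute flux is non-decreasing across levels (tolerance
  1e-6), strictly higher at the last level, with constant sign. Direction
  codes: 0 for irreversible reactions, otherwise the sign of the carried
  flux (forward 1, reverse −1; a reversible reaction that never carries
  flux defaults to forward).

# Synthetic fixtures

The generators emulate the *inputs* of database-driven reconstruction so
that every stage is testable without licensed database content. A fixture
is a pure function of its spec (seed included): pathways are linear chains
of isomerase-like reactions sharing one elemental formula per chain — so
every internal reaction is mass-balanced by construction and the leak test
must stay silent; spontaneous condensations sum formulas; transporters move
chain heads from `e` to `c`. A shadow namespace (ids prefixed `K`) models a
second database: 25% of reaction cross-references are withheld and those
reactions gain an extra proton on the product side, exactly the situation
stage-2 reactant matching exists for. The planted proteome copies enzyme
sequences (optionally mutated at a substitution rate), and the hit table
uses a bit-score proxy of 2 × matches with percent positives = percent
identity: monotone in alignment quality, and decoy queries are 35 aa long
so even a perfect decoy alignment (70 bits) stays below the 100-bit
cut-off by construction. Default condition sizes — 6 pathways × 4
reactions, 5 decoys, planted fraction 0.6, noise 0 — keep each pipeline run
in seconds while leaving every code path (complexes, isozymes, transport,
spontaneous, withheld xrefs, foreign metabolites) exercised.

What passing these tests shows — and does not. Perfect precision/recall on
noiseless planted fixtures validates the *selection logic* (thresholds,
subunit handling, KO closure), not alignment sensitivity on real proteomes;
real BLAST scores, paralogy and promiscuous domains will behave worse. The
synthetic bundles have none of the irregularities of real database exports
(missing fields, nonstandard compartments tags, inconsistent proton
conventions beyond the one modelled), so parsers are validated for the
documented contract only.

# Numerical choices and degenerate inputs

LP feasibility/pivot tolerances are 1e-9 with a 1e-6 flux tolerance at the
interfaces; all variables are boxed, so unbounded statuses cannot arise in
normal use. Empty rule strings mean "no gene association" (`NULL`), never
an empty DNF; an empty AND term is an error. Exchange reactions may have an
empty side in flat text (`A[e] <=>`). Zero stoichiometric coefficients are
dropped on entry. Reaction/metabolite ids pass through SBML via a
reversible escape of non-SId characters. Single-sequence KOs skip the
alignment stage and are flagged rather than failing the training pipeline.

# Known limitations

The simplex is dense and pure R: adequate up to a few hundred reactions,
not for eukaryote-scale models with tens of thousands of columns. Gap
filling's branch-and-bound is exact but exponential in the worst case;
candidate pools beyond a few dozen reactions deserve a dedicated MILP
solver. Metabolite matching relies on curated cross-references plus
coefficient-strict reactant identity — no name-based fuzzy matching.
Sub-cellular localization, solution-space sampling and tissue-specific
model extraction are out of scope.
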