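---
title: "Building and using a substrate-based SLC ontology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and using a substrate-based SLC ontology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slcsub)
```

## Why a substrate ontology

Curated substrate annotations of solute carriers are free text: "glycine",
"L-serine", "Na+". Such names rarely recur across transporters, so a gene
set of upregulated SLCs has almost nothing in common at the level of raw
names, and no enrichment statistic can get traction. A chemical ontology
such as ChEBI fixes this: once each cargo name is an ontology term, every
transporter inherits all the more general terms above it ("amino acid",
"monocarboxylate", "cation"), and those shared ancestors are exactly what
set-level statistics need. The cost is that a general-purpose chemical
ontology is far too large and too finely graded; most of its specificity
distinguishes nothing among a few hundred transporters. This package
therefore *reduces* the ontology to the part that matters for SLC cargo and
then uses it for enrichment and for orphan-substrate prediction.

## The data model

An `slc_annotation` is one row per transporter: gene symbol, family,
substrate and coupled-ion name lists, transport mechanism (symporter /
antiporter / uniporter / unknown), exactly one of eleven substrate classes,
and a localization set. A transporter is an *orphan* when it has neither
substrates nor coupled ions; the two accessory-protein records are orphans
by this definition while keeping their own class, and a record with cargo
may never be classed "orphan" — the loader enforces both directions.
Empty cells, `NA` and `unknown` all decode to "unknown" because
supplementary-table dialects differ.

Distinct cargo names are counted by case-insensitive exact match after
trimming, with no chemical normalization: the curated table is the source
of truth for names, and unification is the mapping step's job.

An `ontology_graph` is a typed directed multigraph. The direction
convention is uniformly *specific to general*: `child -> parent` for
`is_a`, `entity -> role` for `has_role`, `SLC -> chemical term` for
`transports`. Under this convention "one incoming edge" and "one sub-term"
coincide, which is how the pruning rule is phrased below; incoming edges
are counted as *distinct child terms*, so parallel `is_a`/`has_role` edges
from the same child count once.

## Ontology construction, step by step

1. **Parse** the OBO file. Only the five relationship types above are kept;
   everything else (`has_part`, ...) is ignored, and obsolete terms are
   skipped. Role terms are recognised structurally — a term is in the role
   sub-ontology iff its `is_a` ancestry reaches a term labelled "role" —
   rather than by a hard-coded identifier, so toy ontologies behave like
   the real one.
2. **Map** cargo names to terms: exact case-insensitive match against
   labels and exact synonyms first, then an offline curated mapping table.
   The live lookup services a curator would use online are deliberately
   replaced by this file-based tier: runs are reproducible with no network.
   Ambiguous names return all matching terms; unresolved names are
   collected and reported, never dropped silently.
3. **Extract** all terms reachable from the mapped substrate terms. The
   subatomic-particle branch (again found by label-anchored ancestor
   search) is excluded, except that a substrate node itself is never
   excluded — substrate nodes are inviolable throughout the reduction.
4. **Merge cycles.** Tautomer and conjugate acid/base relations are
   circular by design, so the strongly connected components of the graph
   restricted to those relations are contracted. The merged id is the
   lexicographically smallest member id (deterministic and diff-stable);
   members are retained and serialized as `alt_id`s. The result must be a
   DAG — a residual cycle is an integrity error, not a warning.
5. **Prune single-child terms.** A non-substrate term with exactly one
   sub-term is an extra level of specificity that cannot distinguish
   between instances of its branch. It is removed and its single child is
   reconnected to each of its parents with a `derived` edge (unless an edge
   already exists), preserving pairwise reachability among survivors
   exactly. Removals can expose new single-child terms, so the rule is
   iterated to a fixpoint, children before parents in topological order;
   fixpoint iteration is the only order-independent reading of the rule,
   though it can remove more terms than a single pass would.
6. **Attach transporters** via `transports` edges from one node per
   cargo-bearing SLC to the (possibly merged) term of each mapped cargo.
   Orphans get no node by default (`keep_orphans` exists for
   visualization). A transporter's annotation closure is everything
   reachable from its node.

Every step is deterministic; the whole module has no random component.

## Enrichment

Upregulated transporters are those with `log2fc > 0.5` and `fdr < 0.05`
(strict inequalities, both configurable). The test universe is the set of
cargo-bearing transporters with at least one ontology term — orphans carry
no terms, so including them would only inflate the "unannotated,
not-upregulated" cell of every table by the same constant; a flag restores
the all-SLC universe for sensitivity analysis. Testable terms are
chemical-entity terms annotated to at least 5 but fewer than 70% of the
universe: below 5 the test is hopeless, above 70% the term is uninformative
(and role terms describe function, not cargo). The p-value is the one-sided
over-representation tail `P[X >= a]` of the hypergeometric distribution;
Benjamini–Hochberg runs per condition across the tested terms. Finally,
significant terms with a significant descendant are unflagged, so the
reported set is an antichain of most-specific terms — "L-methionine"
suppresses "sulfur-containing amino acid" when both are enriched.

## Substrate classifiers

Each protein is summarized by 93 features over the four topological domain
kinds (cytoplasmic, non-cytoplasmic, transmembrane, signal peptide; residues
pooled across same-kind segments): 20 amino-acid frequencies, segment
count, residue count and mean segment length per kind, plus the
N-glycosylation sequon count (`N-[^P]-[S/T]`, overlapping matches, scanned
per segment) in the non-cytoplasmic domain, where glycosylation happens.
This feature scheme is a deliberate reduction of richer published
sequence-feature catalogs to a self-contained core; user-supplied motif
features can be appended to the matrix, and absolute per-protein scores
should not be expected to match pipelines with other feature sets.

Per target term, positives are transporters whose closure contains the
term, negatives the remaining cargo-bearing transporters; accessory
proteins and proteins without usable topology are excluded before training.
Classes with fewer than 10 members on either side are skipped with an
explicit report rather than trained badly. The forest grid covers `mtry`
{20, 50, 100, 150, 200} (clamped to the feature count), `ntree` {300, 700,
1100, 1500} and class weights (unweighted or class priors) — even coverage
of the tuned ranges. Selection maximizes F1 computed from out-of-bag votes
at the 0.5 cutoff (computing it at the per-cell optimized threshold is
available via `f1_cutoff`); ties resolve toward smaller `ntree`, then
smaller `mtry`, then unweighted. Out-of-bag estimates serve as the only
validation signal — grid choice, threshold choice and the reported
AUROC/AUPRC all derive from them, which avoids a validation split on a few
hundred proteins but also means the reported metrics are mildly optimistic,
as all-OOB protocols are.

The decision threshold maximizes recall subject to precision ≥ 0.75 (ties:
higher precision, then higher threshold; if the floor is unreachable the
precision-maximizing threshold is used and flagged). Because out-of-bag
vote fractions can be exactly 0 or 1, candidate thresholds are clamped to
`[1e-6, 1 - 1e-6]`, keeping the gamma exponent `ln 0.5 / ln t` finite.
Gamma normalization `s^(ln 0.5 / ln t)` then relocates every classifier's
threshold to 0.5, so scores are comparable across terms and a "call" is
simply normalized score ≥ 0.5.

Determinism: the RNG is re-seeded with the caller's seed before every grid
cell, so a fixed seed and grid reproduce the classifier exactly, including
its serialized JSON.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with ground truth
strong enough to compute expected outcomes without re-derivation:

- **Toy ontology** (`make_toy_obo`): a two-root skeleton (chemical entity,
  role) in which every internal term has at least two distinct children,
  plus exactly `n_cycles` conjugate 2-cycles (each removes 1 term and 3
  relationships at merge) and `n_chains` single-child chains (each removes
  `chain_len - 1` terms and edges at prune). Term/edge counts at every
  stage are therefore exact, not statistical. `TOY:` ids keep fixtures
  unmistakable.
- **Annotation + mapping** (`make_annotation_fixture`): round-robin cargo
  assignment covering every leaf, orphan fraction by construction, classes
  consistent with the first cargo's parent, two alternate spellings that
  resolve only through the manual mapping tier.
- **DE tables** (`make_de_fixture`): planted transporters get
  `log2fc = de_effect` (default 2.0) and vanishing raw p-values; the
  background draws `log2fc ~ N(0, 0.2)` and uniform raw p. The `fdr` column
  is produced by BH-adjusting the whole table, giving it the same
  provenance as real differential-expression output. `de_effect = 0` yields
  a pure null table.
- **Sequences** (`make_sequence_fixture`): multi-pass membrane
  architectures (8–12 transmembrane helices of 21 residues, loops of
  10–40, an optional signal peptide) over a fixed background amino-acid
  composition; positives raise the transmembrane leucine sampling weight by
  `class_signal` (default 0.25 — a strong, unambiguous signal chosen so
  that recovery failures indicate broken machinery rather than statistical
  bad luck).

What they do **not** emulate: real ChEBI vocabulary and its dense
multi-parent topology, correlated expression noise, biologically realistic
feature–substrate relationships, or class imbalance as extreme as the real
orphan problem. Passing tests therefore certify the machinery — graph
surgery, counting, test statistics, training protocol — not biological
performance on real data.

## Numerical and degenerate-case choices

- Fisher p-values come from the upper hypergeometric tail (`phyper` on
  `a - 1`); the test suite checks them against an explicit summation
  oracle to 1e-12 over every 2×2 table with `n ≤ 60`, and against
  `fisher.test` spot checks.
- Zero-overlap terms get `p = 1`; empty hit sets are valid and produce no
  significant terms.
- AUROC uses midranks (ties averaged); AUPRC is average precision with tied
  scores grouped, so both are permutation-invariant.
- Absent domains yield all-zero features rather than `NA`; `X` residues
  count toward residue totals but carry no frequency mass, so frequencies
  sum to 1 whenever any standard residue exists.
- The null-label recovery check asserts the *mean* out-of-bag AUROC across
  seeds lies in 0.5 ± 0.1: at ~100 training proteins a single null AUROC
  has a standard deviation near 0.06, so a per-seed band would reject
  correct code with non-trivial probability while the mean is stable.
- Problem sizes in the shipped tests — toy ontologies of ~30–60 terms,
  universes of ~21 transporters, 100 proteins × 93 features, grids of 2–4
  cells — are chosen so each property is exercised at full strength while
  the whole suite stays interactive; all of them scale up through
  `fixture_spec` without code changes.

## Limitations

- Exact-label plus offline-mapping resolution is deliberately conservative;
  names that a live lookup service would fuzzily resolve appear in the
  rejects report and need a mapping row.
- The 70%/5-count testable-term filter and the universe definition follow
  the defaults argued above, but the true curation-scale values of these
  choices are not recoverable from first principles; both are parameters.
- A single pruning pass versus fixpoint iteration can differ in removed-term
  counts on real ontologies; this package commits to the fixpoint.
- All-OOB model selection reuses the same scores three times (grid,
  threshold, metrics); for publication-grade performance claims an outer
  resampling loop would be required.
- Classifier probabilities are not calibrated beyond the gamma anchoring of
  the threshold; compare scores across terms only through the normalized
  scale.
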