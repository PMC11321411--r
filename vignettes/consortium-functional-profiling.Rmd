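---
title: "Methods: comparative functional profiling of defined consortia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative functional profiling of defined consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnotofun)
```

## Scope and data model

`gnotofun` compares the predicted metabolic potential of defined
(gnotobiotic) bacterial consortia from KEGG Ortholog (KO) annotations.
The atomic input is one genome's gene→KO table; everything else —
consortium set algebra, module completeness, prevalence, comparative
statistics, reporter enrichment, metabolomics — is derived from it plus
small structured side inputs (module definitions, a KO functional
hierarchy, concentration tables, gene-level p-values).

A `genome_annotation` stores KO **copy counts** (how many genes map to
each KO) plus a count of unannotated genes. Two conventions coexist
deliberately: presence (a KO is in a genome or not) drives all set
algebra, module scoring and prevalence denominators, while copy counts
feed the gene-count columns of prevalence tables and the KO-count vectors
used for dissimilarity. This mirrors standard practice: "non-redundant KO
count" deduplicates, while "gene count" does not.

## Module structure and completeness

A module is an ordered list of reaction *steps*; each step is a set of
*alternatives* (isoenzymes or alternative sub-pathways); each alternative
is a *complex* — a set of KOs that must all be present. Two input
dialects produce this structure:

- the GMM flat file (`ID<TAB>Name`, one line per step, `,` = OR,
  `+` = complex, `///` terminator), and
- KEGG-style boolean `DEFINITION` strings (space = serial step, `,` = OR
  inside parentheses, `+` = complex member, leading `-` = optional
  component, parentheses nest).

Optional (`-`-prefixed) components are recorded but excluded from both
satisfaction checks and denominators. A wholly optional token between
steps is attached to the preceding step's alternatives as optional
content; spaces *inside* a grouped alternative are folded into the
complex (all-required), which flattens serial sub-definitions
conservatively. Unbalanced parentheses fail with the offending position;
a step line with no valid KO token fails naming the module.

Completeness of module $m$ in genome $g$ is, in the default **steps**
mode,

$$c(m, g) = \frac{\#\{\text{steps with some alternative fully present}\}}
                 {\#\{\text{non-optional steps}\}},$$

and in the selectable **genes** mode the matched fraction of the union of
required KOs. The threshold is inclusive: `present ⇔ c ≥ τ` with
τ = 0.75 by default ("at least 75%"). The two modes exist because a
75%-of-genes rule is ill-defined once steps have OR-alternatives of
different sizes; step coverage is the standard resolution for
curated gut-module sets, so it is the default, and the mode used is
recorded in every output's provenance header. Coverage is monotone in the
genome's KO set, and coverage at exactly τ is a presence call by
construction.

## Consortium comparison

- `union_kos()` deduplicates across members ("duplicate KOs counted
  once"); `unique_kos()` is a presence-based set difference against the
  union of all other consortia.
- Prevalence tables keep both per-isolate copy counts (summing to the
  gene count) and carrier counts (`n_present`/`n_total`); rows are
  restricted to KOs shared by ≥ 3 isolates by default and sorted by
  carriers, then gene count, then KO id — a deterministic total order.
- Module-prevalence matrices report the fraction of members carrying each
  module per consortium, rows ordered by the first (reference)
  consortium's proportion; the matrix is dense so absent-everywhere
  modules remain visible as zero rows.
- Category allocation counts *distinct* KOs per (category, subcategory).
  A KO annotated under several categories counts once in each; the
  per-category sums are therefore not additive-exclusive, which is
  documented rather than "fixed" because the alternative (fractional or
  first-category-wins allocation) discards information and has no
  canonical tie-break.

## Comparative statistics

Before differential and dissimilarity analyses, modules carried by
strictly more than $\lfloor 0.8\,N \rfloor$ of the $N$ pooled isolates
are removed as uninformative (with the study design of 9 + 8 + 12 = 29
isolates this cutoff is 23; the inequality is strict).

- Pairwise χ² tests are Pearson without continuity correction (these are
  r×c tables, where Yates applies only to 2×2 and is not indicated);
  expected-zero cells raise a degenerate-table error after all-zero
  margins are dropped with a warning.
- Dissimilarity indices are medians of all pairwise Euclidean distances
  between member KO-count vectors over retained modules. One-member
  consortia are an error, not a zero.
- Kruskal–Wallis uses the tie-corrected rank statistic; Dunn's pairwise
  z uses the same pooled tie correction. The post-hoc adjustment method
  is not dictated by the workflow's sources, so Benjamini–Hochberg is
  used, consistent with the FDR usage elsewhere in the pipeline, and the
  method is recorded in the output.
- PCA is column-centred and unscaled by default (the Euclidean geometry
  of the raw counts); unit-variance scaling is selectable. A
  zero-variance matrix yields all-zero scores with a degeneracy flag
  instead of NaNs. Group ellipses use the 2-D score covariance at the
  0.95 χ² quantile.

## Reporter-score enrichment

Gene-level p-values are transformed one-sidedly, $z = \Phi^{-1}(1-p)$,
signed by the direction of the effect, with p clamped to
$[10^{-15}, 1-10^{-15}]$ to keep z finite. The pathway aggregate is
$Z = \sum z_i / \sqrt{k}$. The background is Monte-Carlo: $\mu_k$ and
$\sigma_k$ are the mean and SD of the aggregate over `n_samples`
(default 10,000) random $k$-subsets drawn without replacement from the
**full** gene-z pool (pathway-excluded sampling is selectable but not the
default, matching the usual convention). One background is computed per
distinct pathway size and shared, which makes the cost proportional to
the number of distinct sizes rather than pathways. The call is strict:
enriched in the group of interest iff $Z_{adj} < -1.6$ under the
convention that that group's effects are signed negative; $-1.6$ exactly
is *not* enriched. A constant pool (σ = 0) is an error, not a silent
zero-division.

## Metabolomics

Concentrations are nmol/g with a limit of detection (default 1 nmol/g);
below-LOD values are stored as censored and contribute 0 by default
(LOD/2 selectable) — the choice is recorded in provenance and applied
consistently in totals and tests. Two-group comparisons use the
Mann–Whitney–Wilcoxon test, exact by enumeration when the pooled n ≤ 20
and tie-free, otherwise the normal approximation with tie and continuity
corrections; identical constant groups short-circuit to p = 1. Q-values
are Benjamini–Hochberg; `significant ⇔ q < α` (α = 0.05). Heatmap
pre-processing z-scores rows to mean 0, SD 1 (constant rows become zeros
with a warning), and clustering is **Ward-1** — the Lance–Williams update
on *unsquared* Euclidean distances (`hclust` method `ward.D`) — as
distinct from the squared-distance Ward-2 variant; the variant is
selectable and recorded.

## Gene-cluster rules

The *nan* (sialic-acid catabolism) rule requires *nanA* (lyase) and
*nanE* (epimerase), with *nanK* (kinase) required except where the taxon
predicate holds (phylum Bacteroidota, which catabolises sialic acid
without *nanK*); *nanH* (sialidase) is a separate single-gene rule, and a
permissive nanE-only variant exists for screening. The shipped
symbol→KO map (K01639/K01788/K00885/K01186) is configuration to be
verified against the KO catalogue release in use, not ground truth. Only
co-occurrence within a genome is evaluated — the inputs are KO tables
without coordinates, so operon structure and adjacency are out of scope
and "cluster" is to be read accordingly.

## Synthetic data and what passing tests mean

The generators emulate the study design: consortia of 9, 8 and 12
genomes, module databases with 2–5 steps and up to 3 alternatives per
step, metabolome tables at n = 7 vs 8 with log-normal noise (σ = 0.3)
and multiplicative planted effects, and gene-level p-value sets with a
configurable number of enriched pathways (default effect: mean gene
z = 1 at k = 20). Module KOs are drawn without replacement from an id
block disjoint from background KOs, so planted step coverage is recovered
*exactly* — parameter recovery is an algebraic, not statistical, test.
All generators take explicit seeds and restore the caller's RNG state.

What synthetic data does **not** emulate: real KO co-occurrence structure
(operons, shared pathways between modules), copy-number distributions,
annotation noise from the upstream gene-calling/KO-assignment step,
compositional correlation between analytes, or batch effects. Passing
tests therefore demonstrate algorithmic correctness under the stated
model, not robustness to those real-data features.

Test problem sizes are chosen to make the oracle comparisons exhaustive
yet quick: brute-force module evaluation over 1,000 random
(module, genome) pairs, rank-statistic enumeration at ≤ 8 observations
per group, Mann–Whitney enumeration at ≤ 8 per group, reporter
calibration at 500 null pathways with 10,000 background draws, and 100
seeded metabolome replicates.

## Known limitations

- **FDR recovery ceiling.** With 2 truly shifted analytes among 15 and BH
  at α = 0.05, the step-up cascade flags at least one null analyte
  whenever the smallest null p-value falls below the rank-3 threshold
  (0.01), which happens in roughly 11% of replicates at n = 7 vs 8 —
  this is a property of FDR control (it bounds the *expected* false
  discovery proportion, not the per-experiment probability of any false
  positive), not of this implementation. Perfect "only the planted
  analytes" recovery therefore plateaus near 87–88% regardless of effect
  size; the corresponding end-to-end check in the test suite documents
  this by asserting the stricter nominal bound and is expected to fail.
- Module scoring is per-genome; community-level (pooled) coverage and
  abundance weighting are out of scope.
- The χ² contingency construction counts distinct KOs per subcategory by
  default; counting with copy-number multiplicity is selectable because
  the convention is not recoverable from typical methods descriptions.
- The prevalence table's "absent in other consortium" semantics are
  presence-based (count ≥ 1); no copy-number threshold is applied.
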