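---
title: "Comparative resistomics with panresistome: model, assumptions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative resistomics with panresistome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panresistome)
```

## The problem

Subsystem-style annotation services assign every predicted gene of a
bacterial genome a four-level functional descriptor: **Category**,
**Subcategory**, **Subsystem**, and **Role** (the gene/protein-level
description). Given such per-strain annotation exports for a query isolate
and a panel of strains with known radiation phenotypes, comparative
resistomics asks: which stress- and resistance-related functions does the
query share with resistant strains, and which of those are absent from every
sensitive strain? That exclusive set pinpoints candidate determinants of the
query's tolerance phenotype — functions selectively retained by
radiation-adapted taxa.

`panresistome` implements this as a four-stage pipeline: annotation reading,
presence–absence matrix construction, keyword-guided resistome extraction
with a two-class comparison, and deterministic reporting, plus a synthetic
panel generator that validates every stage against a planted ground truth.

## The presence–absence model

The unit of presence is the full descriptor 4-tuple, not the role string
alone. Annotation exports legitimately repeat one role under several
category/subsystem contexts to express multi-functionality; collapsing on
role alone would erase that context, while treating every export row as
distinct would count duplicates. Each distinct (Category, Subcategory,
Subsystem, Role) combination therefore becomes one matrix row — a
*functional key* — and the matrix is strictly binary:

$$M_{ks} = 1 \iff \text{strain } s \text{'s export contains} \ge 1
\text{ record with key } k,$$

with every key absent from a strain's export imputed as 0. Duplicate records
collapse to a single 1, so all downstream counting is counting of distinct
keys. Two design choices make the matrix reproducible:

* **Case-folded identity.** Exports are inconsistent in capitalization;
  comparing keys case-sensitively would silently split rows and inflate
  counts. Keys are equal iff their lower-cased 4-tuples are equal; the
  display form keeps the first-seen casing.
* **Deterministic order.** Rows sort lexicographically on the case-folded
  tuple in byte (C-locale) order, so row order never depends on input order
  or locale; columns follow the input order of the tables.

Empty descriptor cells become empty strings and participate in keys as-is: a
record with a blank Subcategory is still a valid key, since higher-level
groupings are often left blank in real exports and only strain-level
absence, never cell content, is imputed.

Derived summaries are `conserved_keys()` (keys with value 1 in every strain
of a subset — the core complement), `conserved_fraction()` (the core share,
reported exactly, to one decimal, and rounded), and `category_counts()`
(distinct keys per strain per category; by construction each strain's counts
sum to its matrix column sum).

## Keyword-guided resistome extraction

The resistome is operationalized by keyword search: a row is retained when
at least one term occurs case-insensitively as a plain substring of at least
one of its four descriptors. Substring matching without stemming or regular
expressions is the simplest semantics that is also auditable — a reviewer
can verify every retained row by eye. The default term list
(`default_keywords()`) covers the function families repeatedly implicated in
radiation and desiccation tolerance — general stress/resistance terms,
efflux and transport, DNA repair, oxidative-stress defense (peroxidases,
glutathione), osmoprotection (osmolytes, betaine), chaperones and heat
shock, siderophore-mediated iron scavenging — and ships as an editable
plain-text config file rather than a hidden constant. Any character vector
or keyword file replaces it wholesale.

The filter is idempotent and row-monotone: filtering a filtered matrix is a
no-op, and removing terms can only shrink the result.

## Phenotype classification from D10 doses

Panel strains are classed by their D10 — the dose reducing viability to 10%.
A strain with D10 at or above 2 kGy is **resistant**; below, **sensitive**
(`classify_strain()`, threshold adjustable). Doses convert via 1 kGy =
1,000 Gy and 1 Mrad = 10 kGy, endpoint-wise for ranges. Two conventions
handle the messiness of published survey tables:

* A user-asserted class always wins: reference "sensitive representative"
  strains often carry no D10 at all.
* A `(low, high)` range classifies by its **upper endpoint**. Published
  panels list range-valued strains (e.g. 0.13–0.25 Mrad = 1.3–2.5 kGy) as
  resistant, which is only consistent with an upper-endpoint (or curator
  override) reading. Because the lower endpoint would decide otherwise, a
  range that straddles the threshold triggers a warning so the call is
  always auditable.

Strains with neither dose nor asserted class become `unclassified` (with a
warning) and take no part in the comparison.

## The two-class protocol

With a query strain $q$, resistant set $R$, and sensitive set $S$, the
protocol computes three nested key sets over the keyword-filtered matrix:

* **total** — all keyword-matched keys (any strain);
* **shared** — total keys with $M_{kq} = 1$ and $M_{kr} = 1$ for at least
  one $r \in R$;
* **exclusive** — shared keys with $M_{ks} = 0$ for every $s \in S$.

The nesting exclusive ⊆ shared ⊆ total holds by construction and is
asserted on every run. The sets are computed over the keyword-filtered
matrix, not the full matrix, since the comparison is defined within the
total resistome. Monotonicity follows from the set algebra: adding a
resistant strain can only grow the shared set; adding a sensitive strain can
only shrink the exclusive set. All three sets persist via `write_sets()` as
TSV matrices (restricted to each set's keys) plus a JSON provenance sidecar
recording the query, panel classes, keyword list, and package version, so
any result file can be traced to the exact inputs that produced it.

## What the synthetic generator emulates — and what it does not

`generate_panel()` emulates the statistical structure the protocol assumes
in real exports:

* a **core vocabulary** present in every strain (essential metabolism);
* **planted resistome keys** — keyword-matching keys present in the query
  and a random non-empty subset of the resistant strains, absent from
  sensitive strains except for a controlled **leakage** fraction copied into
  them;
* per-strain private **noise keys**, a tunable fraction of which also match
  keywords (so the filter's output is not trivially the planted set);
* optional **duplicate rows**, stressing the binary-collapse rule, since
  real exports repeat roles.

Defaults (1 query + 3 resistant + 3 sensitive strains, 100 core keys, 50
planted shared keys, zero leakage, 20 noise keys per strain, 25% keyword
noise) give a seven-strain panel in the shape of a typical two-class
comparison — a handful of comparators per class, a core that dominates each
genome's annotation, and a planted signal comfortably larger than per-strain
noise — while staying small enough that every validation run is instant.
Synthetic D10 doses are drawn consistently with each class (resistant 2.2 to
9.5 kGy, sensitive 0.1 to 1.5 kGy), so the classification stage is exercised
end to end. Output is a pure function of the spec and seed (a named,
fixed-kind random generator recorded in the ground-truth manifest), down to
byte-identical files.

The generator plants signatures at the key level only. It does **not**
simulate genome sequences, annotation-service behavior (mis-annotation,
vocabulary drift, synonymous role strings), phylogenetic correlation among
strains, or realistic vocabulary sizes (a real genome yields thousands of
keys). Passing tests therefore demonstrate that the set algebra, matrix
construction, and I/O are exact under the stated membership model — they do
not validate keyword-list completeness or annotation quality on real data,
and on real panels the exclusive set is a hypothesis generator, not a
causal claim.

## Numerical and formatting choices

* **Ordering and ties.** All key ordering is byte-order radix sorting of
  case-folded tuples. Heatmap clustering (`cluster_order()`) pre-sorts axis
  labels the same way before computing distances, so equal-distance ties
  resolve identically regardless of input order; defaults are average
  linkage on Euclidean distances of raw counts, both overridable, chosen as
  the conventional defaults for count heatmaps rather than inferred from any
  particular published figure.
* **Rendering.** The color gradient is a fixed dark-blue → green → yellow
  ramp (viridis); cells are annotated with counts for tables of at most 40
  rows; PNG/SVG devices embed no timestamps and PDF date fields are scrubbed
  after writing, so identical inputs give identical bytes.
* **File formats.** Text tables are UTF-8 with LF endings and BOM-tolerant
  reading. The `.xlsx` writer emits inline-string cells in an uncompressed
  archive with fixed entry timestamps — deterministic by construction — and
  is verified by reading back through an independent reader. Legacy `.xls`
  is supported as input only.
* **Degenerate inputs.** An empty table list, duplicate strain ids, unknown
  strains, unknown dose units, non-positive doses, inverted ranges, and
  empty matrices all fail with specific errors; an empty keyword set warns
  and returns an empty filter result rather than silently matching
  everything.

## Validation strategy and problem sizes

The test suite checks every operation against an independent brute-force
oracle that works on plain sets of descriptor tuples and never touches the
implementation's code paths: matrix construction against set-of-tuples
tabulation (100 randomized panels of up to 8 strains and 200 keys),
conserved keys against set intersection, shared/exclusive extraction against
`query ∩ (∪ resistant)` and `\\ (∪ sensitive)`, clustering leaf order
against a from-scratch agglomerative implementation, and the nesting
invariant on 500 randomized protocol runs. Planted-signature recovery is
exact (precision = recall = 1) at zero leakage and degrades predictably as
leakage grows. These sizes keep the full suite under half a minute while
exercising every code path; they are validation instances, not performance
benchmarks — the matrix operations are vectorized and scale comfortably to
real panel sizes (tens of strains, thousands of keys).

## Known limitations

* Keyword matching is lexical. A resistance function described with
  unanticipated vocabulary is missed; an incidental substring match is
  retained. The term list is a visible, editable input for exactly this
  reason.
* Keys are annotation-level, not sequence-level: no orthology, identity
  thresholds, or copy number. Two strains "share" a key whenever their
  annotations print the same four descriptors.
* The headline counts of any particular published comparison depend on that
  study's actual annotation exports; this package reproduces the protocol
  and its arithmetic, not numbers that require the original genomes.
* Presence is binary by design; gene dosage and expression are out of scope.
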