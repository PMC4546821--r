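---
title: "Pathway data overlays and Z-score over-representation analysis with pathora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway data overlays and Z-score over-representation analysis with pathora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathora)
```

## What the package computes

pathora scripts the full loop of diagram-based pathway analysis: build or
load pathway diagrams, attach tabular omics measurements to their nodes
through identifier cross-mapping, paint the measurements onto the nodes as
colour stripes, score every pathway in a collection for over-representation
of "changed" genes, and export the results as a navigable HTML report.
Everything is callable from R, from a batch command line, and over a
namespaced XML-RPC service, so the same analysis can run interactively or
inside a pipeline.

## The over-representation model

A *criterion* is a boolean expression over a measurement row, written in a
bracketed-column dialect, e.g. `[P.Value] < 0.05`.  Scoring a pathway
reduces the dataset to four counts over distinct gene identities:

* $N$ — measured genes (rows that resolve to a mappable identity),
* $R$ — those meeting the criterion,
* $n$ — measured genes linked to the pathway,
* $r$ — linked genes meeting the criterion.

Under the null hypothesis that the pathway's $n$ genes are an exchangeable
draw from the $N$ measured genes, $r$ is hypergeometric with mean $nR/N$.
The package standardises the observed count with the finite-population
variance:

$$
Z \;=\; \frac{r - n R / N}
{\sqrt{\,n \frac{R}{N}\left(1 - \frac{R}{N}\right)\left(1 - \frac{n-1}{N-1}\right)}}
$$

A positive score means the pathway contains more criterion-meeting genes
than expected from the dataset-wide rate; a negative score means fewer.
The score is reported as undefined (`NaN` in text outputs) exactly when the
variance is zero — $n = 0$, $n = N$, $R = 0$ or $R = N$ — rather than
being forced to zero.  The test suite checks the closed form against exact
hypergeometric moments enumerated from binomial coefficients for every
count tuple with $N \le 20$, and against 100&#8239;000 hypergeometric draws
for larger random tuples.

Assumptions worth keeping in mind: genes are treated as exchangeable
(no gene-length or expression-level bias correction), pathways are scored
independently, and **no multiple-testing correction is applied** — the
output is a raw ranked list of Z scores, and ranks near the top of a long
list should be interpreted accordingly.

### Counting rules

Several choices had to be fixed where diagrams and probe-level tables meet:

* **Gene unification.** Rows are unified by the mapping store's
  equivalence classes (see below); duplicate probes for one gene count
  once, and a gene meets the criterion when *any* of its rows does.
* **Dataset-wide $N$.** $N$ covers all measured, mappable genes, not just
  genes appearing in some pathway.  Rows whose identifier the mapping
  store does not know are excluded from $N$ — they can never hit a
  pathway — and their number is reported in the counts object.  When no
  store is supplied, every distinct (system code, identifier) pair counts.
* **Missing cells.** Criterion evaluation is three-valued: a comparison
  on a missing cell is *missing*, `FALSE AND missing` is `FALSE`,
  `TRUE OR missing` is `TRUE`, otherwise missing propagates.  At the
  counting boundary a missing outcome is treated as *not meeting* the
  criterion, so genes with missing statistics stay in $N$ without
  inflating $R$ — this keeps $N$ stable across criteria.
* **Ties and undefined scores.** Ranked output sorts by descending $Z$,
  undefined scores last, ties broken by pathway name ascending — a
  deterministic order for report generation.

## Identifier mapping

Cross-references are loaded from a flat TSV of pairwise links
(`source_code`, `source_id`, `target_code`, `target_id`) and closed
transitively with union-find, so membership behaves as an equivalence web:
if L:1 links to En:E1 and En:E1 links to H:HGNC:1, then L:1 maps to
H:HGNC:1.  Lookups are case-sensitive (database accessions generally are),
and mapping a code to itself passes the identifier through unchanged.
System codes follow the familiar short-letter convention (`L` Entrez Gene,
`En` Ensembl, `Ce` ChEBI, ...) and the table is user-extensible with
`register_system_code()`.

## The GPML dialect

Documents are stored in a GPML-2013a-like XML subset: a `<Pathway>` root
with `Name`/`Organism` attributes and a board-size `<Graphics>` child;
`<DataNode>` and `<Label>` elements carrying a `<Graphics CenterX CenterY
Width Height>` child and an optional `<Xref Database ID>` (the `Database`
attribute holds the short system code); `<Interaction>` elements that
reference endpoint ids through `Source`/`Target` attributes.  Coordinates
are centre-based abstract units with y growing downward; the default node
box is 80×20 units.  Nodes added without coordinates are placed on a grid,
left to right in rows of ten at a 100×40 pitch, so bare gene lists become
readable diagrams without manual layout.

Choices made where the format left room:

* **Unknown elements pass through.**  Children of the root that the model
  does not recognise are kept as opaque blobs and re-emitted verbatim, so
  editing a richer file does not destroy its extra content.  Groups,
  anchors, graphical states and curved connectors are out of scope.
* **Deterministic serialisation.**  Writing assembles the XML by hand
  with a fixed attribute order and 15-significant-digit number formatting,
  so the same document always produces the same bytes and
  write→read→write is byte-idempotent.  The test suite round-trips 500
  random documents.
* **Dangling references survive.**  Removing a node keeps interactions
  that referenced it, flagged as dangling and reported by
  `validate_pathway()` — the least surprising behaviour for scripted
  edits, where a follow-up step often re-adds the node.  Self-loops are
  likewise flagged, not rejected.

## Colour computation and rendering

Two colouring methods exist per data column: a **gradient** interpolates
each RGB channel piecewise-linearly between 2 or 3 anchors, clamping
outside the anchor range and rounding channels half-up to integers; a
**rule list** applies the first rule whose criterion evaluates true, with
a documented fallback (white) when none fires.  The classic scheme is a
blue–white–red gradient anchored at −1, 0, 1 for log2 fold-changes and a
green rule for `[P.Value] <= 0.05`.

Each mapped node is divided into k equal-width **vertical stripes**, one
per spec entry, left to right in spec order; the integer pixel partition
uses boundaries `round(i·w/k)` so stripe widths always sum exactly to the
node width with no overlap.  Nodes with no matching measurement row are
painted light grey (RGB 211,211,211), as is a missing cell within a mapped
node.  When several rows match one node, the first row in file order is
displayed and the node's back page flags the multiplicity and lists all
rows.

Rendering produces an SVG 1.1 string and an RGB raster at a fixed 2 px
per diagram unit, plus one rectangular hit region per data node in raster
pixels for HTML image maps.  Node labels are drawn in the SVG only; the
raster deliberately contains no text so that no font metrics enter the
output, and tests assert geometry and colours, not glyphs.

## The HTML report

`export_report()` writes a self-contained directory: `index.html` with a
settings overview (criterion, $N$, $R$, collection size, dataset
provenance), the clickable pathway list ranked by Z score beside a content
iframe, a legend, one page per pathway embedding its PNG with a
`<map>`/`<area>` image map, and one back page per data node showing its
annotation (with configurable per-database URL templates) and matched
measurement cells.  No timestamps are embedded, so re-export over an
existing directory reproduces identical bytes; the test suite crawls a
report from its index and verifies that no link dangles and that area
counts equal node counts.

## RPC service and batch runs

The XML-RPC server binds port 7777 by default (loopback use is the
expected deployment; the accept loop is single-threaded).  Methods carry
the `PathVisio.` namespace prefix, and rich objects travel as opaque
string handles scoped to the server session — they expire on stop.  The
HTTP loop calls the same `dispatch()` function that library users can call
directly, which is what the equivalence tests exercise.  A dedicated
`system.shutdown` method ends a serving loop cleanly, which is also how
the test suite stops its background server.

The batch runner reads an INI-style settings file (one section per data
file: data path, identifier/system-code columns, pathway source, optional
mapping table and criterion, gradient/rule strings, output directory) and
processes entries independently: one failing entry is logged and does not
stop the rest, but flips the exit status.  An example configuration ships
under `inst/extdata/`.

## The fixture generator

`make_fixture()` emulates the shape of a differential-expression results
table scored against a small pathway collection: an Entrez-like system
("L") in the measurements, an Ensembl-like system ("En") on the pathway
nodes, and a known bijection between them in the mapping TSV, so linking
always exercises the mapper.  Criterion status is planted per gene —
Bernoulli at `background_hit_rate` for background genes and
`enriched_pathway_rate` for genes of the first pathway — and the `P.Value`
column is set to 0.01 or 0.5 so that `[P.Value] < 0.05` recovers the
planted truth exactly.  The truth record carries the exact (N, R, n, r)
per pathway, which is the primary oracle for the statistics tests.

Defaults were chosen once, before testing, to describe a realistic
mid-sized experiment: 1000 measured genes; five disjoint pathways of 30
genes; a background hit rate of 0.2 (a typical fraction of genes at
P&nbsp;<&nbsp;0.05 after a strong perturbation); threefold enrichment
(rate 0.6) in the first pathway; 5% unmappable rows; no missing cells.  A
quick power check motivates the rates: with n = 30 the null pathways
score around 6 ± 1.8 criterion genes while the enriched one scores around
18 ± 2.7, so the enriched pathway should rank first in well over 95% of
generations — which the acceptance suite measures over 200 seeded
generations, and the acceptance script re-measures over 100.

What the generator does **not** emulate: realistic expression
distributions, correlated genes, probe-level noise, overlapping pathways,
or partial mapping ambiguity (the L↔En map is a bijection).  Passing
tests therefore demonstrate the correctness of counting, scoring, linking
and export on clean planted structure — not robustness to the biological
messiness of real microarray or RNA-seq data.

## Problem sizes and numerical choices

The test suite fixes its own sizes: exhaustive Z-score enumeration up to
N = 20 plus twenty 100k-draw sampling checks; 200 seeded generations for
enrichment recovery; 500 random documents for GPML round-trips; 200
random criteria against a truth-table oracle over all 81 assignments of
{0, 1, missing} to four columns; 1000 random gradient evaluations.
Geometry comparisons use a 1e-9 tolerance; Z-score oracle agreement is
asserted at 1e-8 (the closed form and the enumerated moments agree to
rounding error).  Degenerate inputs are defined, not accidental: empty
pathways score NaN, empty rule lists are invalid, empty reports still
crawl cleanly.

## Known limitations

* Raw Z scores only: no p-values, no FDR control, no gene-set
  permutation test.
* One identifier equivalence web per store: no score-weighted or
  probabilistic mappings.
* The GPML subset omits groups, anchors, states and literature elements
  (though it preserves them opaquely).
* The RPC server handles one request at a time and offers no
  authentication; it is meant for loopback automation, not public
  deployment.
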