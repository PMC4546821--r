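# pathora

Scriptable pathway analysis for omics measurements: build and edit
pathway diagrams in a GPML-dialect XML format, link tabular
measurements (logFC, P-values, concentrations, ...) to diagram nodes
through identifier cross-mapping, paint the data onto the nodes with
colour gradients and criterion rules, score every pathway in a
collection with a Z-score over-representation test, and export the
ranked results as a hyperlinked HTML report with image maps and
per-gene back pages.  The same operations are available as an R API, a
batch command line, and a namespaced XML-RPC service (default port
7777), so pathway analysis can run directly inside the scripting
environment that did the primary statistics.

It is aimed at transcriptomics/metabolomics analysts who finish their
differential-expression work in R and want the pathway visualisation and
over-representation step in the same script, without clicking through a
desktop tool once per dataset.

## The statistic at the core

For a dataset with `N` measured genes of which `R` meet a user criterion
(e.g. `[P.Value] < 0.05`), a pathway linking `n` measured genes of which
`r` meet the criterion is scored

    Z = (r − n·R/N) / sqrt( n·(R/N)·(1 − R/N)·(1 − (n−1)/(N−1)) )

— the observed number of changed genes standardised by the
finite-population hypergeometric variance.  Positive Z: more changed
genes than expected from the dataset-wide rate; negative: fewer; NaN when
the variance is zero.  Genes are deduplicated through the identifier
mapper before counting, and criteria evaluate with three-valued logic so
missing cells never inflate `R`.  Pathways are ranked by descending Z.

## Worked example

The package ships a deterministic fixture generator that emulates a
differential-expression experiment: 1000 measured genes, five disjoint
30-gene pathways, background criterion rate 0.2, with the first pathway
enriched threefold.

```r
library(pathora)

fx <- make_fixture(fixture_spec(seed = 42), dir = "fx")
ranked <- rank_pathways(fx$paths$pathway_dir, fx$table, fx$store,
                        "[P.Value] < 0.05")
print(ranked, digits = 3)
#> Pathway over-representation ranking (criterion: [P.Value] < 0.05)
#>               pathway                                 file  n  r    N   R      z
#> 1 pathway_01_enriched fx/pathways/pathway_01_enriched.gpml 30 19 1000 231  5.306
#> 2          pathway_04          fx/pathways/pathway_04.gpml 30  9 1000 231  0.910
#> 3          pathway_03          fx/pathways/pathway_03.gpml 30  6 1000 231 -0.409
#> 4          pathway_02          fx/pathways/pathway_02.gpml 30  4 1000 231 -1.288
#> 5          pathway_05          fx/pathways/pathway_05.gpml 30  4 1000 231 -1.288
```

Of the 1000 measured genes, 231 meet the criterion (rate 0.23).  The
planted pathway shows 19/30 changed genes against the ~7 expected and
tops the list at Z = 5.3; the four background pathways scatter around
zero.  Visualising and exporting the full report:

```r
spec <- visualization_spec(list(
  logFC   = color_gradient(c(-1, 0, 1), c("blue", "white", "red")),
  P.Value = list(color_rule("[P.Value] <= 0.05", "green"))
))
rendered <- lapply(fx$docs, function(doc) {
  render_pathway(doc, link_to_pathway(fx$table, doc, fx$store), fx$table, spec)
})
export_report(ranked, rendered, fx$table, spec, "report")
# browse report/index.html: ranked clickable list, legend, image maps,
# one back page per gene with its measurements
```

Colours follow the classic scheme — e.g. a log2 fold-change of 0.25 on
the blue–white–red gradient paints RGB `(255, 191, 191)`:

```r
interpolate_color(color_gradient(c(-1, 0, 1), c("blue", "white", "red")), 0.25)
#> [1] 255 191 191
```

The same pipeline runs from the shell
(`inst/scripts/pathora analyze --data ... --pathways ... --criterion ...
--out ...`, or `batch config.ini`, or `serve` for the XML-RPC service)
and over XML-RPC:

```r
h <- start_server()   # binds port 7777
# in another process:  rpc_call("PathVisio.createPathway", "Glycolysis")
```

## Documentation

The methods vignette (`vignettes/pathway-data-overlay.Rmd`) describes
the model and its assumptions, the counting rules, the GPML dialect, the
colour and rendering contracts, the fixture generator's design, and the
package's known limitations (raw Z scores, no multiple-testing
correction).
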