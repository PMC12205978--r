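# bsnermap

Curation tools for BioSample metadata: extract cell-line names and
experimentally modulated genes from heterogeneous key–value sample
attributes with a pluggable text-generation backend, map the extractions to
Cellosaurus terms and HGNC gene ids with deterministic rules, and score the
results against a gold standard.

## Who this is for

BioSample records describe samples as free-form key–value pairs, and the
same concept hides under many attribute names — the package's audit tools
show a single cell-line value spread across keys like `cell line`,
`cell_line`, `source_name`, `isolate`, `strain`. Conservative rule-based
mappers that only read whitelisted keys miss everything else; scanning all
values blindly trips over homonyms (`"H1"`) and procedural text ("seeds
were sown … leaf tissue was harvested"). `bsnermap` is for curators and
secondary-database maintainers who want a language model to handle only the
interpretation steps (is this sample a cell line? which of several
identically named terms fits?) while keeping the ontology mapping itself
rule-based, auditable, and reproducible — and who need the entire pipeline
testable offline with a deterministic scripted backend.

## The method in brief

Per record, with attribute set $A$ serialized as a JSON object:

1. a fixed extraction prompt asks the model for `{"cell_line": s}` or the
   sentinel `{"cell_line": "None"}`;
2. $s$ is resolved against a Cellosaurus index through a normalization
   ladder — verbatim → case-fold → delimiters (`_`,`-`) → spaces → both —
   stopping at the first level with hits; short strings (|s| ≤ 2) are
   searchable without restriction;
3. if several terms share the name, a selection prompt presents each term's
   JSON context (name, exact/related synonyms, diseases, category, sex) and
   the model returns one id or `"not unique"`; ids outside the candidate
   set are rejected as hallucinations.

Predictions against a gold standard are summarized by four metrics:

- cell-line accuracy = correct mappings / outputs mapping to a cell line
- cell-line coverage = correct mappings / gold cell-line entries
- non-cell-line precision = correct non-mappings / all non-mapping outputs
- non-cell-line recall = correct non-mappings / gold non-cell-line entries

with `NOT_UNIQUE` outputs counted as incorrect mappings even when the right
term is among the candidates. A parallel task extracts
`{"gene", "method"}` modulation pairs, canonicalizes method names
(knockout / knockdown / overexpression vocabularies, everything else
verbatim), and resolves symbols case-insensitively across all HGNC symbol
classes at once (approved, previous, alias, withdrawn) — one string may
legitimately resolve to several ids.

## Worked example

Everything below runs offline: the generator emits records, a gold
standard, and a scripted backend that replays ideal model answers.

```r
library(bsnermap)

onto    <- make_mini_ontology(seed = 7)
index   <- build_index(onto$terms)
fx      <- make_records(fixture_spec(n_records = 60, seed = 7), onto)
backend <- scripted_backend(fx$responses)

mappings <- run_cellline_pipeline(fx$records, index, backend)
table(vapply(mappings, `[[`, character(1), "status"))
#>       MAPPED NO_CELL_LINE
#>           30           30

compute_metrics(score_mappings(mappings, fx$gold))
#> Cell line accuracy:       1.000   (30/30)
#> Cell line coverage:       1.000   (denominator: with-term)
#> Non-cell line precision:  1.000   (30/30)
#> Non-cell line recall:     1.000   (gold non-cell lines: 30)

# conservative baseline: match only whitelisted cell line / cell type keys
compute_metrics(score_mappings(run_keyrestricted_pipeline(fx$records, index),
                               fx$gold))
#> Cell line accuracy:       0.824   (14/17)
#> Cell line coverage:       0.467   (denominator: with-term)
#> Non-cell line precision:  0.698   (30/43)
#> Non-cell line recall:     1.000   (gold non-cell lines: 30)
```

With ideal answers the full pipeline is perfect by construction; the
key-restricted baseline keeps recall on non-cell-lines but loses half the
cell-line coverage, because many generated records store the line name
under keys like `source_name` — the accuracy-versus-coverage trade-off that
motivates putting a language model in front of the matcher.

The audit tools quantify attribute heterogeneity directly:

```r
find_attributes_by_value(fx$records, "H1", mode = "substring")
#> # A tibble: 4 × 3
#>   attribute_key n_projects n_samples
#> 1 description           12        12
#> 2 title                  3         3
#> 3 cell line              2         2
#> 4 cell_line              1         1
```

`"H1"` shows up in descriptions and titles far more often than in cell-line
attributes — exactly why containment scans cannot be trusted on short
names.

A command-line interface wraps every stage
(`inst/exec/bsnermap`): `fixtures make`, `index`, `cellline run`,
`disambiguate`, `genes run`, `genes map`, `evaluate`, `audit`, with
JSON-lines interchange files and an optional run manifest.

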