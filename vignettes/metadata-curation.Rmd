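---
title: "Curating BioSample metadata with a language-model-assisted pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating BioSample metadata with a language-model-assisted pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsnermap)
```

## The problem

BioSample stores experimental sample metadata as free-form key–value
attribute pairs. Submitters describe the same concept under wildly different
keys — a single well-known cell line value can appear under dozens of
attribute names (`cell line`, `cell_line`, `source_name`, `isolate`,
`strain`, ...) — and attribute values mix genuine sample descriptors with
procedural free text. Rule-based mappers that only trust whitelisted keys
(`cell line` / `cell type`) are precise but blind to everything recorded
elsewhere; naive string scanning over all values is drowned by homonyms
(`"H1"` names an embryonic stem cell line, a histone, and plate wells) and
by words used in a negative or procedural context (a description mentioning
*seeds* and *leaf* does not make the sample a seed).

`bsnermap` implements a pipeline that uses a text-generation model for the
two steps that need language understanding — deciding whether a sample *is*
a cell line and extracting its name; choosing among identically named
ontology terms — while keeping the ontology mapping itself deterministic
and rule-based. Everything is testable offline through a scripted backend
that plays back pre-authored model replies.

## Pipeline

For each record:

1. **Extraction.** The record's attributes are serialized as one JSON
   object and embedded in an instruction prompt that defines cell lines,
   fixes the output contract `{"cell_line": "NAME"}`, and provides the
   escape hatch `{"cell_line": "None"}`. A reasoning directive
   ("think step by step") is appended after the payload; replies may
   therefore contain prose, and the parser takes the *last* syntactically
   valid JSON value of the expected shape.
2. **Ontology matching.** The extracted name is treated as the value of a
   derived `cell_line` attribute and resolved against a Cellosaurus index
   through a normalization ladder: verbatim → case-folded →
   delimiters (`_`, `-`) replaced by spaces → both. Matching stops at the
   first ladder level with any hit; all hits at that level are returned.
   Length-1 and length-2 strings are indexed and searchable without
   restriction, because over-matching is filtered by the selection stage
   rather than by excluding short queries.
3. **Disambiguation.** If several terms share the name, each candidate's
   annotations (name, scoped synonyms, diseases, cell-line category, sex)
   are serialized as JSON and presented with the sample; the model returns
   one term id or `"not unique"`. A returned id outside the candidate set is
   treated as a hallucination and recorded as unparseable — the pipeline
   never accepts a term it did not propose.

Each record ends in exactly one status: `MAPPED`, `NOT_UNIQUE`,
`NO_CELL_LINE`, `UNMAPPED_NAME`, or `UNPARSEABLE`.

A parallel task extracts experimentally modulated genes: the gene prompt
defines knockout / knockdown / overexpression vocabulary and requests a JSON
array of `{"gene", "method"}` objects (an empty array when nothing is
modulated). Method strings are canonicalized case-insensitively
(knockout ∈ {knockout, KO, -/-, deletion}; knockdown ∈ {knockdown, KD,
shRNA, siRNA, RNAi, si\<GENE\>}; overexpression ∈ {overexpression, OE,
transfection, transduction}; anything else passes through verbatim, e.g.
`dTAG`), and gene symbols are resolved case-insensitively against all HGNC
symbol classes at once (approved, previous, alias, withdrawn), which can
legitimately yield multiple ids for one string.

## Prompt conventions

The three prompt preambles are frozen package constants and hash-checked in
the test suite; they are part of the recorded experimental conditions, down
to a historical "trasfection" misspelling that is preserved intact. Two
framing choices were genuinely open and are resolved as follows:

* the reasoning directive is appended after the JSON payload on a single
  user turn (the printed prompts end with "Are you ready?", so "end of the
  prompt" is ambiguous); no multi-turn handshake is simulated;
* the selection payload is one JSON object
  `{"sample": <attributes>, "terms": [<term contexts>]}`, keeping the
  payload a single valid JSON value while carrying both the sample JSON the
  prompt refers to and the appended candidate annotations.

Duplicate attribute keys — legal in BioSample, illegal in JSON objects —
are suffixed `#2`, `#3`, ... in payloads so the repetition stays visible.

## Evaluation

Against a gold standard labelling each accession as a cell line (with its
Cellosaurus term), a cell line with no term, or not a cell line, four
metrics are computed:

* **cell-line accuracy** — correct mappings / all outputs that mapped to a
  cell line (a `NOT_UNIQUE` output counts as a mapping attempt and is
  incorrect even when the right term is among the candidates);
* **cell-line coverage** — correct mappings / gold cell-line entries;
* **non-cell-line precision** — correct non-mapping outputs / all
  non-mapping outputs;
* **non-cell-line recall** — correct non-mapping outputs / gold
  non-cell-line entries.

Zero-denominator ratios are reported as absent, never as 0. Two conventions
are deliberately configurable because the bucketing of term-less cell-line
golds is not uniquely determined: the coverage denominator (`with-term`,
the default — entries a mapper could possibly get right — or
`all-cellline`) and the judgment of non-mapping outputs on term-less golds
(`noncellline_incorrect` by default, or `excluded`). Reports are emitted
pooled and stratified by experiment type (ChIP-seq vs ATAC-seq).

## What the synthetic generator emulates — and what it does not

`fixture_spec()` defaults encode the study conditions this package targets:
600 records (300 per experiment type), a 0.5 cell-line fraction, a 0.05
homonym fraction (matching the observed rate of multi-candidate samples,
26/600), and a 0.2 distractor fraction. Cell-line records draw their
attribute key from the measured key-variant distribution (weights 667:435:
338:88:33:20:7:6 for `cell line`, `cell_line`, `source_name`, `isolate`,
`cell type`, `strain`, `cell_type`, `tissue`), with at least one record
forced onto `source_name` so the key-restricted baseline provably loses
coverage. Distractor records embed ontology labels inside procedural
protocol text and ChIP antibody names. The mini ontology (50–200 terms;
generation is capped there to keep the brute-force oracle cheap) carries
per-term synonym structure in the Cellosaurus style — delimiter variants as
RELATED synonyms, a case variant as EXACT — plus one `"H1"` homonym pair,
and since 300 cell-line records draw from fewer than 200 terms, terms recur
across records. Term-less cell lines (`CELL_LINE_NO_TERM`) are absent from
generated gold standards by default, so an ideal backend can reach all four
metrics = 1.0 by construction.

The scripted backend replays *ideal* answers. Passing end-to-end tests
therefore demonstrates that the plumbing around the model — prompt
rendering, reply parsing, matching, disambiguation bookkeeping, scoring —
is correct and deterministic; it says nothing about how well any actual
language model extracts names from real metadata, and the generator makes
no attempt to model real extraction errors (derivative cell lines,
overlooked names, noncanonical names). Those failure modes are represented
only as storable human error-category annotations.

## Numerical and design choices

* Unicode: values are preserved verbatim at parse time; only the matcher
  case-folds (full Unicode lowercasing, no transliteration — Greek-letter
  gene names stay Greek and typically fail HGNC resolution, which is
  reported, not repaired).
* The matcher ladder stops at the first level with hits; whether hits from
  all levels should pool is unspecified upstream, and first-hit semantics
  keep results deterministic and testable against a brute-force oracle.
* An edit-distance-1 fallback exists behind a flag and is off by default.
* Candidates sharing a term id through different synonyms count once;
  match classes rank name > exact synonym > related synonym for reporting.
* `"None"` from the extraction prompt is matched case-insensitively.
* Seeded generators save and restore the global RNG state, so fixtures are
  byte-identical per seed and leave callers' randomness untouched.
* Attribute audits count samples per record (a duplicated key within one
  record counts once) and projects on a per-project basis; records without
  a project form singleton groups.

## Limitations

* The HTTP generation backend (Ollama-style `/api/generate`) is untested
  plumbing for interactive use; all tested paths use the scripted backend.
* Only cell lines are mapped — no tissue, cell-type, or disease mapping.
* Gene-extraction correctness is judged by humans in the workflow this
  package supports; the package records and resolves extractions but does
  not auto-judge them. Fusion-gene notation passes through unmodified and
  is flagged, not resolved.
* Re-scoring externally deposited prediction sets is supported through
  `read_gold_standard()` + `score_mappings()` + `compute_metrics()` (or the
  `evaluate` subcommand), but no downloader is bundled.
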