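# Shared in-code fixtures: a worked ontology term, tiny term sets, and
# small record/backeend builders. Everything is constructed programmatically
# so no binary fixtures are needed.

cvcl_4719_term <- function() {
  ontology_term("CVCL:4719", "S-2",
                exact_synonyms = "s-2",
                related_synonyms = c("S 2", "S2"),
                diseases = "Lung small cell carcinoma",
                cell_line_type = "Cancer_cell_line",
                sex = "Male")
}

tiny_terms <- function() {
  list(
    `CVCL:4719` = cvcl_4719_term(),
    `CVCL:0001` = ontology_term("CVCL:0001", "HeLa",
                                related_synonyms = c("Hela", "He La"),
                                diseases = "Cervical adenocarcinoma",
                                cell_line_type = "Cancer_cell_line",
                                sex = "Female"),
    `CVCL:0100` = ontology_term("CVCL:0100", "H1",
                                related_synonyms = "WA01",
                                cell_line_type = "Embryonic_stem_cell",
                                sex = "Male"),
    `CVCL:0101` = ontology_term("CVCL:0101", "H1",
                                related_synonyms = "H-1",
                                diseases = "Hepatoblastoma",
                                cell_line_type = "Cancer_cell_line",
                                sex = "Female")
  )
}

tiny_index <- function() build_index(tiny_terms())

# Table-layout flat-JSON record for a knocked-down/transfected ATAC sample
g401_record_json <- function() {
  paste0('{"accession":"SAMN08370440","cell line":"G401",',
         '"passage":"ten-thirty","source_name":"MRT cells",',
         '"title":"ATAC-seq OMOMYC rep3","transfection":"OMOMYC"}')
}

# `.accession` is dot-prefixed so short attribute keys passed through `...`
# (e.g. a = "1") cannot partially match it
make_record <- function(.accession = "S1", ..., project_id = NA_character_) {
  kv <- list(...)
  sample_record(.accession, names(kv), unlist(kv, use.names = FALSE),
                project_id = project_id)
}

oracle_backend <- function(...) scripted_backend(list(...))

# brute-force matcher used as the independent oracle in matcher tests;
# mirrors the ladder semantics by scanning every term's full label-variant
# set (computed once per term, no index involved)
brute_oracle <- function(terms) {
  variant_sets <- lapply(terms, function(term) {
    labels <- c(term$name, term$exact_synonyms, term$related_synonyms)
    labels <- labels[nzchar(trimws(labels))]
    unique(unlist(lapply(labels, normalize_string), use.names = FALSE))
  })
  ids <- vapply(terms, `[[`, character(1), "id")
  function(query) {
    for (v in normalize_string(query)) {
      hit <- vapply(variant_sets, function(vs) v %in% vs, logical(1))
      if (any(hit)) return(sort(unique(ids[hit])))
    }
    character()
  }
}

brute_match_ids <- function(terms, query) brute_oracle(terms)(query)
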