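#' Extract experimentally modulated genes from a record
#'
#' Renders the gene-modulation prompt, invokes the backend, and parses the
#' JSON array of `{"gene": ..., "method": ...}` objects. An empty array is a
#' valid answer (no modulation described); multiple modulations per sample
#' are permitted, including the same gene under two methods (e.g. a knockout
#' rescued by an overexpressed cDNA).
#'
#' @inheritParams extract_cell_line
#' @return Tibble with columns `accession`, `gene`, `method` (zero rows when
#'   nothing is modulated); attribute `unparseable` is `TRUE` when no
#'   conforming JSON array was found, in which case the sample is skipped
#'   downstream.
#' @export
extract_gene_modulations <- function(record, backend, config = backend_config()) {
  bundle <- render_prompt("gene_extraction", record)
  resp <- invoke_backend(backend, bundle, config)
  parsed <- parse_response_json(resp$raw_text, "array_of_gene_method")
  if (parsed$status != "ok") {
    out <- tibble::tibble(accession = character(), gene = character(),
                          method = character())
    attr(out, "unparseable") <- TRUE
    attr(out, "raw_response") <- resp$raw_text
    return(out)
  }
  out <- tibble::tibble(
    accession = rep(record$accession, length(parsed$value)),
    gene = vapply(parsed$value, `[[`, character(1), "gene"),
    method = vapply(parsed$value, `[[`, character(1), "method")
  )
  attr(out, "unparseable") <- FALSE
  attr(out, "raw_response") <- resp$raw_text
  out
}

#' Run gene extraction over a batch of records
#'
#' @param records List of [sample_record()] objects.
#' @inheritParams extract_cell_line
#' @param canonicalize Apply [canonicalize_method()] to the extracted method
#'   strings (default `TRUE`).
#' @return Tibble of all modulations; unparseable samples are listed in the
#'   `unparseable_accessions` attribute.
#' @export
run_gene_pipeline <- function(records, backend, config = backend_config(),
                              canonicalize = TRUE) {
  pieces <- list()
  bad <- character()
  for (record in records) {
    mods <- extract_gene_modulations(record, backend, config)
    if (isTRUE(attr(mods, "unparseable"))) {
      bad <- c(bad, record$accession)
    } else if (nrow(mods) > 0) {
      pieces[[length(pieces) + 1L]] <- mods
    }
  }
  out <- if (length(pieces)) dplyr::bind_rows(pieces) else
    tibble::tibble(accession = character(), gene = character(), method = character())
  if (canonicalize && nrow(out) > 0) {
    out$method <- vapply(out$method, canonicalize_method, character(1),
                         USE.NAMES = FALSE)
  }
  attr(out, "unparseable_accessions") <- bad
  out
}

# Synonym vocabularies for the three canonical modulation methods. Matching
# is case-insensitive; anything not in a set passes through verbatim (e.g.
# "dTAG", "degron", inhibitor names).
.METHOD_SYNONYMS <- list(
  knockout = c("knockout", "ko", "-/-", "deletion"),
  knockdown = c("knockdown", "kd", "shrna", "sirna", "rnai"),
  overexpression = c("overexpression", "oe", "transfection", "transduction")
)

#' Canonicalize a gene-modulation method name
#'
#' Maps the many surface forms of the three major modulation methods to
#' canonical labels: knockout (`"knockout"`, `"KO"`, `"-/-"`,
#' `"deletion"`), knockdown (`"knockdown"`, `"KD"`, `"shRNA"`, `"siRNA"`,
#' `"RNAi"`, and `si<GENE>` forms such as `"siTP53"`), overexpression
#' (`"overexpression"`, `"OE"`, `"transfection"`, `"transduction"`).
#' Membership is case-insensitive. Any other method string is returned
#' verbatim. The function is idempotent.
#'
#' @param raw_method Non-empty method string.
#' @return Canonical label or the input unchanged.
#' @export
canonicalize_method <- function(raw_method) {
  if (!is.character(raw_method) || length(raw_method) != 1L ||
      is.na(raw_method) || !nzchar(raw_method)) {
    stop("raw_method must be a non-empty string", call. = FALSE)
  }
  folded <- stringi::stri_trans_tolower(stringi::stri_trim_both(raw_method))
  for (canon in names(.METHOD_SYNONYMS)) {
    if (folded %in% .METHOD_SYNONYMS[[canon]]) return(canon)
  }
  # si<GENE>: lowercase "si" prefix followed by an uppercase-led gene token
  if (stringi::stri_detect_regex(stringi::stri_trim_both(raw_method),
                                 "^si[A-Z0-9][A-Za-z0-9.-]*$")) {
    return("knockdown")
  }
  raw_method
}

#' Extract the gene hinted by an si<GENE> method string
#'
#' `"siTP53"` hints at the gene `TP53`. Off by default in the pipeline: the
#' hint is only for consumers that want a fallback when the extraction named
#' the method but not the gene.
#' @param raw_method Method string.
#' @return The stripped gene token, or `NA_character_`.
#' @export
si_gene_hint <- function(raw_method) {
  m <- stringi::stri_match_first_regex(stringi::stri_trim_both(raw_method),
                                       "^si([A-Z0-9][A-Za-z0-9.-]*)$")
  m[1, 2]
}

#' Load an HGNC symbol table
#'
#' Consumes the standard HGNC complete-set TSV layout. Required columns:
#' `hgnc_id`, `symbol`, `status`; multi-valued columns `alias_symbol` and
#' `prev_symbol` are pipe-separated. Every symbol of every class (approved,
#' previous, alias, withdrawn) is indexed under its case-folded form; one
#' symbol string may map to several ids. Rows whose status is not
#' `"Approved"` contribute their symbol to the withdrawn class (trailing
#' `~withdrawn` markers are stripped).
#'
#' @param path TSV file path.
#' @return An object of class `bsn_hgnc` wrapping the case-folded lookup.
#' @export
load_hgnc_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("hgnc_id", "symbol", "status")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("HGNC table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("alias_symbol", "prev_symbol")) {
    if (!col %in% names(tab)) tab[[col]] <- ""
  }
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  add <- function(symbol, id, class) {
    symbol <- stringi::stri_trim_both(symbol)
    if (!nzchar(symbol)) return(invisible())
    key <- stringi::stri_trans_tolower(symbol)
    lookup[[key]] <- c(lookup[[key]], list(list(hgnc_id = id, class = class)))
  }
  split_multi <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    stringi::stri_trim_both(strsplit(x, "|", fixed = TRUE)[[1]])
  }
  for (i in seq_len(nrow(tab))) {
    id <- tab$hgnc_id[i]
    approved <- tab$status[i] == "Approved"
    sym <- sub("~withdrawn$", "", tab$symbol[i])
    add(sym, id, if (approved) "approved" else "withdrawn")
    for (s in split_multi(tab$prev_symbol[i])) add(s, id, "previous")
    for (s in split_multi(tab$alias_symbol[i])) add(s, id, "alias")
  }
  structure(list(lookup = lookup, table = tibble::as_tibble(tab)),
            class = "bsn_hgnc")
}

.GENE_CLASS_RANK <- c(approved = 1L, previous = 2L, alias = 3L, withdrawn = 4L)

#' Resolve a gene symbol against the HGNC index
#'
#' Case-insensitive lookup across all symbol classes simultaneously, as the
#' multi-symbol checker does with every class enabled. One distinct id is a
#' `UNIQUE` resolution (with `matched_via` reporting the best class,
#' approved > previous > alias > withdrawn); two or more ids are `MULTIPLE`
#' (gene symbols are unique among approved names but not among synonyms);
#' none is `UNMAPPED` (typical for non-human constructs such as GFP, and
#' for fusion notation like `"A::B"`, which passes through unmodified).
#'
#' @param hgnc A [load_hgnc_table()] result.
#' @param symbol Non-empty gene symbol.
#' @return List of class `bsn_gene_mapping`: `input_symbol`, `status`
#'   (`"UNIQUE"`, `"MULTIPLE"`, `"UNMAPPED"`), `hgnc_ids`, `matched_via`,
#'   `is_fusion_notation`.
#' @export
map_gene_symbol <- function(hgnc, symbol) {
  stopifnot(inherits(hgnc, "bsn_hgnc"))
  if (!is.character(symbol) || length(symbol) != 1L || !nzchar(symbol)) {
    stop("symbol must be a non-empty string", call. = FALSE)
  }
  entries <- hgnc$lookup[[stringi::stri_trans_tolower(stringi::stri_trim_both(symbol))]]
  fusion <- stringi::stri_detect_regex(symbol, "::") ||
    stringi::stri_detect_regex(symbol, "^[A-Za-z0-9]+-[A-Za-z0-9]+$") &&
    is.null(entries)
  if (is.null(entries)) {
    return(structure(list(input_symbol = symbol, status = "UNMAPPED",
                          hgnc_ids = character(), matched_via = NA_character_,
                          is_fusion_notation = isTRUE(fusion)),
                     class = "bsn_gene_mapping"))
  }
  ids <- unique(vapply(entries, `[[`, character(1), "hgnc_id"))
  classes <- vapply(entries, `[[`, character(1), "class")
  best <- names(sort(.GENE_CLASS_RANK[unique(classes)]))[1]
  structure(list(
    input_symbol = symbol,
    status = if (length(ids) == 1L) "UNIQUE" else "MULTIPLE",
    hgnc_ids = ids,
    matched_via = if (length(ids) == 1L) best else NA_character_,
    is_fusion_notation = FALSE
  ), class = "bsn_gene_mapping")
}

#' Resolve all extracted modulations
#'
#' Every extracted modulation appears in the report exactly once; nothing is
#' silently dropped.
#'
#' @param hgnc A [load_hgnc_table()] result.
#' @param modulations Tibble from [run_gene_pipeline()] (columns `accession`,
#'   `gene`, `method`).
#' @return Tibble with one row per modulation: `accession`, `gene`, `method`,
#'   `status`, `hgnc_ids` (comma-joined), `matched_via`, `is_fusion_notation`.
#' @export
map_gene_modulations <- function(hgnc, modulations) {
  if (nrow(modulations) == 0) {
    return(tibble::tibble(accession = character(), gene = character(),
                          method = character(), status = character(),
                          hgnc_ids = character(), matched_via = character(),
                          is_fusion_notation = logical()))
  }
  maps <- lapply(modulations$gene, function(g) map_gene_symbol(hgnc, g))
  tibble::tibble(
    accession = modulations$accession,
    gene = modulations$gene,
    method = modulations$method,
    status = vapply(maps, `[[`, character(1), "status"),
    hgnc_ids = vapply(maps, function(m) paste(m$hgnc_ids, collapse = ","), character(1)),
    matched_via = vapply(maps, `[[`, character(1), "matched_via"),
    is_fusion_notation = vapply(maps, `[[`, logical(1), "is_fusion_notation")
  )
}
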