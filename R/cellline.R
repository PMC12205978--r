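#' Extract a cell-line name from a sample record
#'
#' Renders the extraction prompt with the record's attributes as the JSON
#' payload, invokes the backend, and parses the `{"cell_line": ...}` reply.
#' The `"None"` answer (matched case-insensitively) is the explicit
#' not-a-cell-line sentinel.
#'
#' @param record A [sample_record()].
#' @param backend A backend object ([scripted_backend()] or
#'   [http_generation_backend()]).
#' @param config A [backend_config()].
#' @return List of class `bsn_extraction`: `accession`, `extracted_name`
#'   (character or `NA`), `is_none`, `unparseable`, `raw_response`.
#' @export
extract_cell_line <- function(record, backend, config = backend_config()) {
  bundle <- render_prompt("cell_line_extraction", record)
  resp <- invoke_backend(backend, bundle, config)
  parsed <- parse_response_json(resp$raw_text, "object_with_cell_line")
  out <- list(accession = record$accession, extracted_name = NA_character_,
              is_none = FALSE, unparseable = FALSE, raw_response = resp$raw_text)
  if (parsed$status != "ok") {
    out$unparseable <- TRUE
  } else {
    name <- parsed$value[["cell_line"]]
    if (stringi::stri_trans_tolower(name) == "none") {
      out$is_none <- TRUE
    } else {
      out$extracted_name <- name
    }
  }
  structure(out, class = "bsn_extraction")
}

.MAPPING_STATUSES <- c("MAPPED", "NOT_UNIQUE", "NO_CELL_LINE", "UNMAPPED_NAME",
                       "UNPARSEABLE")

.new_mapping <- function(accession, status, term_id = NA_character_,
                         candidates = NULL, extracted_name = NA_character_,
                         selection_response = NA_character_,
                         provisional = FALSE) {
  status <- match.arg(status, .MAPPING_STATUSES)
  if (is.null(candidates)) candidates <- .candidates_tibble(list(), NA_character_)
  structure(
    list(accession = accession, status = status, term_id = term_id,
         candidates = candidates, extracted_name = extracted_name,
         selection_response = selection_response, provisional = provisional),
    class = "bsn_mapping"
  )
}

#' @export
print.bsn_mapping <- function(x, ...) {
  cat("<bsn_mapping> ", x$accession, ": ", x$status,
      if (!is.na(x$term_id)) paste0(" -> ", x$term_id) else "",
      if (isTRUE(x$provisional)) " (provisional)" else "", "\n", sep = "")
  invisible(x)
}

#' Map an extracted name to ontology terms
#'
#' The extracted name is treated as the value of a derived `cell_line`
#' attribute and matched against the index; the original record is never
#' mutated. The not-a-cell-line sentinel maps to `NO_CELL_LINE`; zero
#' candidates to `UNMAPPED_NAME`; one distinct term to `MAPPED`; two or more
#' distinct terms to a provisional `NOT_UNIQUE` awaiting [disambiguate()].
#'
#' @param extraction An [extract_cell_line()] result.
#' @param index A [build_index()] result.
#' @return A `bsn_mapping`.
#' @export
map_extraction <- function(extraction, index) {
  stopifnot(inherits(extraction, "bsn_extraction"))
  acc <- extraction$accession
  if (isTRUE(extraction$unparseable)) {
    return(.new_mapping(acc, "UNPARSEABLE"))
  }
  if (isTRUE(extraction$is_none)) {
    return(.new_mapping(acc, "NO_CELL_LINE"))
  }
  name <- extraction$extracted_name
  candidates <- match_string(index, name)
  n <- length(unique(candidates$term_id))
  if (n == 0L) {
    .new_mapping(acc, "UNMAPPED_NAME", extracted_name = name)
  } else if (n == 1L) {
    .new_mapping(acc, "MAPPED", term_id = candidates$term_id[1],
                 candidates = candidates, extracted_name = name)
  } else {
    .new_mapping(acc, "NOT_UNIQUE", candidates = candidates,
                 extracted_name = name, provisional = TRUE)
  }
}

#' Disambiguate a homonymous cell-line name
#'
#' When several ontology terms share the extracted name, the selection
#' prompt presents each candidate's annotations ([term_context_json()])
#' alongside the sample JSON and asks for the single best term id, or
#' `"not unique"` to withhold judgment. A returned id outside the candidate
#' set is treated as an unparseable hallucination and retained verbatim for
#' inspection -- the pipeline never accepts a term it did not propose.
#'
#' @param mapping A provisional `NOT_UNIQUE` mapping from [map_extraction()].
#' @param record The originating [sample_record()].
#' @param index A [build_index()] result.
#' @inheritParams extract_cell_line
#' @return A final `bsn_mapping` (`MAPPED`, `NOT_UNIQUE`, or `UNPARSEABLE`).
#' @export
disambiguate <- function(mapping, record, index, backend,
                         config = backend_config()) {
  stopifnot(inherits(mapping, "bsn_mapping"))
  if (!(mapping$status == "NOT_UNIQUE" && isTRUE(mapping$provisional))) {
    stop("disambiguate() expects a provisional NOT_UNIQUE mapping", call. = FALSE)
  }
  ids <- unique(mapping$candidates$term_id)
  contexts <- vapply(ids, function(id) term_context_json(index$term_store[[id]]),
                     character(1))
  bundle <- render_prompt("cell_line_selection",
                          list(cell_line = mapping$extracted_name,
                               contexts = unname(contexts), record = record))
  resp <- invoke_backend(backend, bundle, config)
  parsed <- parse_response_json(resp$raw_text, "object_with_cell_line_id")
  out <- mapping
  out$provisional <- FALSE
  out$selection_response <- resp$raw_text
  if (parsed$status != "ok") {
    out$status <- "UNPARSEABLE"
    return(out)
  }
  chosen <- parsed$value[["cell_line_id"]]
  if (identical(stringi::stri_trans_tolower(chosen), "not unique")) {
    out$status <- "NOT_UNIQUE"
  } else if (chosen %in% ids) {
    out$status <- "MAPPED"
    out$term_id <- chosen
  } else {
    out$status <- "UNPARSEABLE"
  }
  out
}

#' Run the full cell-line mapping pipeline
#'
#' Per record: extract the cell-line name, match it against the ontology
#' index, and disambiguate homonyms through the selection prompt. Per-sample
#' failures (unparseable replies) never abort the batch; a hard backend
#' failure stops with the completed prefix attached to the error condition.
#' Output order matches input order.
#'
#' @param records List of [sample_record()] objects.
#' @param index A [build_index()] result.
#' @inheritParams extract_cell_line
#' @return List of `bsn_mapping` objects, one per record.
#' @export
run_cellline_pipeline <- function(records, index, backend,
                                  config = backend_config()) {
  out <- vector("list", length(records))
  for (i in seq_along(records)) {
    record <- records[[i]]
    mapping <- tryCatch({
      extraction <- extract_cell_line(record, backend, config)
      m <- map_extraction(extraction, index)
      if (m$status == "NOT_UNIQUE" && isTRUE(m$provisional)) {
        m <- disambiguate(m, record, index, backend, config)
      }
      m
    }, error = function(e) {
      cond <- simpleError(paste0("backend failure at record ", record$accession,
                                 " (", i, "/", length(records), "): ",
                                 conditionMessage(e)))
      cond$partial <- out[seq_len(i - 1L)]
      stop(cond)
    })
    out[[i]] <- mapping
  }
  out
}

#' Key-restricted conservative matcher
#'
#' A rule-based baseline in the style of conservative metadata mappers:
#' only attributes whose key is one of the whitelisted cell-line/cell-type
#' names are considered, and their verbatim values are matched against the
#' index with no language-model stage. High precision, limited coverage --
#' cell lines recorded under nonstandard keys (e.g. `source_name`) are
#' missed by construction.
#'
#' @param records List of [sample_record()] objects.
#' @param index A [build_index()] result.
#' @param keys Attribute keys eligible for matching.
#' @return List of `bsn_mapping` objects.
#' @export
run_keyrestricted_pipeline <- function(records, index,
                                       keys = c("cell line", "cell_line",
                                                "cell type", "cell_type")) {
  lapply(records, function(record) {
    attrs <- record$attributes
    eligible <- attrs[attrs$key %in% keys, , drop = FALSE]
    for (i in seq_len(nrow(eligible))) {
      value <- eligible$value[i]
      if (!nzchar(stringi::stri_trim_both(value))) next
      candidates <- match_string(index, value)
      n <- length(unique(candidates$term_id))
      if (n == 1L) {
        return(.new_mapping(record$accession, "MAPPED",
                            term_id = candidates$term_id[1],
                            candidates = candidates, extracted_name = value))
      }
      if (n >= 2L) {
        return(.new_mapping(record$accession, "NOT_UNIQUE",
                            candidates = candidates, extracted_name = value))
      }
    }
    .new_mapping(record$accession, "NO_CELL_LINE")
  })
}

#' Tabulate mappings
#' @param mappings List of `bsn_mapping` objects.
#' @return Tibble with one row per mapping.
#' @export
mappings_to_tibble <- function(mappings) {
  tibble::tibble(
    accession = vapply(mappings, `[[`, character(1), "accession"),
    status = vapply(mappings, `[[`, character(1), "status"),
    term_id = vapply(mappings, `[[`, character(1), "term_id"),
    extracted_name = vapply(mappings, `[[`, character(1), "extracted_name"),
    n_candidates = vapply(mappings, function(m) length(unique(m$candidates$term_id)),
                          integer(1))
  )
}

#' Write / read mappings as JSON-lines
#'
#' One JSON object per record in input order; candidate trails and the raw
#' selection response are preserved, so a rerun with the same scripted
#' backend reproduces the file byte for byte.
#' @param mappings List of `bsn_mapping` objects.
#' @param path File path.
#' @export
write_mappings_jsonl <- function(mappings, path) {
  lines <- vapply(mappings, function(m) {
    obj <- list(
      accession = jsonlite::unbox(m$accession),
      status = jsonlite::unbox(m$status),
      term_id = jsonlite::unbox(m$term_id),
      extracted_name = jsonlite::unbox(m$extracted_name),
      candidates = lapply(seq_len(nrow(m$candidates)), function(i) {
        list(term_id = jsonlite::unbox(m$candidates$term_id[i]),
             matched_label = jsonlite::unbox(m$candidates$matched_label[i]),
             match_class = jsonlite::unbox(m$candidates$match_class[i]),
             normalization = jsonlite::unbox(m$candidates$normalization[i]))
      }),
      selection_response = jsonlite::unbox(m$selection_response)
    )
    as.character(jsonlite::toJSON(obj, null = "null", na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_mappings_jsonl
#' @export
read_mappings_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    cands <- if (length(obj$candidates)) {
      tibble::tibble(
        term_id = vapply(obj$candidates, function(c) c$term_id %||% NA_character_, character(1)),
        matched_label = vapply(obj$candidates, function(c) c$matched_label %||% NA_character_, character(1)),
        match_class = vapply(obj$candidates, function(c) c$match_class %||% NA_character_, character(1)),
        normalization = vapply(obj$candidates, function(c) c$normalization %||% NA_character_, character(1))
      )
    } else NULL
    .new_mapping(obj$accession, obj$status,
                 term_id = obj$term_id %||% NA_character_,
                 candidates = cands,
                 extracted_name = obj$extracted_name %||% NA_character_,
                 selection_response = obj$selection_response %||% NA_character_)
  })
}
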