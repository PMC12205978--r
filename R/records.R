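#' Construct a BioSample record
#'
#' A sample record is an accession plus an ordered list of key--value
#' attribute pairs. Duplicate keys are permitted and input order is
#' preserved; keys and values are character strings (possibly empty, never
#' `NA`).
#'
#' @param accession BioSample accession, e.g. `"SAMN08370440"`.
#' @param keys,values Character vectors of equal length with the attribute
#'   keys and values in input order.
#' @param source_dialect One of `"flat-json"`, `"ebi-json"`, `"ncbi-xml"`.
#' @param project_id Optional BioProject / study grouping identifier.
#' @return An object of class `bsn_record`.
#' @export
sample_record <- function(accession, keys = character(), values = character(),
                          source_dialect = "flat-json", project_id = NA_character_) {
  stopifnot(is.character(accession), length(accession) == 1L, !is.na(accession),
            nzchar(accession))
  keys <- unname(as.character(keys))
  values <- unname(as.character(values))
  if (length(keys) != length(values)) {
    stop("keys and values must have equal length", call. = FALSE)
  }
  if (anyNA(keys) || anyNA(values)) {
    stop("attribute keys and values must be non-missing (empty strings are allowed)",
         call. = FALSE)
  }
  structure(
    list(
      accession = accession,
      attributes = tibble::tibble(key = keys, value = values),
      source_dialect = source_dialect,
      project_id = if (is.null(project_id)) NA_character_ else as.character(project_id)[1]
    ),
    class = "bsn_record"
  )
}

#' @export
print.bsn_record <- function(x, ...) {
  cat("<bsn_record> ", x$accession,
      if (!is.na(x$project_id)) paste0(" [", x$project_id, "]") else "",
      "  (", nrow(x$attributes), " attributes, ", x$source_dialect, ")\n", sep = "")
  if (nrow(x$attributes) > 0) {
    print(x$attributes, n = 10)
  }
  invisible(x)
}

# Flatten one parsed flat-JSON object into a record. `accession` is lifted
# out of the attribute set; the project key (default "bioproject_accession")
# sets project_id but stays an attribute, since it is genuine sample metadata.
.record_from_flat <- function(obj, project_key, dialect = "flat-json") {
  keys <- names(obj)
  if (is.null(keys)) keys <- character()
  vals <- vapply(obj, function(v) paste(as.character(unlist(v)), collapse = " "),
                 character(1))
  acc_idx <- which(keys == "accession")
  accession <- if (length(acc_idx)) unname(vals[acc_idx[1]]) else NA_character_
  if (length(acc_idx)) {
    keys <- keys[-acc_idx[1]]
    vals <- vals[-acc_idx[1]]
  }
  if (is.na(accession) || !nzchar(accession)) {
    return(NULL)
  }
  pid <- if (project_key %in% keys) unname(vals[match(project_key, keys)]) else NA_character_
  sample_record(accession, keys, vals, source_dialect = dialect, project_id = pid)
}

.record_from_ebi <- function(obj, project_key) {
  accession <- obj[["accession"]]
  if (is.null(accession) || !nzchar(accession)) return(NULL)
  chars <- obj[["characteristics"]]
  keys <- character()
  vals <- character()
  if (!is.null(chars)) {
    for (k in names(chars)) {
      entry <- chars[[k]]
      # EBI characteristics are arrays of {"text": ...} objects; multi-valued
      # keys flatten to one pair per element, in array order.
      for (el in entry) {
        txt <- if (is.list(el) && !is.null(el[["text"]])) el[["text"]] else el
        keys <- c(keys, k)
        vals <- c(vals, paste(as.character(unlist(txt)), collapse = " "))
      }
    }
  }
  pid <- NA_character_
  if (!is.null(obj[[project_key]])) {
    pid <- as.character(obj[[project_key]])[1]
  } else if (project_key %in% keys) {
    pid <- vals[match(project_key, keys)]
  }
  sample_record(accession, keys, vals, source_dialect = "ebi-json", project_id = pid)
}

#' Parse BioSample records
#'
#' Reads sample metadata in one of three dialects: `flat-json` (one JSON
#' object per record, either a JSON array or JSON-lines; the `accession` key
#' is lifted out, all other keys become attributes), `ebi-json` (EBI
#' BioSamples objects with a nested `characteristics` map whose array values
#' flatten to one pair per element), or `ncbi-xml` (NCBI BioSampleSet XML with
#' `<Attribute attribute_name=...>` elements).
#'
#' Records lacking an accession are rejected with a warning, never silently
#' dropped. Attribute text is preserved as-is (no Unicode normalization).
#'
#' @param input Path to a file, or a character string containing the document.
#' @param dialect `"flat-json"`, `"ebi-json"`, or `"ncbi-xml"`.
#' @param project_key Attribute key holding the project/study identifier used
#'   for project-basis auditing. Default `"bioproject_accession"`.
#' @return A list of [sample_record()] objects.
#' @export
parse_records <- function(input, dialect = c("flat-json", "ebi-json", "ncbi-xml"),
                          project_key = "bioproject_accession") {
  dialect <- match.arg(dialect)
  txt <- .read_input_text(input)
  if (dialect == "ncbi-xml") {
    return(.parse_records_xml(txt, project_key))
  }
  objs <- .parse_json_stream(txt)
  maker <- if (dialect == "flat-json") {
    function(o) .record_from_flat(o, project_key)
  } else {
    function(o) .record_from_ebi(o, project_key)
  }
  recs <- lapply(objs, maker)
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " record(s) without an accession were rejected", call. = FALSE)
  }
  recs <- recs[!bad]
  .check_unique_accessions(recs)
  recs
}

.read_input_text <- function(input) {
  if (length(input) == 1L && !grepl("[\n{<\\[]", input) && file.exists(input)) {
    return(paste(readLines(input, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
  }
  paste(input, collapse = "\n")
}

# Accepts a single JSON value (object or array of objects) or JSON-lines.
.parse_json_stream <- function(txt) {
  trimmed <- stringi::stri_trim_both(txt)
  if (!nzchar(trimmed)) return(list())
  parse1 <- function(s, where) {
    tryCatch(
      jsonlite::fromJSON(s, simplifyVector = FALSE),
      error = function(e) {
        stop("malformed JSON ", where, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  }
  if (startsWith(trimmed, "[")) {
    return(parse1(trimmed, "document"))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(stringi::stri_trim_both(lines))]
  if (length(lines) > 1L) {
    return(lapply(seq_along(lines), function(i) {
      parse1(lines[i], sprintf("(line %d)", i))
    }))
  }
  list(parse1(trimmed, "document"))
}

.parse_records_xml <- function(txt, project_key) {
  doc <- tryCatch(
    xml2::read_xml(txt),
    error = function(e) stop("malformed XML: ", conditionMessage(e), call. = FALSE)
  )
  nodes <- xml2::xml_find_all(doc, ".//BioSample")
  recs <- lapply(nodes, function(node) {
    accession <- xml2::xml_attr(node, "accession")
    if (is.na(accession) || !nzchar(accession)) {
      ids <- xml2::xml_find_first(node, ".//Ids/Id[@db='BioSample']")
      accession <- if (!inherits(ids, "xml_missing")) xml2::xml_text(ids) else NA_character_
    }
    if (is.na(accession) || !nzchar(accession)) return(NULL)
    attrs <- xml2::xml_find_all(node, ".//Attributes/Attribute")
    keys <- xml2::xml_attr(attrs, "attribute_name")
    vals <- xml2::xml_text(attrs)
    keys[is.na(keys)] <- ""
    pid <- NA_character_
    link <- xml2::xml_find_first(node, ".//Links/Link[@target='bioproject']")
    if (!inherits(link, "xml_missing")) pid <- xml2::xml_text(link)
    if (is.na(pid) && project_key %in% keys) pid <- vals[match(project_key, keys)]
    sample_record(accession, keys, vals, source_dialect = "ncbi-xml", project_id = pid)
  })
  bad <- vapply(recs, is.null, logical(1))
  if (any(bad)) {
    warning(sum(bad), " record(s) without an accession were rejected", call. = FALSE)
  }
  recs <- recs[!bad]
  .check_unique_accessions(recs)
  recs
}

.check_unique_accessions <- function(recs) {
  acc <- vapply(recs, function(r) r$accession, character(1))
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in input: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  invisible(recs)
}

#' Serialize records to flat JSON-lines
#'
#' One JSON object per line with the accession first, then every attribute in
#' order. Parsing the output with `parse_records(dialect = "flat-json")`
#' reproduces the attribute sequences exactly. Duplicate keys within a record
#' get `#2`, `#3`, ... suffixes (JSON objects cannot repeat keys); the
#' suffixes are stripped on re-parse by no one -- they are part of the payload
#' convention for prompts, so records intended for round-tripping should not
#' repeat keys.
#'
#' @param records List of [sample_record()] objects.
#' @param path Optional output path; when `NULL` the JSON-lines text is
#'   returned invisibly as a character vector.
#' @export
write_records_jsonl <- function(records, path = NULL) {
  lines <- vapply(records, function(r) {
    keys <- .dedupe_keys(r$attributes$key)
    obj <- c(list(accession = r$accession),
             stats::setNames(as.list(r$attributes$value), keys))
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  invisible(lines)
}

#' Serialize records to a long TSV
#'
#' Columns `accession`, `key`, `value`; one row per attribute occurrence.
#' @inheritParams write_records_jsonl
#' @export
write_records_tsv <- function(records, path = NULL) {
  tab <- dplyr::bind_rows(lapply(records, function(r) {
    if (nrow(r$attributes) == 0) return(NULL)
    tibble::tibble(accession = r$accession,
                   key = r$attributes$key, value = r$attributes$value)
  }))
  if (is.null(tab) || nrow(tab) == 0) {
    tab <- tibble::tibble(accession = character(), key = character(),
                          value = character())
  }
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}

.dedupe_keys <- function(keys) {
  if (!anyDuplicated(keys)) return(keys)
  out <- keys
  counts <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    n <- (counts[[k]] %||% 0L) + 1L
    counts[[k]] <- n
    if (n > 1L) out[i] <- paste0(k, "#", n)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Audit attribute-name usage on a project basis
#'
#' Samples from the same project tend to share attribute layouts, so raw
#' sample counts overweight large projects; usage is therefore counted both
#' per sample and per project. Records without a `project_id` each form their
#' own singleton group.
#'
#' @param records List of [sample_record()] objects.
#' @return A tibble with columns `attribute_key`, `n_projects`, `n_samples`,
#'   sorted by `n_projects` descending, ties by `n_samples` descending then
#'   key ascending. `n_samples` counts records containing the key.
#' @export
audit_attribute_usage <- function(records) {
  occ <- .attribute_occurrences(records)
  if (nrow(occ) == 0) {
    return(tibble::tibble(attribute_key = character(),
                          n_projects = integer(), n_samples = integer()))
  }
  .summarise_usage(occ)
}

.attribute_occurrences <- function(records) {
  dplyr::bind_rows(lapply(records, function(r) {
    if (nrow(r$attributes) == 0) return(NULL)
    pid <- if (is.na(r$project_id)) paste0("..singleton..", r$accession) else r$project_id
    tibble::tibble(accession = r$accession, project = pid,
                   key = r$attributes$key, value = r$attributes$value)
  }))
}

.summarise_usage <- function(occ) {
  out <- occ |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(n_projects = dplyr::n_distinct(.data$project),
                     n_samples = dplyr::n_distinct(.data$accession),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_projects), dplyr::desc(.data$n_samples),
                   .data$key)
  names(out)[1] <- "attribute_key"
  out
}

#' Find attribute keys used with a given value
#'
#' Restricts the usage audit to attribute occurrences whose value equals
#' (`mode = "exact"`) or contains (`mode = "substring"`) the needle. Both
#' modes are case-sensitive: scanning for a short string such as `"H1"` is a
#' containment scan over verbatim values.
#'
#' @inheritParams audit_attribute_usage
#' @param needle Non-empty search string.
#' @param mode `"exact"` or `"substring"`.
#' @return Same shape as [audit_attribute_usage()].
#' @export
find_attributes_by_value <- function(records, needle,
                                     mode = c("exact", "substring")) {
  mode <- match.arg(mode)
  if (!is.character(needle) || length(needle) != 1L || !nzchar(needle)) {
    stop("needle must be a non-empty string", call. = FALSE)
  }
  occ <- .attribute_occurrences(records)
  if (nrow(occ) == 0) {
    return(audit_attribute_usage(list()))
  }
  keep <- if (mode == "exact") {
    occ$value == needle
  } else {
    stringi::stri_detect_fixed(occ$value, needle)
  }
  occ <- occ[keep, , drop = FALSE]
  if (nrow(occ) == 0) return(audit_attribute_usage(list()))
  .summarise_usage(occ)
}
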