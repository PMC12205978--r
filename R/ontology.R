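#' Construct a cell-line ontology term
#'
#' Cellosaurus entries carry a main label, synonyms split into EXACT and
#' RELATED scopes, associated diseases, the cell-line category (e.g.
#' `Cancer_cell_line`), and the sex of the originating individual.
#'
#' @param id CURIE, e.g. `"CVCL:4719"`.
#' @param name Main label (non-empty).
#' @param exact_synonyms,related_synonyms Character vectors (may be empty).
#' @param diseases,cell_line_type,sex Character vectors (may be empty).
#' @return An object of class `bsn_term`.
#' @export
ontology_term <- function(id, name, exact_synonyms = character(),
                          related_synonyms = character(),
                          diseases = character(), cell_line_type = character(),
                          sex = character()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(name), length(name) == 1L, nzchar(name))
  structure(
    list(id = id, name = name,
         exact_synonyms = as.character(exact_synonyms),
         related_synonyms = as.character(related_synonyms),
         diseases = as.character(diseases),
         cell_line_type = as.character(cell_line_type),
         sex = as.character(sex)),
    class = "bsn_term"
  )
}

#' @export
print.bsn_term <- function(x, ...) {
  cat("<bsn_term> ", x$id, "  ", x$name, "\n", sep = "")
  if (length(x$exact_synonyms)) cat("  exact:   ", paste(x$exact_synonyms, collapse = ", "), "\n")
  if (length(x$related_synonyms)) cat("  related: ", paste(x$related_synonyms, collapse = ", "), "\n")
  invisible(x)
}

# Subset labels Cellosaurus uses for sex of the donor; any other subset is
# treated as a cell-line category.
.SEX_SUBSETS <- c("Male", "Female", "Mixed_sex", "Sex_ambiguous", "Sex_unspecified")

#' Load a cell-line ontology from an OBO file
#'
#' A line-based reader for the OBO stanza format as serialized by
#' Cellosaurus: `[Term]` stanzas with `id:`, `name:`,
#' `synonym: "..." EXACT|RELATED []`, `subset:` (sex or cell-line category),
#' `xref: NCIt:... ! disease name` and `is_obsolete: true`. Obsolete terms
#' are dropped. Identifiers are normalized to colon CURIEs
#' (`CVCL_4719` -> `CVCL:4719`).
#'
#' @param path Path to an OBO file.
#' @return Named list of [ontology_term()] objects, keyed by id.
#' @export
load_cellosaurus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  terms <- list()
  cur <- NULL
  cur_line <- 0L
  flush <- function(cur) {
    if (is.null(cur) || isTRUE(cur$obsolete)) return(NULL)
    if (is.null(cur$id)) {
      stop(sprintf("OBO parse error near line %d: [Term] stanza without id", cur$line),
           call. = FALSE)
    }
    if (is.null(cur$name)) {
      stop(sprintf("OBO parse error near line %d: term %s has no name", cur$line, cur$id),
           call. = FALSE)
    }
    ontology_term(cur$id, cur$name,
                  exact_synonyms = cur$exact %||% character(),
                  related_synonyms = cur$related %||% character(),
                  diseases = cur$diseases %||% character(),
                  cell_line_type = cur$type %||% character(),
                  sex = cur$sex %||% character())
  }
  in_term <- FALSE
  for (i in seq_along(lines)) {
    ln <- stringi::stri_trim_both(lines[i])
    if (ln == "[Term]") {
      t <- flush(cur)
      if (!is.null(t)) terms[[t$id]] <- t
      cur <- list(line = i)
      in_term <- TRUE
      next
    }
    if (startsWith(ln, "[")) { # some other stanza type ([Typedef], ...)
      t <- flush(cur)
      if (!is.null(t)) terms[[t$id]] <- t
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln) || startsWith(ln, "!")) next
    colon <- stringi::stri_locate_first_fixed(ln, ": ")[1, 1]
    if (is.na(colon)) {
      stop(sprintf("OBO parse error at line %d: expected 'tag: value', got '%s'", i, ln),
           call. = FALSE)
    }
    tag <- substr(ln, 1L, colon - 1L)
    val <- substr(ln, colon + 2L, nchar(ln))
    if (tag == "id") {
      cur$id <- sub("^CVCL_", "CVCL:", val)
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(stringi::stri_trim_both(val), "true")
    } else if (tag == "synonym") {
      m <- stringi::stri_match_first_regex(val, '^"((?:[^"\\\\]|\\\\.)*)"\\s+(EXACT|RELATED|BROAD|NARROW)')
      if (is.na(m[1, 1])) {
        stop(sprintf("OBO parse error at line %d: unparseable synonym '%s'", i, val),
             call. = FALSE)
      }
      syn <- stringi::stri_replace_all_regex(m[1, 2], "\\\\(.)", "$1")
      if (m[1, 3] == "EXACT") {
        cur$exact <- c(cur$exact, syn)
      } else if (m[1, 3] == "RELATED") {
        cur$related <- c(cur$related, syn)
      } # BROAD/NARROW scopes are not used for matching
    } else if (tag == "subset") {
      if (val %in% .SEX_SUBSETS) cur$sex <- c(cur$sex, val) else cur$type <- c(cur$type, val)
    } else if (tag == "xref") {
      # disease cross-references: "NCIt:C1234 ! Lung small cell carcinoma"
      m <- stringi::stri_match_first_regex(val, "^NCIt:\\S+\\s*!\\s*(.+)$")
      if (!is.na(m[1, 1])) cur$diseases <- c(cur$diseases, stringi::stri_trim_both(m[1, 2]))
    }
  }
  t <- flush(cur)
  if (!is.null(t)) terms[[t$id]] <- t
  terms
}

#' Normalization ladder for query and label strings
#'
#' Produces the ordered variant list `[verbatim, case-folded,
#' delimiters-to-spaces, case-folded delimiters-to-spaces]` with duplicates
#' removed keeping first occurrence. Delimiters replaced are `_` and `-`;
#' runs of whitespace collapse to single spaces; case folding is full
#' Unicode lowercasing (no transliteration -- Greek letters stay Greek).
#'
#' @param s A non-empty string (after trimming).
#' @param labelled If `TRUE`, return a named character vector whose names are
#'   the ladder level of each surviving variant.
#' @return Character vector of 1--4 variants in ladder order.
#' @export
normalize_string <- function(s, labelled = FALSE) {
  stopifnot(is.character(s), length(s) == 1L, !is.na(s))
  squash <- function(x) stringi::stri_trim_both(stringi::stri_replace_all_regex(x, "\\s+", " "))
  v <- squash(s)
  if (!nzchar(v)) stop("cannot normalize an all-whitespace string", call. = FALSE)
  d <- squash(stringi::stri_replace_all_regex(v, "[_-]", " "))
  variants <- c(v, stringi::stri_trans_tolower(v), d, stringi::stri_trans_tolower(d))
  levels <- c("verbatim", "case_fold", "delimiter_space", "case_fold+delimiter_space")
  # delimiter-only strings vanish at the delimiter-replacement level; an
  # empty string is never a usable variant
  keep <- !duplicated(variants) & nzchar(variants)
  out <- variants[keep]
  if (labelled) names(out) <- levels[keep]
  out
}

#' Build the normalized lookup index over ontology terms
#'
#' Every term name and synonym is indexed under all of its normalized
#' variants. Short strings are indexed without restriction: length-1 and
#' length-2 labels (e.g. `"H1"`, `"S2"`) are first-class keys, since
#' over-matching is filtered later by the selection stage rather than by
#' excluding short queries.
#'
#' @param terms Named list of [ontology_term()] objects.
#' @return An object of class `bsn_index` with a hashed `lookup`
#'   environment (normalized string -> list of candidate prototypes) and a
#'   `term_store` (id -> term).
#' @export
build_index <- function(terms) {
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  store <- list()
  for (term in terms) {
    store[[term$id]] <- term
    labels <- c(stats::setNames(term$name, "name"),
                stats::setNames(term$exact_synonyms,
                                rep("exact_synonym", length(term$exact_synonyms))),
                stats::setNames(term$related_synonyms,
                                rep("related_synonym", length(term$related_synonyms))))
    for (j in seq_along(labels)) {
      lab <- labels[[j]]
      cls <- names(labels)[j]
      if (!nzchar(stringi::stri_trim_both(lab))) next
      for (v in normalize_string(lab)) {
        proto <- list(term_id = term$id, matched_label = lab, match_class = cls)
        lookup[[v]] <- c(lookup[[v]], list(proto))
      }
    }
  }
  structure(list(lookup = lookup, term_store = store,
                 format_version = .BSN_INDEX_VERSION),
            class = "bsn_index")
}

.BSN_INDEX_VERSION <- 1L

#' @export
print.bsn_index <- function(x, ...) {
  cat("<bsn_index> ", length(x$term_store), " terms, ",
      length(ls(x$lookup)), " lookup keys\n", sep = "")
  invisible(x)
}

#' Persist / restore a term index
#'
#' The cache carries a format-version header; loading a file with a
#' different version fails with a clear message.
#' @param index A [build_index()] result.
#' @param path Cache file path.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "bsn_index"))
  # environments don't serialize usefully; store the lookup as a named list
  payload <- list(format_version = index$format_version,
                  lookup = as.list(index$lookup),
                  term_store = index$term_store)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt index file '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(payload) || !identical(payload$format_version, .BSN_INDEX_VERSION)) {
    stop("index file '", path, "' has format version ",
         deparse(payload$format_version %||% NULL),
         "; this build reads version ", .BSN_INDEX_VERSION, call. = FALSE)
  }
  lookup <- new.env(parent = emptyenv(), hash = TRUE)
  for (k in names(payload$lookup)) lookup[[k]] <- payload$lookup[[k]]
  structure(list(lookup = lookup, term_store = payload$term_store,
                 format_version = payload$format_version),
            class = "bsn_index")
}

#' Match a free-text string against the term index
#'
#' The query's normalization variants are tried in ladder order
#' (verbatim, case-folded, delimiters-to-spaces, both); all hits at the
#' first ladder level that yields any are returned and later levels are not
#' consulted. Hits are de-duplicated by term id keeping the strongest match
#' class (`name` > `exact_synonym` > `related_synonym`). No hit is an empty
#' result, not an error. An optional edit-distance-1 fallback can be enabled
#' for queries that miss at every ladder level; it is off by default.
#'
#' @param index A [build_index()] result.
#' @param query Non-empty string.
#' @param edit_distance_fallback If `TRUE`, queries with no ladder hit are
#'   retried allowing one single-character edit against the case-folded
#'   delimiter-normalized keys.
#' @return Tibble with columns `term_id`, `matched_label`, `match_class`,
#'   `normalization` (the ladder level that hit); zero rows if no match.
#' @export
match_string <- function(index, query, edit_distance_fallback = FALSE) {
  stopifnot(inherits(index, "bsn_index"))
  if (!is.character(query) || length(query) != 1L || !nzchar(stringi::stri_trim_both(query))) {
    stop("query must be a non-empty string", call. = FALSE)
  }
  variants <- normalize_string(query, labelled = TRUE)
  for (j in seq_along(variants)) {
    protos <- index$lookup[[variants[[j]]]]
    if (!is.null(protos)) {
      return(.candidates_tibble(protos, names(variants)[j]))
    }
  }
  if (edit_distance_fallback) {
    q <- variants[[length(variants)]]
    keys <- ls(index$lookup)
    d <- utils::adist(q, keys)
    hit_keys <- keys[d == 1L]
    if (length(hit_keys)) {
      protos <- unlist(lapply(hit_keys, function(k) index$lookup[[k]]), recursive = FALSE)
      return(.candidates_tibble(protos, "edit_distance_1"))
    }
  }
  .candidates_tibble(list(), NA_character_)
}

.MATCH_CLASS_RANK <- c(name = 1L, exact_synonym = 2L, related_synonym = 3L)

.candidates_tibble <- function(protos, level) {
  if (length(protos) == 0) {
    return(tibble::tibble(term_id = character(), matched_label = character(),
                          match_class = character(), normalization = character()))
  }
  tab <- tibble::tibble(
    term_id = vapply(protos, `[[`, character(1), "term_id"),
    matched_label = vapply(protos, `[[`, character(1), "matched_label"),
    match_class = vapply(protos, `[[`, character(1), "match_class"),
    normalization = level
  )
  tab <- tab[order(.MATCH_CLASS_RANK[tab$match_class]), , drop = FALSE]
  tab[!duplicated(tab$term_id), , drop = FALSE]
}

#' Serialize a term's context for the selection prompt
#'
#' Emits a compact JSON object with exactly the keys `id`, `name`,
#' `related_synonyms`, `exact_synonyms`, `diseases`, `cell line type`, `sex`
#' in that order; list-valued fields are always arrays (empty lists stay
#' `[]`).
#'
#' @param term An [ontology_term()].
#' @return A single JSON string.
#' @export
term_context_json <- function(term) {
  stopifnot(inherits(term, "bsn_term"))
  obj <- list(
    id = jsonlite::unbox(term$id),
    name = jsonlite::unbox(term$name),
    related_synonyms = term$related_synonyms,
    exact_synonyms = term$exact_synonyms,
    diseases = term$diseases,
    `cell line type` = term$cell_line_type,
    sex = term$sex
  )
  as.character(jsonlite::toJSON(obj))
}

#' Parse a term-context JSON string back into a term
#'
#' Inverse of [term_context_json()]; used by round-trip checks and by tools
#' consuming selection-prompt payloads.
#' @param json A JSON string as produced by [term_context_json()].
#' @export
parse_term_context <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  as_chr <- function(x) if (length(x) == 0) character() else as.character(x)
  ontology_term(obj$id, obj$name,
                exact_synonyms = as_chr(obj$exact_synonyms),
                related_synonyms = as_chr(obj$related_synonyms),
                diseases = as_chr(obj$diseases),
                cell_line_type = as_chr(obj$`cell line type`),
                sex = as_chr(obj$sex))
}
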