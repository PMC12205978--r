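.GOLD_LABELS <- c("CELL_LINE", "CELL_LINE_NO_TERM", "NOT_CELL_LINE")

#' Read / write a gold-standard table
#'
#' TSV with columns `accession`, `experiment_type` (`ChIP-seq` or
#' `ATAC-seq`), `label` (`CELL_LINE`, `CELL_LINE_NO_TERM`, `NOT_CELL_LINE`)
#' and `term_id` (the single Cellosaurus id for `CELL_LINE` rows, empty
#' otherwise). One row per accession.
#'
#' @param path TSV path.
#' @return Tibble.
#' @export
read_gold_standard <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("accession", "experiment_type", "label", "term_id")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("gold-standard table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(tab$label), .GOLD_LABELS)
  if (length(bad)) {
    stop("unknown gold label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$accession)) {
    stop("gold standard has duplicate accession(s)", call. = FALSE)
  }
  no_term <- tab$label == "CELL_LINE" & (is.na(tab$term_id) | !nzchar(tab$term_id))
  if (any(no_term)) {
    stop("CELL_LINE gold rows must carry exactly one term id (offending: ",
         paste(utils::head(tab$accession[no_term], 3), collapse = ", "), ")",
         call. = FALSE)
  }
  tab$term_id[is.na(tab$term_id)] <- ""
  tibble::as_tibble(tab)
}

#' @rdname read_gold_standard
#' @param gold Tibble in the layout above.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(gold, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select gold-standard samples under the stated constraints
#'
#' Emulates the sampling design of a curation benchmark: per experiment
#' type, up to `n_per_type` human samples with pairwise-distinct project ids
#' and pairwise-distinct curated terms, so no project or cell line dominates
#' the set. Selection is a seeded shuffle followed by greedy acceptance, so
#' the same seed always yields the same set.
#'
#' @param candidates Tibble with columns `accession`, `project_id`,
#'   `experiment_type`, `curated_term`, `organism`.
#' @param n_per_type Target count per experiment type.
#' @param seed Integer seed.
#' @return Character vector of selected accessions.
#' @export
select_gold_samples <- function(candidates, n_per_type, seed) {
  required <- c("accession", "project_id", "experiment_type", "curated_term",
                "organism")
  missing <- setdiff(required, names(candidates))
  if (length(missing)) {
    stop("candidate table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  human <- candidates[candidates$organism == "Homo sapiens", , drop = FALSE]
  selected <- character()
  for (etype in unique(human$experiment_type)) {
    pool <- human[human$experiment_type == etype, , drop = FALSE]
    ord <- .seeded_shuffle(nrow(pool), seed + match(etype, unique(human$experiment_type)))
    pool <- pool[ord, , drop = FALSE]
    seen_projects <- character()
    seen_terms <- character()
    taken <- 0L
    for (i in seq_len(nrow(pool))) {
      if (taken >= n_per_type) break
      if (pool$project_id[i] %in% seen_projects) next
      if (nzchar(pool$curated_term[i]) && pool$curated_term[i] %in% seen_terms) next
      seen_projects <- c(seen_projects, pool$project_id[i])
      if (nzchar(pool$curated_term[i])) seen_terms <- c(seen_terms, pool$curated_term[i])
      selected <- c(selected, pool$accession[i])
      taken <- taken + 1L
    }
    if (taken < n_per_type) {
      warning("experiment type '", etype, "': only ", taken, " of ",
              n_per_type, " requested samples were eligible", call. = FALSE)
    }
  }
  selected
}

.seeded_shuffle <- function(n, seed) {
  if (n == 0L) return(integer())
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n)
}

#' Score one mapping against its gold entry
#'
#' Judgment buckets follow the four-metric design: an output that maps to a
#' cell line (`MAPPED` or `NOT_UNIQUE` -- suggesting several terms counts as
#' a mapping attempt but is incorrect unless exactly the right single term
#' was produced) is judged on the cell-line side; a non-mapping output
#' (`NO_CELL_LINE`, `UNMAPPED_NAME`, `UNPARSEABLE`) on the non-cell-line
#' side. Gold `CELL_LINE_NO_TERM` entries (real cell lines with no ontology
#' term) can either count non-mapping outputs as `noncellline_incorrect`
#' (default) or be excluded from scoring, via `no_term_policy`.
#'
#' @param pred A `bsn_mapping`.
#' @param gold_row One-row slice of a [read_gold_standard()] tibble with a
#'   matching accession.
#' @param no_term_policy `"noncellline_incorrect"` or `"excluded"`.
#' @return One of `"cellline_correct"`, `"cellline_incorrect"`,
#'   `"noncellline_correct"`, `"noncellline_incorrect"`, `"excluded"`.
#' @export
score_mapping <- function(pred, gold_row,
                          no_term_policy = c("noncellline_incorrect", "excluded")) {
  no_term_policy <- match.arg(no_term_policy)
  if (!identical(pred$accession, gold_row$accession[1])) {
    stop("accession mismatch: prediction ", pred$accession, " vs gold ",
         gold_row$accession[1], call. = FALSE)
  }
  mapped <- pred$status %in% c("MAPPED", "NOT_UNIQUE")
  label <- gold_row$label[1]
  if (label == "CELL_LINE") {
    if (pred$status == "MAPPED" && identical(pred$term_id, gold_row$term_id[1])) {
      return("cellline_correct")
    }
    if (mapped) return("cellline_incorrect")
    return("noncellline_incorrect")
  }
  if (label == "NOT_CELL_LINE") {
    if (mapped) return("cellline_incorrect")
    return("noncellline_correct")
  }
  # CELL_LINE_NO_TERM
  if (mapped) return("cellline_incorrect")
  if (no_term_policy == "excluded") return("excluded")
  "noncellline_incorrect"
}

#' Score a batch of mappings against a gold standard
#'
#' @param mappings List of `bsn_mapping` objects.
#' @param gold A [read_gold_standard()] tibble; every mapping's accession
#'   must appear in it (extra gold rows are ignored).
#' @inheritParams score_mapping
#' @return Tibble with `accession`, `experiment_type`, `pred_status`,
#'   `pred_term`, `gold_label`, `gold_term`, `judgment`.
#' @export
score_mappings <- function(mappings, gold,
                           no_term_policy = c("noncellline_incorrect", "excluded")) {
  no_term_policy <- match.arg(no_term_policy)
  rows <- lapply(mappings, function(m) {
    g <- gold[gold$accession == m$accession, , drop = FALSE]
    if (nrow(g) == 0) {
      stop("no gold entry for accession ", m$accession, call. = FALSE)
    }
    tibble::tibble(
      accession = m$accession,
      experiment_type = g$experiment_type[1],
      pred_status = m$status,
      pred_term = m$term_id,
      gold_label = g$label[1],
      gold_term = g$term_id[1],
      judgment = score_mapping(m, g, no_term_policy)
    )
  })
  dplyr::bind_rows(rows)
}

#' Compute the four evaluation metrics
#'
#' Over a judged prediction set:
#' * cell-line accuracy = correct cell-line mappings / all outputs that
#'   mapped to a cell line;
#' * cell-line coverage = correct cell-line mappings / gold cell-line
#'   entries (by default only those carrying an ontology term -- the entries
#'   a mapper could possibly get right; `coverage_denominator =
#'   "all-cellline"` includes term-less cell-line entries);
#' * non-cell-line precision = correct non-mapping outputs / all non-mapping
#'   outputs;
#' * non-cell-line recall = correct non-mapping outputs / gold non-cell-line
#'   entries.
#'
#' Undefined quotients (zero denominator) are reported as `NA`, never as 0.
#'
#' @param judgments A [score_mappings()] tibble.
#' @param coverage_denominator `"with-term"` (default) or `"all-cellline"`.
#' @return An object of class `bsn_metrics`: the confusion counts, the gold
#'   composition, and the four ratios.
#' @export
compute_metrics <- function(judgments,
                            coverage_denominator = c("with-term", "all-cellline")) {
  coverage_denominator <- match.arg(coverage_denominator)
  judgments <- judgments[judgments$judgment != "excluded", , drop = FALSE]
  cnt <- function(j) sum(judgments$judgment == j)
  cl_ok <- cnt("cellline_correct")
  cl_bad <- cnt("cellline_incorrect")
  ncl_ok <- cnt("noncellline_correct")
  ncl_bad <- cnt("noncellline_incorrect")
  n_gold_cl_term <- sum(judgments$gold_label == "CELL_LINE")
  n_gold_cl_noterm <- sum(judgments$gold_label == "CELL_LINE_NO_TERM")
  n_gold_ncl <- sum(judgments$gold_label == "NOT_CELL_LINE")
  cov_denom <- if (coverage_denominator == "with-term") n_gold_cl_term else
    n_gold_cl_term + n_gold_cl_noterm
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    n_pred_cellline = cl_ok + cl_bad,
    n_pred_cellline_correct = cl_ok,
    n_pred_noncellline = ncl_ok + ncl_bad,
    n_pred_noncellline_correct = ncl_ok,
    n_gold_cellline = n_gold_cl_term + n_gold_cl_noterm,
    n_gold_cellline_with_term = n_gold_cl_term,
    n_gold_noncellline = n_gold_ncl,
    coverage_denominator = coverage_denominator,
    cell_line_accuracy = ratio(cl_ok, cl_ok + cl_bad),
    cell_line_coverage = ratio(cl_ok, cov_denom),
    non_cell_line_precision = ratio(ncl_ok, ncl_ok + ncl_bad),
    non_cell_line_recall = ratio(ncl_ok, n_gold_ncl)
  ), class = "bsn_metrics")
}

#' @export
print.bsn_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("Cell line accuracy:      ", fmt(x$cell_line_accuracy),
      sprintf("  (%d/%d)\n", x$n_pred_cellline_correct, x$n_pred_cellline))
  cat("Cell line coverage:      ", fmt(x$cell_line_coverage),
      sprintf("  (denominator: %s)\n", x$coverage_denominator))
  cat("Non-cell line precision: ", fmt(x$non_cell_line_precision),
      sprintf("  (%d/%d)\n", x$n_pred_noncellline_correct, x$n_pred_noncellline))
  cat("Non-cell line recall:    ", fmt(x$non_cell_line_recall),
      sprintf("  (gold non-cell lines: %d)\n", x$n_gold_noncellline))
  invisible(x)
}

#' Pooled and per-experiment-type metric reports
#'
#' @inheritParams compute_metrics
#' @return Named list: `pooled` plus one `bsn_metrics` per experiment type.
#' @export
compute_metrics_by_type <- function(judgments,
                                    coverage_denominator = c("with-term", "all-cellline")) {
  coverage_denominator <- match.arg(coverage_denominator)
  out <- list(pooled = compute_metrics(judgments, coverage_denominator))
  for (etype in sort(unique(judgments$experiment_type))) {
    out[[etype]] <- compute_metrics(
      judgments[judgments$experiment_type == etype, , drop = FALSE],
      coverage_denominator)
  }
  out
}

#' Error-category annotations
#'
#' Human-assigned failure categories for incorrectly handled samples
#' (derivation of a named line, overlooked names, noncanonical names,
#' selection failures, wrong extractions, ontology gaps). The tool stores
#' and round-trips the annotations; it never assigns them automatically.
#'
#' @param path TSV sidecar with columns `accession`, `category`, `note`.
#' @export
read_error_categories <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE)
  required <- c("accession", "category", "note")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("error-category table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  known <- c("Derivation", "Overlook", "Noncanonical name", "Selection failure",
             "Wrong extraction", "Ontology insufficiency")
  bad <- setdiff(unique(tab$category), known)
  if (length(bad)) {
    warning("unrecognized error categor(ies): ", paste(bad, collapse = ", "),
            call. = FALSE)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_error_categories
#' @param categories Tibble with columns `accession`, `category`, `note`.
#' @export
write_error_categories <- function(categories, path) {
  utils::write.table(categories, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a metrics report to JSON
#' @param report A `bsn_metrics` or [compute_metrics_by_type()] list.
#' @param path Output path.
#' @export
write_metrics_json <- function(report, path) {
  strip <- function(m) {
    vals <- unclass(m)
    vals[!vapply(vals, function(v) is.numeric(v) && is.na(v), logical(1))]
  }
  payload <- if (inherits(report, "bsn_metrics")) strip(report) else lapply(report, strip)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
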