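mk_map <- function(accession, status, term_id = NA_character_) {
  structure(list(accession = accession, status = status, term_id = term_id,
                 candidates = NULL, extracted_name = NA_character_,
                 selection_response = NA_character_, provisional = FALSE),
            class = "bsn_mapping")
}

mk_gold <- function(accession, label, term_id = "",
                    experiment_type = "ChIP-seq") {
  tibble::tibble(accession = accession, experiment_type = experiment_type,
                 label = label, term_id = term_id)
}

test_that("single-mapping judgments follow the scoring rules", {
  g_cl <- mk_gold("S1", "CELL_LINE", "CVCL:4719")
  expect_equal(score_mapping(mk_map("S1", "MAPPED", "CVCL:4719"), g_cl),
               "cellline_correct")
  expect_equal(score_mapping(mk_map("S1", "MAPPED", "CVCL:0001"), g_cl),
               "cellline_incorrect")
  # multiple suggestions are incorrect even if the right term is among them
  expect_equal(score_mapping(mk_map("S1", "NOT_UNIQUE"), g_cl),
               "cellline_incorrect")
  expect_equal(score_mapping(mk_map("S1", "NO_CELL_LINE"), g_cl),
               "noncellline_incorrect")
  g_non <- mk_gold("S1", "NOT_CELL_LINE")
  expect_equal(score_mapping(mk_map("S1", "NO_CELL_LINE"), g_non),
               "noncellline_correct")
  expect_equal(score_mapping(mk_map("S1", "UNMAPPED_NAME"), g_non),
               "noncellline_correct")
  expect_equal(score_mapping(mk_map("S1", "MAPPED", "CVCL:4719"), g_non),
               "cellline_incorrect")
  g_nt <- mk_gold("S1", "CELL_LINE_NO_TERM")
  expect_equal(score_mapping(mk_map("S1", "MAPPED", "CVCL:4719"), g_nt),
               "cellline_incorrect")
  expect_equal(score_mapping(mk_map("S1", "NO_CELL_LINE"), g_nt),
               "noncellline_incorrect")
  expect_equal(score_mapping(mk_map("S1", "NO_CELL_LINE"), g_nt,
                             no_term_policy = "excluded"), "excluded")
  expect_error(score_mapping(mk_map("S2", "MAPPED", "x"), g_cl), "mismatch")
})

test_that("metric formulas match worked hand counts", {
  # 4 gold cell lines with terms; 3 mapped outputs, of which 2 correct
  preds <- list(mk_map("A", "MAPPED", "CVCL:0001"),
                mk_map("B", "MAPPED", "CVCL:0002"),
                mk_map("C", "MAPPED", "CVCL:9999"),
                mk_map("D", "NO_CELL_LINE"))
  gold <- dplyr::bind_rows(
    mk_gold("A", "CELL_LINE", "CVCL:0001"),
    mk_gold("B", "CELL_LINE", "CVCL:0002"),
    mk_gold("C", "CELL_LINE", "CVCL:0003"),
    mk_gold("D", "CELL_LINE", "CVCL:0004"))
  m <- compute_metrics(score_mappings(preds, gold))
  expect_equal(m$cell_line_accuracy, 2 / 3)
  expect_equal(m$cell_line_coverage, 2 / 4)
  # 10 mapping outputs, 9 correct
  preds10 <- lapply(1:10, function(i)
    mk_map(paste0("P", i), "MAPPED", if (i <= 9) "CVCL:1" else "CVCL:2"))
  gold10 <- dplyr::bind_rows(lapply(1:10, function(i)
    mk_gold(paste0("P", i), "CELL_LINE", "CVCL:1")))
  expect_equal(compute_metrics(score_mappings(preds10, gold10))$cell_line_accuracy,
               0.9)
})

test_that("perfect predictions on a balanced set give all four metrics 1", {
  preds <- c(lapply(1:5, function(i) mk_map(paste0("C", i), "MAPPED", "CVCL:1")),
             lapply(1:5, function(i) mk_map(paste0("N", i), "NO_CELL_LINE")))
  gold <- dplyr::bind_rows(
    lapply(1:5, function(i) mk_gold(paste0("C", i), "CELL_LINE", "CVCL:1")),
    lapply(1:5, function(i) mk_gold(paste0("N", i), "NOT_CELL_LINE")))
  m <- compute_metrics(score_mappings(preds, gold))
  expect_equal(m$cell_line_accuracy, 1)
  expect_equal(m$cell_line_coverage, 1)
  expect_equal(m$non_cell_line_precision, 1)
  expect_equal(m$non_cell_line_recall, 1)
})

test_that("zero denominators are reported as absent, not zero", {
  preds <- list(mk_map("S1", "NO_CELL_LINE"))
  gold <- mk_gold("S1", "NOT_CELL_LINE")
  m <- compute_metrics(score_mappings(preds, gold))
  expect_true(is.na(m$cell_line_accuracy))
  expect_true(is.na(m$cell_line_coverage))
  expect_equal(m$non_cell_line_precision, 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(m, f)
  out <- jsonlite::fromJSON(f)
  expect_false("cell_line_accuracy" %in% names(out))
  expect_equal(out$non_cell_line_recall, 1)
})

test_that("coverage denominator convention is switchable for term-less cell lines", {
  preds <- list(mk_map("A", "MAPPED", "CVCL:1"), mk_map("B", "NO_CELL_LINE"))
  gold <- dplyr::bind_rows(mk_gold("A", "CELL_LINE", "CVCL:1"),
                           mk_gold("B", "CELL_LINE_NO_TERM"))
  j <- score_mappings(preds, gold)
  expect_equal(compute_metrics(j, "with-term")$cell_line_coverage, 1)
  expect_equal(compute_metrics(j, "all-cellline")$cell_line_coverage, 0.5)
})

test_that("every sample lands in exactly one judgment bucket and recounts agree", {
  set.seed(7)
  statuses <- c("MAPPED", "NOT_UNIQUE", "NO_CELL_LINE", "UNMAPPED_NAME",
                "UNPARSEABLE")
  labels <- c("CELL_LINE", "CELL_LINE_NO_TERM", "NOT_CELL_LINE")
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    accs <- paste0("R", seq_len(n))
    preds <- lapply(accs, function(a) {
      s <- sample(statuses, 1)
      mk_map(a, s, if (s == "MAPPED") sample(c("CVCL:1", "CVCL:2"), 1) else NA_character_)
    })
    gold <- dplyr::bind_rows(lapply(accs, function(a) {
      l <- sample(labels, 1)
      mk_gold(a, l, if (l == "CELL_LINE") "CVCL:1" else "",
              experiment_type = sample(c("ChIP-seq", "ATAC-seq"), 1))
    }))
    j <- score_mappings(preds, gold)
    expect_equal(nrow(j), n)
    m <- compute_metrics(j)
    # independent recount straight from the judgment definitions
    mapped <- j$pred_status %in% c("MAPPED", "NOT_UNIQUE")
    correct_cl <- mapped & j$gold_label == "CELL_LINE" &
      j$pred_status == "MAPPED" & j$pred_term == j$gold_term
    expect_equal(m$n_pred_cellline_correct, sum(correct_cl, na.rm = TRUE))
    expect_equal(m$n_pred_cellline, sum(mapped))
    expect_equal(m$n_pred_noncellline, sum(!mapped))
    if (sum(mapped) > 0) {
      expect_equal(m$cell_line_accuracy,
                   sum(correct_cl, na.rm = TRUE) / sum(mapped),
                   tolerance = 1e-12)
    }
    ncl_ok <- !mapped & j$gold_label == "NOT_CELL_LINE"
    if (sum(!mapped) > 0) {
      expect_equal(m$non_cell_line_precision, sum(ncl_ok) / sum(!mapped),
                   tolerance = 1e-12)
    }
    if (any(j$gold_label == "NOT_CELL_LINE")) {
      expect_equal(m$non_cell_line_recall,
                   sum(ncl_ok) / sum(j$gold_label == "NOT_CELL_LINE"),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-type reports stratify without changing the pooled result", {
  preds <- list(mk_map("A", "MAPPED", "CVCL:1"), mk_map("B", "NO_CELL_LINE"))
  gold <- dplyr::bind_rows(
    mk_gold("A", "CELL_LINE", "CVCL:1", experiment_type = "ChIP-seq"),
    mk_gold("B", "NOT_CELL_LINE", experiment_type = "ATAC-seq"))
  rep <- compute_metrics_by_type(score_mappings(preds, gold))
  expect_setequal(names(rep), c("pooled", "ChIP-seq", "ATAC-seq"))
  expect_equal(rep$pooled$cell_line_accuracy, 1)
  expect_equal(rep$`ChIP-seq`$n_gold_noncellline, 0)
})

test_that("gold-sample selection enforces human-only, distinct-project, distinct-term rules", {
  cand <- tibble::tibble(
    accession = paste0("S", 1:8),
    project_id = c("P1", "P1", "P2", "P3", "P4", "P5", "P6", "P7"),
    experiment_type = rep("ChIP-seq", 8),
    curated_term = c("HeLa", "K562", "HeLa", "K562", "G401", "U2OS", "", ""),
    organism = c(rep("Homo sapiens", 7), "Mus musculus"))
  expect_warning(sel <- select_gold_samples(cand, n_per_type = 8, seed = 1),
                 "eligible")
  picked <- cand[cand$accession %in% sel, ]
  expect_false("S8" %in% sel)
  expect_equal(anyDuplicated(picked$project_id), 0L)
  terms <- picked$curated_term[nzchar(picked$curated_term)]
  expect_equal(anyDuplicated(terms), 0L)
  expect_identical(select_gold_samples(cand, 3, seed = 42),
                   select_gold_samples(cand, 3, seed = 42))
  expect_warning(select_gold_samples(cand, 8, seed = 2), "eligible")
})

test_that("gold tables and error-category sidecars validate and round-trip", {
  gold <- dplyr::bind_rows(mk_gold("A", "CELL_LINE", "CVCL:1"),
                           mk_gold("B", "NOT_CELL_LINE"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gold_standard(gold, f)
  expect_equal(read_gold_standard(f)$label, gold$label)
  bad <- gold
  bad$term_id[1] <- ""
  write_gold_standard(bad, f)
  expect_error(read_gold_standard(f), "term id")
  cats <- tibble::tibble(accession = "A", category = "Derivation",
                         note = "derived clone")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_error_categories(cats, f2)
  expect_equal(read_error_categories(f2)$category, "Derivation")
  cats$category <- "Novel failure"
  write_error_categories(cats, f2)
  expect_warning(read_error_categories(f2), "unrecognized")
})
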