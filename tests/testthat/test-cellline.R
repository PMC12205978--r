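test_that("cell-line extraction handles name, sentinel, and prose-only replies", {
  recs <- parse_records(g401_record_json())
  backend <- oracle_backend(
    SAMN08370440 = list(cell_line_extraction = '{"cell_line":"G401"}'))
  ex <- extract_cell_line(recs[[1]], backend)
  expect_equal(ex$extracted_name, "G401")
  expect_false(ex$is_none)

  wheat <- make_record("SAMEA104646470",
                       `plant anatomical entity` = "leaf",
                       description = "Seeds were surface sterilized and sown; leaf tissue was sampled.")
  backend2 <- oracle_backend(
    SAMEA104646470 = list(cell_line_extraction =
      'The words seeds and leaf describe the protocol, not a cultured line. {"cell_line": "None"}'))
  ex2 <- extract_cell_line(wheat, backend2)
  expect_true(ex2$is_none)

  backend3 <- oracle_backend(S1 = list(cell_line_extraction = "prose only, no json"))
  ex3 <- extract_cell_line(make_record("S1", a = "1"), backend3)
  expect_true(ex3$unparseable)
})

test_that("extraction outcomes map to the four pre-disambiguation statuses", {
  idx <- tiny_index()
  mk_ex <- function(name = NA, none = FALSE, bad = FALSE) {
    structure(list(accession = "S1", extracted_name = name, is_none = none,
                   unparseable = bad, raw_response = ""),
              class = "bsn_extraction")
  }
  expect_equal(map_extraction(mk_ex(none = TRUE), idx)$status, "NO_CELL_LINE")
  expect_equal(map_extraction(mk_ex(bad = TRUE), idx)$status, "UNPARSEABLE")
  m <- map_extraction(mk_ex("S2"), idx)
  expect_equal(m$status, "MAPPED")
  expect_equal(m$term_id, "CVCL:4719")
  expect_equal(map_extraction(mk_ex("QQQX-77"), idx)$status, "UNMAPPED_NAME")
  amb <- map_extraction(mk_ex("H1"), idx)
  expect_equal(amb$status, "NOT_UNIQUE")
  expect_true(amb$provisional)
  expect_equal(length(unique(amb$candidates$term_id)), 2)
})

test_that("disambiguation accepts candidate ids, honors withholding, and rejects hallucinated ids", {
  idx <- tiny_index()
  record <- make_record("S1", `cell type` = "H1", disease = "hepatoblastoma")
  mk_prov <- function() {
    ex <- structure(list(accession = "S1", extracted_name = "H1",
                         is_none = FALSE, unparseable = FALSE, raw_response = ""),
                    class = "bsn_extraction")
    map_extraction(ex, idx)
  }
  pick <- oracle_backend(S1 = list(cell_line_selection = '{"cell_line_id":"CVCL:0101"}'))
  d1 <- disambiguate(mk_prov(), record, idx, pick)
  expect_equal(d1$status, "MAPPED")
  expect_equal(d1$term_id, "CVCL:0101")

  withhold <- oracle_backend(S1 = list(cell_line_selection = '{"cell_line_id": "not unique"}'))
  expect_equal(disambiguate(mk_prov(), record, idx, withhold)$status, "NOT_UNIQUE")

  outside <- oracle_backend(S1 = list(cell_line_selection = '{"cell_line_id":"CVCL:9999"}'))
  d3 <- disambiguate(mk_prov(), record, idx, outside)
  expect_equal(d3$status, "UNPARSEABLE")
  expect_match(d3$selection_response, "CVCL:9999")
  # a selected term is always one of the proposed candidates
  expect_false(isTRUE(d3$term_id %in% "CVCL:9999"))
})

test_that("the pipeline yields one final status per record in input order", {
  idx <- tiny_index()
  recs <- list(
    make_record("A1", `cell line` = "S2"),
    make_record("A2", tissue = "liver"),
    make_record("A3", `cell type` = "H1")
  )
  backend <- oracle_backend(
    A1 = list(cell_line_extraction = '{"cell_line":"S2"}'),
    A2 = list(cell_line_extraction = '{"cell_line":"None"}'),
    A3 = list(cell_line_extraction = '{"cell_line":"H1"}',
              cell_line_selection = '{"cell_line_id":"not unique"}')
  )
  maps <- run_cellline_pipeline(recs, idx, backend)
  expect_equal(vapply(maps, `[[`, character(1), "accession"),
               c("A1", "A2", "A3"))
  expect_equal(vapply(maps, `[[`, character(1), "status"),
               c("MAPPED", "NO_CELL_LINE", "NOT_UNIQUE"))
  expect_true(all(vapply(maps, function(m) m$status %in%
                           c("MAPPED", "NOT_UNIQUE", "NO_CELL_LINE",
                             "UNMAPPED_NAME", "UNPARSEABLE"), logical(1))))
  expect_equal(run_cellline_pipeline(list(), idx, backend), list())
})

test_that("per-sample parse failures never abort the batch; backend gaps do, with partial results", {
  idx <- tiny_index()
  recs <- list(make_record("B1", a = "x"), make_record("B2", `cell line` = "HeLa"))
  soft <- oracle_backend(
    B1 = list(cell_line_extraction = "no json at all"),
    B2 = list(cell_line_extraction = '{"cell_line":"HeLa"}'))
  maps <- run_cellline_pipeline(recs, idx, soft)
  expect_equal(vapply(maps, `[[`, character(1), "status"),
               c("UNPARSEABLE", "MAPPED"))
  hard <- oracle_backend(B1 = list(cell_line_extraction = '{"cell_line":"HeLa"}'))
  err <- tryCatch(run_cellline_pipeline(recs, idx, hard), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "B2")
  expect_length(err$partial, 1)
})

test_that("mapping files round-trip byte-identically on rerun", {
  idx <- tiny_index()
  recs <- list(make_record("C1", `cell line` = "S2"),
               make_record("C2", `cell type` = "H1"))
  backend <- oracle_backend(
    C1 = list(cell_line_extraction = '{"cell_line":"S2"}'),
    C2 = list(cell_line_extraction = '{"cell_line":"H1"}',
              cell_line_selection = '{"cell_line_id":"CVCL:0100"}'))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_mappings_jsonl(run_cellline_pipeline(recs, idx, backend), f1)
  write_mappings_jsonl(run_cellline_pipeline(recs, idx, backend), f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_mappings_jsonl(f1)
  expect_equal(vapply(back, `[[`, character(1), "status"),
               c("MAPPED", "MAPPED"))
  expect_equal(back[[2]]$term_id, "CVCL:0100")
})

test_that("the key-restricted matcher never exceeds the full pipeline's coverage", {
  onto <- make_mini_ontology(seed = 5)
  idx <- build_index(onto$terms)
  fx <- make_records(fixture_spec(n_records = 80, seed = 5), onto)
  full <- run_cellline_pipeline(fx$records, idx, scripted_backend(fx$responses))
  conservative <- run_keyrestricted_pipeline(fx$records, idx)
  cov_full <- compute_metrics(score_mappings(full, fx$gold))$cell_line_coverage
  cov_cons <- compute_metrics(score_mappings(conservative, fx$gold))$cell_line_coverage
  expect_lte(cov_cons, cov_full)
})
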