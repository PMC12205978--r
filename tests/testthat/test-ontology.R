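test_that("OBO loading reproduces the worked term and drops obsolete stanzas", {
  obo <- paste(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: CVCL_4719",
    "name: S-2",
    'synonym: "s-2" EXACT []',
    'synonym: "S 2" RELATED []',
    'synonym: "S2" RELATED []',
    "subset: Cancer_cell_line",
    "subset: Male",
    "xref: NCIt:C1234 ! Lung small cell carcinoma",
    "",
    "[Term]",
    "id: CVCL_0999",
    "name: Gone",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: CVCL_0001",
    "name: HeLa",
    "",
    "[Term]",
    "id: CVCL_0002",
    "name: Jurkat",
    sep = "\n")
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, path)
  terms <- load_cellosaurus(path)
  expect_length(terms, 3)
  expect_false("CVCL:0999" %in% names(terms))
  expect_equal(anyDuplicated(names(terms)), 0L)
  t <- terms[["CVCL:4719"]]
  expect_equal(unclass(t), unclass(cvcl_4719_term()))
})

test_that("ill-formed OBO input errors with a line number", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: CVCL_0001", "name: A", "garbage line here"), path)
  expect_error(load_cellosaurus(path), "line 4")
  writeLines(c("[Term]", "id: CVCL_0002", "name: B",
               'synonym: unquoted RELATED []'), path)
  expect_error(load_cellosaurus(path), "synonym")
})

test_that("normalization ladder emits the forced variant sequences", {
  expect_equal(normalize_string("S_2"), c("S_2", "s_2", "S 2", "s 2"))
  expect_equal(normalize_string("HeLa"), c("HeLa", "hela"))
  v <- normalize_string("HEK-293T")
  expect_true(all(c("HEK 293T", "hek 293t") %in% v))
  expect_equal(normalize_string("  a   b  "), c("a b"))
  expect_error(normalize_string("   "), "whitespace")
})

test_that("index answers case and delimiter variants, including length-2 strings", {
  idx <- tiny_index()
  for (q in c("s-2", "S 2", "S2", "s2")) {
    expect_equal(match_string(idx, q)$term_id, "CVCL:4719", label = q)
  }
  h1 <- match_string(idx, "h1")
  expect_setequal(h1$term_id, c("CVCL:0100", "CVCL:0101"))
  expect_equal(nrow(match_string(idx, "XYZZY-9")), 0)
})

test_that("matches carry class and ladder level, deduplicated by strongest class", {
  idx <- tiny_index()
  m <- match_string(idx, "S2")
  expect_equal(m$match_class, "related_synonym")
  m2 <- match_string(idx, "s-2")
  # the query variant "s-2" equals both the name under case folding and the
  # exact synonym verbatim: one row per term, strongest class reported
  expect_equal(nrow(m2), 1)
  expect_equal(m2$term_id, "CVCL:4719")
  expect_equal(m2$match_class, "name")
  expect_equal(match_string(idx, "HELA")$term_id, "CVCL:0001")
})

test_that("matcher equals the brute-force oracle on a generated ontology", {
  onto <- make_mini_ontology(n_terms = 200, seed = 11)
  idx <- build_index(onto$terms)
  terms <- onto$terms
  labels <- unlist(lapply(terms, function(t) c(t$name, t$exact_synonyms,
                                               t$related_synonyms)))
  set.seed(99)
  mangle <- function(s) {
    switch(sample(4, 1),
           stringi::stri_trans_toupper(s),
           stringi::stri_trans_tolower(s),
           gsub("-", "_", s, fixed = TRUE),
           paste0(s, sample(c("", "X", "-9"), 1)))
  }
  queries <- c(sample(labels, 600, replace = TRUE),
               vapply(sample(labels, 350, replace = TRUE), mangle, character(1)),
               vapply(1:100, function(i) paste0(sample(c(LETTERS, 0:9, "-", "_"),
                                                       sample(1:6, 1), replace = TRUE),
                                                collapse = ""), character(1)))
  oracle <- brute_oracle(terms)
  for (q in queries) {
    expect_equal(sort(unique(match_string(idx, q)$term_id)),
                 oracle(q), label = q)
  }
})

test_that("matching is case-invariant and monotone under synonym addition", {
  idx <- tiny_index()
  for (q in c("HeLa", "s-2", "h1", "wa01")) {
    base <- sort(match_string(idx, q)$term_id)
    expect_equal(sort(match_string(idx, stringi::stri_trans_toupper(q))$term_id), base)
    expect_equal(sort(match_string(idx, stringi::stri_trans_tolower(q))$term_id), base)
  }
  terms <- tiny_terms()
  before <- lapply(c("HeLa", "S2", "H1"), function(q)
    sort(match_string(build_index(terms), q)$term_id))
  terms[["CVCL:0001"]]$related_synonyms <-
    c(terms[["CVCL:0001"]]$related_synonyms, "HeLa-NEW")
  after_idx <- build_index(terms)
  after <- lapply(c("HeLa", "S2", "H1"), function(q)
    sort(match_string(after_idx, q)$term_id))
  for (i in seq_along(before)) {
    expect_true(all(before[[i]] %in% after[[i]]))
  }
})

test_that("term context JSON has the exact key order and round-trips", {
  t <- cvcl_4719_term()
  json <- term_context_json(t)
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(names(obj), c("id", "name", "related_synonyms", "exact_synonyms",
                             "diseases", "cell line type", "sex"))
  expect_equal(unclass(parse_term_context(json)), unclass(t))
  empty <- ontology_term("CVCL:0002", "Jurkat")
  j2 <- term_context_json(empty)
  expect_match(j2, '"related_synonyms":\\[\\]')
  expect_equal(unclass(parse_term_context(j2)), unclass(empty))
})

test_that("index persistence round-trips and rejects corrupt or foreign files", {
  idx <- tiny_index()
  path <- withr::local_tempfile(fileext = ".bin")
  save_index(idx, path)
  idx2 <- load_index(path)
  expect_equal(sort(match_string(idx2, "h1")$term_id),
               sort(match_string(idx, "h1")$term_id))
  saveRDS(list(format_version = 99L), path)
  expect_error(load_index(path), "format version")
  writeLines("not an index", path)
  expect_error(load_index(path), "corrupt")
})

test_that("edit-distance fallback stays off by default and is bounded to one edit", {
  idx <- tiny_index()
  expect_equal(nrow(match_string(idx, "HeLb")), 0)
  m <- match_string(idx, "HeLb", edit_distance_fallback = TRUE)
  expect_true("CVCL:0001" %in% m$term_id)
  expect_equal(unique(m$normalization), "edit_distance_1")
})
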