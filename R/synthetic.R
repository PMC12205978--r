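#' Fixture specification
#'
#' Parameters of the synthetic benchmark generator. Defaults mirror the
#' conditions of the curation study the package targets: 600 records (300
#' per experiment type), roughly half of them cell-line samples, a small
#' fraction of homonym traps (short shared labels like `"H1"`), and a
#' fifth of the records carrying procedural free-text distractors. Every
#' generator is a pure function of its spec: the same seed yields identical
#' fixture bytes.
#'
#' @param n_records Number of sample records.
#' @param cellline_fraction Fraction of records that are cell-line samples.
#' @param ambiguous_fraction Fraction of records (all of them cell-line
#'   samples) whose name is shared by two ontology terms.
#' @param distractor_fraction Fraction of records (all non-cell-line) whose
#'   free text mentions ontology labels in a non-sample context.
#' @param modulated_fraction Fraction of records carrying a gene-modulation
#'   description.
#' @param seed Integer seed.
#' @export
fixture_spec <- function(n_records = 600, cellline_fraction = 0.5,
                         ambiguous_fraction = 0.05, distractor_fraction = 0.2,
                         modulated_fraction = 0.3, seed = 1) {
  fr <- c(cellline_fraction, ambiguous_fraction, distractor_fraction,
          modulated_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (ambiguous_fraction > cellline_fraction) {
    stop("ambiguous_fraction cannot exceed cellline_fraction", call. = FALSE)
  }
  if (distractor_fraction > 1 - cellline_fraction) {
    stop("distractor_fraction cannot exceed the non-cell-line fraction",
         call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records),
                 cellline_fraction = cellline_fraction,
                 ambiguous_fraction = ambiguous_fraction,
                 distractor_fraction = distractor_fraction,
                 modulated_fraction = modulated_fraction,
                 seed = as.integer(seed)),
            class = "bsn_fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.DISEASE_POOL <- c("Lung small cell carcinoma", "Hepatoblastoma",
                   "Acute myeloid leukemia", "Colon adenocarcinoma",
                   "Breast ductal carcinoma", "Glioblastoma",
                   "Embryonal rhabdomyosarcoma", "Melanoma")
.TYPE_POOL <- c("Cancer_cell_line", "Finite_cell_line",
                "Spontaneously_immortalized_cell_line",
                "Embryonic_stem_cell")

#' Generate a miniature cell-line ontology
#'
#' Produces 50--200 terms in the Cellosaurus style: each term has a
#' delimited name (e.g. `"KT-431"`), RELATED synonyms that differ only by
#' delimiter handling (`"KT 431"`, `"KT431"`), an EXACT synonym differing
#' only by case (`"kt-431"`), a disease, a category and a sex. One homonym
#' pair is always present: two distinct terms both named `"H1"`. A truth
#' table lists, for every query derived from the labels, the term ids the
#' matcher must return (computed by a brute-force scan over all labels with
#' the same normalization ladder).
#'
#' @param n_terms Number of terms (50--200).
#' @param seed Integer seed.
#' @param obo_path Optional path; when given, the OBO document is written
#'   there.
#' @return List with `terms` (named list of [ontology_term()]), `obo_text`,
#'   `truth` (tibble `query`, `expected_ids` comma-joined), and
#'   `homonym_ids` (the two `"H1"` term ids).
#' @export
make_mini_ontology <- function(n_terms = 120, seed = 1, obo_path = NULL) {
  if (n_terms < 50 || n_terms > 200) {
    stop("n_terms must be between 50 and 200", call. = FALSE)
  }
  .with_seed(seed, {
    prefixes <- apply(expand.grid(LETTERS, LETTERS), 1, paste, collapse = "")
    terms <- list()
    for (i in seq_len(n_terms - 2L)) {
      base <- paste0(prefixes[i], "-", 100L + i)
      related <- c(gsub("-", " ", base, fixed = TRUE),
                   gsub("-", "", base, fixed = TRUE))
      exact <- stringi::stri_trans_tolower(base)
      id <- sprintf("CVCL:%04d", i)
      terms[[id]] <- ontology_term(
        id, base,
        exact_synonyms = exact, related_synonyms = related,
        diseases = sample(.DISEASE_POOL, 1),
        cell_line_type = sample(.TYPE_POOL, 1),
        sex = sample(c("Male", "Female"), 1)
      )
    }
    # homonym pair: a short embryonic-stem-cell-style label shared verbatim
    for (k in 1:2) {
      id <- sprintf("CVCL:%04d", 9000L + k)
      terms[[id]] <- ontology_term(
        id, "H1",
        exact_synonyms = character(),
        related_synonyms = if (k == 1) "WA01" else "H-1",
        diseases = if (k == 1) character() else "Hepatoblastoma",
        cell_line_type = if (k == 1) "Embryonic_stem_cell" else "Cancer_cell_line",
        sex = if (k == 1) "Male" else "Female"
      )
    }
    truth <- .ontology_truth_table(terms)
    obo_text <- .terms_to_obo(terms)
    if (!is.null(obo_path)) {
      writeLines(obo_text, obo_path, useBytes = TRUE)
    }
    list(terms = terms, obo_text = obo_text, truth = truth,
         homonym_ids = sprintf("CVCL:%04d", 9001:9002))
  })
}

# Brute-force matching oracle mirroring the ladder semantics: try the
# query's variants in order, at each level scan every term's full
# label-variant set (precomputed once), stop at the first level with a hit.
.brute_force_oracle <- function(terms) {
  variant_sets <- lapply(terms, function(t) {
    labels <- c(t$name, t$exact_synonyms, t$related_synonyms)
    labels <- labels[nzchar(stringi::stri_trim_both(labels))]
    unique(unlist(lapply(labels, normalize_string), use.names = FALSE))
  })
  ids <- vapply(terms, `[[`, character(1), "id")
  function(query) {
    for (v in normalize_string(query)) {
      hit <- vapply(variant_sets, function(vs) v %in% vs, logical(1))
      if (any(hit)) return(unique(ids[hit]))
    }
    character()
  }
}

.ontology_truth_table <- function(terms) {
  queries <- unique(unlist(lapply(terms, function(t) {
    labels <- c(t$name, t$exact_synonyms, t$related_synonyms)
    c(labels, stringi::stri_trans_toupper(labels))
  })))
  oracle <- .brute_force_oracle(terms)
  tibble::tibble(
    query = queries,
    expected_ids = vapply(queries, function(q) {
      paste(sort(oracle(q)), collapse = ",")
    }, character(1), USE.NAMES = FALSE)
  )
}

.terms_to_obo <- function(terms) {
  stanzas <- vapply(terms, function(t) {
    lines <- c("[Term]",
               paste0("id: ", sub("^CVCL:", "CVCL_", t$id)),
               paste0("name: ", t$name))
    for (s in t$exact_synonyms) lines <- c(lines, sprintf('synonym: "%s" EXACT []', s))
    for (s in t$related_synonyms) lines <- c(lines, sprintf('synonym: "%s" RELATED []', s))
    for (s in t$cell_line_type) lines <- c(lines, paste0("subset: ", s))
    for (s in t$sex) lines <- c(lines, paste0("subset: ", s))
    for (j in seq_along(t$diseases)) {
      lines <- c(lines, sprintf("xref: NCIt:C%04d ! %s", 1000L + j, t$diseases[j]))
    }
    paste(lines, collapse = "\n")
  }, character(1))
  paste0("format-version: 1.2\nontology: cvcl-mini\n\n",
         paste(stanzas, collapse = "\n\n"), "\n")
}

.CELLLINE_KEY_POOL <- c("cell line", "cell_line", "source_name", "isolate",
                        "cell type", "strain", "cell_type", "tissue")
# relative frequencies follow the measured project-basis key distribution
# for a well-known cell-line value (rounded)
.CELLLINE_KEY_WEIGHTS <- c(667, 435, 338, 88, 33, 20, 7, 6)

.CONSERVATIVE_KEYS <- c("cell line", "cell_line", "cell type", "cell_type")

.ANTIBODY_POOL <- c("anti-FLAG", "H3K27ac antibody", "H3K4me3 (Abcam ab8580)",
                    "CTCF rabbit polyclonal", "Pol II (CST 14958)")
.TISSUE_POOL <- c("liver", "peripheral blood", "frontal cortex", "kidney",
                  "skeletal muscle")
.MOD_GENES <- c("ARID1A", "CHAF1A", "TP53", "ZBTB1", "SUZ12", "PAF1")
.MOD_METHODS_RAW <- c("KO", "shRNA", "overexpression", "dTAG", "siRNA",
                      "deletion")

#' Generate synthetic sample records with gold labels and scripted answers
#'
#' Builds a record set reproducing the statistical structure of the task:
#' cell-line records use heterogeneous attribute keys sampled from the
#' measured key-variant distribution (with at least one record guaranteed to
#' use a key outside the conservative `cell line`/`cell type` whitelist);
#' homonym-trap records carry the shared `"H1"` label; distractor records
#' embed ontology labels inside procedural free text (seeds/leaf-style
#' protocol descriptions) and ChIP antibody protein names; the remainder are
#' plain tissue samples. Alongside the records it emits the gold-standard
#' table and a scripted-backend answer file with ideal replies for all three
#' prompt tasks, so an end-to-end pipeline run is fully determined offline.
#'
#' @param spec A [fixture_spec()].
#' @param ontology A [make_mini_ontology()] result.
#' @return List with `records`, `gold` (tibble), `responses` (scripted
#'   backend answers), `modulation_truth` (tibble of planted modulations).
#' @export
make_records <- function(spec, ontology) {
  stopifnot(inherits(spec, "bsn_fixture_spec"))
  n <- spec$n_records
  n_cell <- round(n * spec$cellline_fraction)
  n_amb <- min(round(n * spec$ambiguous_fraction), n_cell)
  n_non <- n - n_cell
  n_dis <- min(round(n * spec$distractor_fraction), n_non)
  .with_seed(spec$seed + 1L, {
    plain_ids <- setdiff(names(ontology$terms), ontology$homonym_ids)
    records <- vector("list", n)
    gold <- vector("list", n)
    responses <- list()
    mod_truth <- list()
    etypes <- rep(c("ChIP-seq", "ATAC-seq"), length.out = n)
    kinds <- c(rep("amb", n_amb), rep("cell", n_cell - n_amb),
               rep("distractor", n_dis), rep("plain_non", n_non - n_dis))
    kinds <- kinds[sample.int(n)]
    # terms recur across records when more cell-line records are requested
    # than the mini ontology has terms
    assigned_terms <- sample(plain_ids, max(n_cell - n_amb, 0L),
                             replace = (n_cell - n_amb) > length(plain_ids))
    term_cursor <- 0L
    forced_nonstandard <- FALSE
    for (i in seq_len(n)) {
      accession <- sprintf("SAMN%08d", 70000000L + i)
      project <- sprintf("PRJNA%06d", 500000L + i)
      etype <- etypes[i]
      kind <- kinds[i]
      keys <- c("organism", "bioproject_accession")
      vals <- c("Homo sapiens", project)
      mods <- NULL
      if (kind %in% c("cell", "amb")) {
        if (kind == "amb") {
          term_id <- sample(ontology$homonym_ids, 1)
          label <- "H1"
        } else {
          term_cursor <- term_cursor + 1L
          term_id <- assigned_terms[term_cursor]
          term <- ontology$terms[[term_id]]
          label <- sample(c(term$name, term$exact_synonyms, term$related_synonyms), 1)
        }
        key <- sample(.CELLLINE_KEY_POOL, 1, prob = .CELLLINE_KEY_WEIGHTS)
        if (kind == "cell" && !forced_nonstandard) {
          key <- "source_name"  # guarantee >=1 record the key-restricted rule misses
          forced_nonstandard <- TRUE
        }
        keys <- c(keys, key, "title")
        vals <- c(vals, label, paste0(etype, " of ", label, " rep", sample(1:3, 1)))
        if (etype == "ChIP-seq") {
          keys <- c(keys, "chip antibody")
          vals <- c(vals, sample(.ANTIBODY_POOL, 1))
        }
        if (stats::runif(1) < spec$modulated_fraction) {
          gene <- sample(.MOD_GENES, 1)
          method_raw <- sample(.MOD_METHODS_RAW, 1)
          keys <- c(keys, "genotype/variation")
          vals <- c(vals, paste0(gene, " ", method_raw))
          mods <- list(gene = gene, method_raw = method_raw)
        }
        gold[[i]] <- tibble::tibble(accession = accession,
                                    experiment_type = etype,
                                    label = "CELL_LINE", term_id = term_id)
        responses[[accession]] <- list(
          cell_line_extraction = paste0(
            "Let's think step by step. The attributes describe a cultured ",
            "cell line sample.\n", '{"cell_line": "', label, '"}'),
          cell_line_selection = paste0(
            "Comparing diseases and cell line type with the sample ",
            "metadata, confidence is highest for one term.\n",
            '{"cell_line_id": "', term_id, '"}'),
          gene_extraction = if (is.null(mods)) {
            "No modulated genes are described.\n[]"
          } else {
            paste0("The genotype attribute describes a perturbation.\n",
                   '[{"gene": "', mods$gene, '", "method": "',
                   mods$method_raw, '"}]')
          }
        )
        if (!is.null(mods)) {
          mod_truth[[length(mod_truth) + 1L]] <- tibble::tibble(
            accession = accession, gene = mods$gene,
            method_raw = mods$method_raw,
            method_canonical = canonicalize_method(mods$method_raw))
        }
      } else {
        if (kind == "distractor") {
          decoy <- ontology$terms[[sample(plain_ids, 1)]]$name
          keys <- c(keys, "tissue", "description")
          vals <- c(vals,
                    sample(.TISSUE_POOL, 1),
                    paste0("Seeds were sown on plates; after 10 days leaf ",
                           "tissue was harvested. Chromatin was compared ",
                           "with the ", decoy, " reference track and the H1 ",
                           "histone control."))
        } else {
          keys <- c(keys, "tissue", "sex")
          vals <- c(vals, sample(.TISSUE_POOL, 1), sample(c("male", "female"), 1))
        }
        if (etype == "ChIP-seq") {
          keys <- c(keys, "chip antibody")
          vals <- c(vals, sample(.ANTIBODY_POOL, 1))
        }
        gold[[i]] <- tibble::tibble(accession = accession,
                                    experiment_type = etype,
                                    label = "NOT_CELL_LINE", term_id = "")
        responses[[accession]] <- list(
          cell_line_extraction = paste0(
            "Let's think step by step. The strings naming cell lines appear ",
            "only in procedural context; the sample itself is a tissue.\n",
            '{"cell_line": "None"}'),
          gene_extraction = "No modulated genes are described.\n[]"
        )
      }
      records[[i]] <- sample_record(accession, keys, vals,
                                    source_dialect = "flat-json",
                                    project_id = project)
    }
    list(records = records,
         gold = dplyr::bind_rows(gold),
         responses = responses,
         modulation_truth = if (length(mod_truth)) dplyr::bind_rows(mod_truth) else
           tibble::tibble(accession = character(), gene = character(),
                          method_raw = character(), method_canonical = character()))
  })
}

#' Generate a miniature HGNC symbol table
#'
#' A fixed small table exercising every resolution path: approved symbols, a
#' previous symbol, aliases (one shared by two ids, so it cannot resolve
#' uniquely), a withdrawn entry, and a case-variant trap. All entries are
#' synthetic stand-ins in the standard complete-set column layout.
#'
#' @param path Optional TSV output path.
#' @return List with `table` (tibble) and `truth` (tibble `query`,
#'   `expected_status`).
#' @export
make_hgnc_fixture <- function(path = NULL) {
  tab <- tibble::tibble(
    hgnc_id = c("HGNC:11110", "HGNC:19145", "HGNC:11998", "HGNC:12930",
                "HGNC:17101", "HGNC:26360", "HGNC:90001", "HGNC:90002",
                "HGNC:90003"),
    symbol = c("ARID1A", "CHAF1A", "TP53", "ZBTB1", "SUZ12", "PAF1",
               "DUSP27", "AAB5", "AAB6"),
    status = c(rep("Approved", 6), "Entry Withdrawn", "Approved", "Approved"),
    alias_symbol = c("BAF250|BAF250a", "CAF1P150", "p53|LFS1", "ZNF909",
                     "CHET9|JJAZ1", "PD2", "", "SHRD1", "SHRD1"),
    prev_symbol = c("C1orf4", "", "", "", "KIAA0160", "", "", "", "")
  )
  truth <- tibble::tibble(
    query = c("ARID1A", "arid1a", "BAF250", "C1orf4", "p53", "SHRD1",
              "shrd1", "DUSP27", "GFP", "EWSR1::FLI1"),
    expected_status = c("UNIQUE", "UNIQUE", "UNIQUE", "UNIQUE", "UNIQUE",
                        "MULTIPLE", "MULTIPLE", "UNIQUE", "UNMAPPED",
                        "UNMAPPED")
  )
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(table = tab, truth = truth)
}

#' Write a complete fixture set to a directory
#'
#' Emits `records.jsonl`, `gold.tsv`, `mini.obo`, `hgnc.tsv`,
#' `backend_script.json` and `ontology_truth.tsv`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_fixture_set <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  onto <- make_mini_ontology(seed = spec$seed, obo_path = file.path(dir, "mini.obo"))
  fx <- make_records(spec, onto)
  write_records_jsonl(fx$records, file.path(dir, "records.jsonl"))
  write_gold_standard(fx$gold, file.path(dir, "gold.tsv"))
  make_hgnc_fixture(file.path(dir, "hgnc.tsv"))
  jsonlite::write_json(fx$responses, file.path(dir, "backend_script.json"),
                       auto_unbox = TRUE)
  utils::write.table(onto$truth, file.path(dir, "ontology_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(spec = spec, ontology = onto, fixture = fx))
}
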