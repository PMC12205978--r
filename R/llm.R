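#' @name prompts
#' @title Canonical task prompts
#' @description
#' The three instruction prompts driving the extraction and selection tasks.
#' They are frozen verbatim as package constants (ASCII quotes, one sentence
#' per line): a general cell-line definition with a JSON output contract and
#' a `{"cell_line": "None"}` escape hatch; a candidate-selection prompt with
#' a `{{cell_line}}` placeholder, confidence-score instruction and a
#' `"not unique"` escape hatch; and a gene-modulation prompt defining the
#' knockout / knockdown / overexpression vocabulary (including a historical
#' "trasfection" misspelling preserved intact, since the prompts are part of
#' the recorded experimental conditions) with a JSON-array output contract.
#' @keywords internal
NULL

.PROMPT_CELL_LINE_EXTRACTION <- paste(
  "A cell line is a group of cells that are genetically identical and have been cultured in a laboratory setting. For example, HeLa, Jurkat, HEK293, etc. are names of commonly used cell lines.",
  "I will input json formatted metadata of a sample for a biological experiment. If the sample is considered to be a cell line, extract the cell line name from the input data.",
  "Your output must be JSON format, like {\"cell_line\": \"NAME\"}. \"NAME\" is just a place holder. Replace this with a string you extract.",
  "When input sample data is not of a cell line, you are not supposed to extract any text from input. If you can not find a cell line name in input, your output is like {\"cell_line\": \"None\"}. Are you ready?",
  sep = "\n")

.PROMPT_CELL_LINE_SELECTION <- paste(
  "I searched an ontology for the cell line, \"{{cell_line}}.\" I have found multiple terms which may represent the sample. Below are the annotations for each term. For each term, compare it with the input JSON of the sample and show your confidence score (a value between 0-1) about to what extent the entry represents the sample. In the comparison, consider the information such as:",
  "Whether the term has a name or a synonym exactly matches the extracted cell line name, \"{{cell_line}}.\"",
  "Whether the term has disease or cell line type information which matches sample information.",
  "Based on the confidence score, output the ID of the term that is most likely to represent the input sample in the format of {\"cell_line_id\": \"\"}. If it is not clear which one is most likely from the given information, output {\"cell_line_id\": \"not unique\"}.",
  sep = "\n")

.PROMPT_GENE_EXTRACTION <- paste(
  "There are several experimental methods to modulate gene expression.",
  "Gene knockout (KO), also known as gene deletion, involves completely eliminating the expression of a target gene by replacing it with a non-functional version, usually through homologous recombination in cells or animals. This results in a complete loss of the gene's function.",
  "Meanwhile, gene knockdown (KD), also known as RNA interference (RNAi), involves reducing the expression of a target gene without completely eliminating it. KD is achieved by introducing small RNA molecules, siRNA or shRNA, that specifically bind to and degrade the messenger RNA (mRNA) of the target gene.",
  "Gene overexpression refers to the process of increasing the expression of a specific gene beyond its normal levels in a cell. This is achieved by trasfection of a plasmid carrying the gene of interest, transduction of viruses carrying the gene of interest, etc.",
  "I will input json formatted metadata of a sample for a biological experiment. If the sample is considered to have genes whose expression is experimentally modulated, extract the gene names from the input data and specify the modulation method.",
  "Your output must be in JSON format, like [{\"gene\": \"GENE_NAME\", \"method\": \"METHOD_NAME\"}]. \"GENE_NAME\" and \"METHOD_NAME\" are placeholders. Replace them with the gene name you extract and the modulation method name you specify, respectively. If the modulation method is either gene knockout, gene knockdown, or gene overexpression, the value of the \"method\" attribute must be \"knockout,\" \"knockdown,\" and \"overexpression,\" respectively. Otherwise, the value of the \"method\" attribute must be the method name found in the input data.",
  "If the input sample data is not considered to have genes whose expression is modulated, your output JSON must be an empty list (namely, \"[]\"). Note that multiple genes can be modulated in one sample. In this case, be sure to include all of them in the list of the output JSON. For example, if you find \"PRNP\" and \"MSTN\" as knocked out genes, your output must be [{\"gene\": \"PRNP\", \"method\": \"knockout\"}, {\"gene\": \"MSTN\", \"method\": \"knockout\"}]. Note also that multiple gene modulation methods can be used for one sample. For example, you may find \"ARID1A\" as a knocked-out gene and \"CHAF1A\" as a gene treated with dTAG. In this case, your output must be [{\"gene\": \"ARID1A\", \"method\": \"knockout\"}, {\"gene\": \"CHAF1A\", \"method\": \"dTAG\"}].",
  "Are you ready?",
  sep = "\n")

.THINK_SUFFIX <- "think step by step"

.PROMPT_TASKS <- c("cell_line_extraction", "cell_line_selection", "gene_extraction")

#' Retrieve a canonical prompt preamble
#' @param task One of `"cell_line_extraction"`, `"cell_line_selection"`,
#'   `"gene_extraction"`.
#' @return The prompt text (with the `{{cell_line}}` placeholder still in
#'   place for the selection prompt).
#' @export
prompt_preamble <- function(task = .PROMPT_TASKS) {
  task <- match.arg(task)
  switch(task,
         cell_line_extraction = .PROMPT_CELL_LINE_EXTRACTION,
         cell_line_selection = .PROMPT_CELL_LINE_SELECTION,
         gene_extraction = .PROMPT_GENE_EXTRACTION)
}

# JSON object of a record's attributes; duplicate keys get "#2","#3" suffixes
# (JSON objects cannot repeat keys and the suffix keeps the repetition
# visible to the model).
.attributes_json <- function(record) {
  keys <- .dedupe_keys(record$attributes$key)
  obj <- stats::setNames(as.list(record$attributes$value), keys)
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
}

#' Render a task prompt bundle
#'
#' For the extraction tasks the payload is a single JSON object of the
#' record's attributes. For the selection task, `record_or_context` is a list
#' with elements `cell_line` (the extracted name), `contexts` (character
#' vector of [term_context_json()] strings) and optionally `record`; the
#' `{{cell_line}}` placeholder is substituted and the payload is one JSON
#' object `{"sample": <attributes>, "terms": [<contexts>]}` so the sample
#' JSON the prompt refers to travels with the candidate annotations. The
#' reasoning directive `"think step by step"` is appended after the payload.
#'
#' @param task See [prompt_preamble()].
#' @param record_or_context A [sample_record()] for extraction tasks, or the
#'   selection list described above.
#' @param think_step_by_step Append the reasoning directive (default `TRUE`).
#' @return An object of class `bsn_prompt` with fields `task`, `preamble`,
#'   `payload`, `suffix`, `accession`.
#' @export
render_prompt <- function(task, record_or_context, think_step_by_step = TRUE) {
  task <- match.arg(task, .PROMPT_TASKS)
  suffix <- if (think_step_by_step) .THINK_SUFFIX else ""
  if (task %in% c("cell_line_extraction", "gene_extraction")) {
    record <- record_or_context
    stopifnot(inherits(record, "bsn_record"))
    if (nrow(record$attributes) == 0) {
      warning("record ", record$accession,
              " has no attributes; rendering an empty payload", call. = FALSE)
    }
    bundle <- list(task = task, preamble = prompt_preamble(task),
                   payload = .attributes_json(record), suffix = suffix,
                   accession = record$accession)
  } else {
    ctx <- record_or_context
    stopifnot(is.list(ctx), is.character(ctx$cell_line), length(ctx$cell_line) == 1L,
              is.character(ctx$contexts), length(ctx$contexts) >= 1L)
    preamble <- stringi::stri_replace_all_fixed(prompt_preamble(task),
                                               "{{cell_line}}", ctx$cell_line)
    sample_json <- if (!is.null(ctx$record)) .attributes_json(ctx$record) else "{}"
    payload <- paste0('{"sample":', sample_json, ',"terms":[',
                      paste(ctx$contexts, collapse = ","), "]}")
    bundle <- list(task = task, preamble = preamble, payload = payload,
                   suffix = suffix,
                   accession = if (!is.null(ctx$record)) ctx$record$accession else NA_character_)
  }
  structure(bundle, class = "bsn_prompt")
}

#' Full prompt text of a bundle
#' @param bundle A [render_prompt()] result.
#' @export
prompt_text <- function(bundle) {
  stopifnot(inherits(bundle, "bsn_prompt"))
  parts <- c(bundle$preamble, bundle$payload,
             if (nzchar(bundle$suffix)) bundle$suffix)
  paste(parts, collapse = "\n")
}

#' @export
print.bsn_prompt <- function(x, ...) {
  cat("<bsn_prompt> task=", x$task, " accession=", x$accession,
      " (", nchar(prompt_text(x)), " chars)\n", sep = "")
  invisible(x)
}

#' Backend configuration
#'
#' Generation is run deterministically: the sampling temperature defaults to
#' 0 so repeated runs of the same prompt give the same output.
#'
#' @param model Model identifier passed to the backend.
#' @param temperature Sampling temperature; default 0.
#' @param timeout Per-request timeout in seconds.
#' @param retries Bounded retry count for transient backend failures.
#' @export
backend_config <- function(model = "scripted", temperature = 0,
                           timeout = 120, retries = 2) {
  list(model = model, temperature = temperature, timeout = timeout,
       retries = retries)
}

#' Deterministic scripted backend
#'
#' A stand-in for a text-generation model: responses are pre-authored and
#' keyed by `(accession, task)`. Requesting a key with no scripted response
#' is an explicit error, never a silent default, so fixture gaps surface
#' immediately.
#'
#' @param responses Named list: `responses[[accession]][[task]]` is the raw
#'   text to return.
#' @return An object of classes `bsn_backend_scripted`, `bsn_backend`.
#' @export
scripted_backend <- function(responses) {
  stopifnot(is.list(responses))
  structure(list(responses = responses, backend_id = "scripted"),
            class = c("bsn_backend_scripted", "bsn_backend"))
}

#' HTTP generation backend
#'
#' Minimal client for an Ollama-style `/api/generate` endpoint. This is
#' untested plumbing intended for interactive use against a locally hosted
#' model; all offline work uses [scripted_backend()].
#'
#' @param endpoint Base URL, e.g. `"http://localhost:11434"`.
#' @export
http_generation_backend <- function(endpoint) {
  structure(list(endpoint = endpoint, backend_id = "http-generation-server"),
            class = c("bsn_backend_http", "bsn_backend"))
}

#' Invoke a generation backend
#'
#' @param backend A backend object.
#' @param bundle A [render_prompt()] result.
#' @param config A [backend_config()].
#' @return List with `raw_text`, `backend_id`, `model_id`, `temperature`.
#' @export
invoke_backend <- function(backend, bundle, config = backend_config()) {
  UseMethod("invoke_backend")
}

#' @export
invoke_backend.bsn_backend_scripted <- function(backend, bundle,
                                                config = backend_config()) {
  stopifnot(inherits(bundle, "bsn_prompt"))
  acc <- bundle$accession
  entry <- backend$responses[[acc %||% ""]]
  raw <- entry[[bundle$task]]
  if (is.null(raw)) {
    stop("no scripted response for accession '", acc, "', task '", bundle$task,
         "'", call. = FALSE)
  }
  list(raw_text = raw, backend_id = backend$backend_id,
       model_id = config$model, temperature = config$temperature)
}

#' @export
invoke_backend.bsn_backend_http <- function(backend, bundle,
                                            config = backend_config()) {
  if (!requireNamespace("httr", quietly = TRUE)) {
    stop("the http backend requires the 'httr' package", call. = FALSE)
  }
  url <- paste0(sub("/$", "", backend$endpoint), "/api/generate")
  body <- list(model = config$model, prompt = prompt_text(bundle),
               stream = FALSE, options = list(temperature = config$temperature))
  last_err <- NULL
  for (attempt in seq_len(config$retries + 1L)) {
    resp <- tryCatch(
      httr::POST(url, body = body, encode = "json",
                 httr::timeout(config$timeout)),
      error = function(e) e
    )
    if (!inherits(resp, "error") && httr::status_code(resp) < 500L) {
      parsed <- httr::content(resp, as = "parsed", type = "application/json")
      return(list(raw_text = parsed$response %||% "",
                  backend_id = backend$backend_id,
                  model_id = config$model, temperature = config$temperature))
    }
    last_err <- resp
  }
  stop("backend unreachable after ", config$retries + 1L, " attempt(s): ",
       if (inherits(last_err, "error")) conditionMessage(last_err) else "server error",
       call. = FALSE)
}

# Locate every balanced top-level JSON object/array span in free text,
# respecting string literals and escapes. Returns a list of substrings in
# order of their starting position.
.json_spans <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  spans <- list()
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c("{", "[")) {
      depth <- 0L
      in_str <- FALSE
      esc <- FALSE
      j <- i
      end <- NA_integer_
      while (j <= n) {
        ch <- chars[j]
        if (in_str) {
          if (esc) esc <- FALSE
          else if (ch == "\\") esc <- TRUE
          else if (ch == '"') in_str <- FALSE
        } else {
          if (ch == '"') in_str <- TRUE
          else if (ch %in% c("{", "[")) depth <- depth + 1L
          else if (ch %in% c("}", "]")) {
            depth <- depth - 1L
            if (depth == 0L) { end <- j; break }
          }
        }
        j <- j + 1L
      }
      if (!is.na(end)) {
        spans[[length(spans) + 1L]] <- substr(text, i, end)
        i <- end + 1L
        next
      }
    }
    i <- i + 1L
  }
  spans
}

.shape_ok <- function(value, span, expected_shape) {
  is_str1 <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
  if (expected_shape == "object_with_cell_line") {
    return(startsWith(span, "{") && is.list(value) &&
             !is.null(value[["cell_line"]]) && is_str1(value[["cell_line"]]))
  }
  if (expected_shape == "object_with_cell_line_id") {
    return(startsWith(span, "{") && is.list(value) &&
             !is.null(value[["cell_line_id"]]) && is_str1(value[["cell_line_id"]]))
  }
  # array_of_gene_method
  if (!startsWith(span, "[") || !is.list(value)) return(FALSE)
  all(vapply(value, function(el) {
    is.list(el) && setequal(names(el), c("gene", "method")) &&
      length(el) == 2L && is_str1(el[["gene"]]) && is_str1(el[["method"]])
  }, logical(1)))
}

#' Parse a structured reply out of free-form model output
#'
#' Step-by-step reasoning output may surround -- and even contain
#' intermediate candidates of -- the requested JSON, so the *last*
#' syntactically valid JSON value matching the expected shape wins. The
#' function is total: any input yields either a conforming value or an
#' `"unparseable"` status, never an error, so a single bad reply cannot abort
#' a batch.
#'
#' @param raw Raw generated text.
#' @param expected_shape One of `"object_with_cell_line"`,
#'   `"object_with_cell_line_id"`, `"array_of_gene_method"`.
#' @return List with `status` (`"ok"` or `"unparseable"`), `value` (the
#'   parsed value, or `NULL`), `json_text` (the winning span), and `prose`
#'   (the raw text with the winning span removed, kept for logging).
#' @export
parse_response_json <- function(raw,
                                expected_shape = c("object_with_cell_line",
                                                   "object_with_cell_line_id",
                                                   "array_of_gene_method")) {
  expected_shape <- match.arg(expected_shape)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    return(list(status = "unparseable", value = NULL, json_text = NA_character_,
                prose = if (is.character(raw)) paste(raw, collapse = "\n") else ""))
  }
  best <- NULL
  for (span in .json_spans(raw)) {
    value <- tryCatch(jsonlite::fromJSON(span, simplifyVector = FALSE),
                      error = function(e) NULL)
    if (is.null(value) && !identical(stringi::stri_trim_both(span), "[]") &&
        !identical(stringi::stri_trim_both(span), "{}")) next
    if (is.null(value)) value <- list()
    # also consider nested spans: a conforming object inside a reasoning
    # object is found because .json_spans restarts after each balanced span;
    # nested candidates are covered by scanning the span's interior.
    if (.shape_ok(value, span, expected_shape)) {
      best <- list(value = value, span = span)
    } else {
      inner <- .nested_conforming(span, expected_shape)
      if (!is.null(inner)) best <- inner
    }
  }
  if (is.null(best)) {
    return(list(status = "unparseable", value = NULL, json_text = NA_character_,
                prose = raw))
  }
  list(status = "ok", value = best$value, json_text = best$span,
       prose = stringi::stri_replace_first_fixed(raw, best$span, ""))
}

.nested_conforming <- function(span, expected_shape) {
  interior <- substr(span, 2L, nchar(span) - 1L)
  if (!grepl("[{\\[]", interior)) return(NULL)
  best <- NULL
  for (s in .json_spans(interior)) {
    value <- tryCatch(jsonlite::fromJSON(s, simplifyVector = FALSE),
                      error = function(e) NULL)
    if (is.null(value)) next
    if (.shape_ok(value, s, expected_shape)) best <- list(value = value, span = s)
    else {
      deeper <- .nested_conforming(s, expected_shape)
      if (!is.null(deeper)) best <- deeper
    }
  }
  best
}
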