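#' Credibility label values
#'
#' The three-value credibility schema used throughout the package:
#' `CRED` (credible: verifiable, consistent with current medical knowledge),
#' `NONCRED` (non-credible: false, unverifiable, or persuading against
#' current recommendations), and `NEU` (neutral: no factual medical content,
#' e.g. a question).
#'
#' @return Character vector of the three admissible label values.
#' @export
#' @examples
#' credibility_labels()
credibility_labels <- function() c("CRED", "NONCRED", "NEU")

#' Reason-tag vocabulary for non-credible annotations
#'
#' The fixed nine-item vocabulary of machine-readable reasons an annotator may
#' attach to a `NONCRED` label: weak or irrelevant argumentation,
#' encouragement to act against current medical knowledge, an author lacking
#' substantive knowledge or objectivity, anecdote or rumor, advertisement of
#' an unproven drug or therapy, research on a small sample, invalid numerical
#' data, outdated information, or an incomprehensible/ungrammatical sentence.
#'
#' @return Character vector of nine snake_case tag identifiers.
#' @export
reason_tag_vocabulary <- function() {
  c(
    "weak_or_irrelevant_argument",
    "act_against_medical_knowledge",
    "author_lacks_knowledge_or_objectivity",
    "anecdote_or_rumor",
    "unproven_drug_or_therapy_ad",
    "small_sample_research",
    "invalid_numerical_data",
    "outdated_information",
    "incomprehensible_or_ungrammatical"
  )
}

corpus_columns <- function() {
  c("sentence_id", "text", "topic", "source_id", "gold_label")
}

#' Construct and validate a sentence corpus
#'
#' A sentence corpus is a tibble with one row per sentence and columns
#' `sentence_id`, `text`, `topic`, `source_id`, `gold_label`. `source_id` and
#' `gold_label` may be `NA`; `gold_label`, when present, must be one of
#' [credibility_labels()] and is consumed only by the simulated oracle and the
#' evaluation module, never by the ranking itself.
#'
#' @param x A data frame (or tibble) with at least `sentence_id`, `text` and
#'   `topic` columns. Missing optional columns are added as `NA`.
#' @return A validated tibble with the five canonical columns, input row
#'   order preserved.
#' @export
#' @examples
#' as_sentence_corpus(data.frame(
#'   sentence_id = c("s1", "s2"),
#'   text = c("Statins lower cholesterol.", "What a day!"),
#'   topic = "cholesterol_statins"
#' ))
as_sentence_corpus <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sentence_id", "text", "topic")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    cl_stop("credlift_parse_error", "corpus is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(corpus_columns(), names(x))) x[[col]] <- NA_character_
  x <- x[, corpus_columns()]
  for (col in corpus_columns()) x[[col]] <- as.character(x[[col]])

  if (anyNA(x$sentence_id) || any(!nzchar(x$sentence_id))) {
    cl_stop("credlift_parse_error", "sentence_id must be non-missing and non-empty")
  }
  dup <- unique(x$sentence_id[duplicated(x$sentence_id)])
  if (length(dup) > 0) {
    cl_stop("credlift_duplicate_id_error",
            "duplicate sentence_id(s): %s", paste(dup, collapse = ", "))
  }
  stripped <- trimws(x$text)
  if (anyNA(stripped) || any(!nzchar(stripped))) {
    cl_stop("credlift_parse_error",
            "text must be non-empty after whitespace stripping (offending id(s): %s)",
            paste(x$sentence_id[is.na(stripped) | !nzchar(stripped)], collapse = ", "))
  }
  bad_label <- !is.na(x$gold_label) & !(x$gold_label %in% credibility_labels())
  if (any(bad_label)) {
    cl_stop("credlift_unknown_label_error",
            "gold_label must be one of %s; got: %s",
            paste(credibility_labels(), collapse = "/"),
            paste(unique(x$gold_label[bad_label]), collapse = ", "))
  }
  tibble::as_tibble(x)
}

empty_corpus <- function() {
  tibble::as_tibble(stats::setNames(
    as.data.frame(matrix(character(0), nrow = 0, ncol = 5), stringsAsFactors = FALSE),
    corpus_columns()
  ))
}

#' Read a sentence corpus from JSONL or CSV
#'
#' JSONL holds one JSON object per line with keys equal to the corpus columns;
#' CSV is comma-separated, quoted, UTF-8 with a header row. A zero-byte JSONL
#' file is a valid empty corpus; a CSV file must at least carry its header.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; default inferred from the file
#'   extension.
#' @return A validated sentence corpus tibble in file order.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- infer_format(path, match.arg(format))
  if (!file.exists(path)) {
    cl_stop("credlift_io_error", "file does not exist: %s", path)
  }
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_corpus())
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        cl_stop("credlift_parse_error", "line %d: invalid JSON (%s)",
                                i, conditionMessage(e))
                      })
      rows[[i]] <- lapply(stats::setNames(corpus_columns(), corpus_columns()),
                          function(f) {
                            v <- rec[[f]]
                            if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
                          })
    }
    df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  } else {
    if (file.size(path) == 0) {
      cl_stop("credlift_empty_file_error", "empty CSV file (no header row): %s", path)
    }
    df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
    if (nrow(df) == 0) return(empty_corpus())
    # CSV has no null literal: empty optional fields come back as "" and are
    # restored to NA (text/sentence_id stay as-is so validation can flag them)
    for (col in intersect(c("source_id", "gold_label"), names(df))) {
      df[[col]][!nzchar(df[[col]])] <- NA_character_
    }
  }
  as_sentence_corpus(df)
}

#' Write a sentence corpus to JSONL or CSV
#'
#' Output is UTF-8 with deterministic column order and round-trips through
#' [read_corpus()] byte-for-byte on the `text` field (newlines included).
#'
#' @param records A sentence corpus (validated with [as_sentence_corpus()]).
#' @param path Output file path.
#' @inheritParams read_corpus
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, format = c("auto", "jsonl", "csv")) {
  format <- infer_format(path, match.arg(format))
  records <- if (nrow(as.data.frame(records)) == 0) empty_corpus() else as_sentence_corpus(records)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) cl_stop("credlift_io_error", "cannot write %s", path))
  on.exit(close(con), add = TRUE)
  if (format == "jsonl") {
    if (nrow(records) > 0) {
      for (i in seq_len(nrow(records))) {
        row <- lapply(as.list(records[i, ]), function(v) if (is.na(v)) NULL else v)
        writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null"),
                   con, useBytes = TRUE)
      }
    }
  } else {
    txt <- utils::capture.output(
      utils::write.csv(as.data.frame(records), stdout(), row.names = FALSE, na = "")
    )
    # capture.output splits embedded newlines into separate elements already
    # quoted by write.csv, so re-joining with \n reproduces the stream.
    writeLines(enc2utf8(txt), con, useBytes = TRUE)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) return("jsonl")
  if (ext %in% c("csv")) return("csv")
  cl_stop("credlift_io_error",
          "cannot infer format from extension '%s'; pass format explicitly", ext)
}
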