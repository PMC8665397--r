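#' Construct an annotation record
#'
#' One expert judgment of one sentence: the credibility label, optional
#' machine-readable reason tags (meaningful only for `NONCRED`), an optional
#' free-text reason, how many surrounding sentences the annotator had to read
#' (`context_needed`), and the evaluation time in milliseconds.
#'
#' @param sentence_id Sentence identifier.
#' @param label One of [credibility_labels()].
#' @param reason_tags Character vector drawn from [reason_tag_vocabulary()]
#'   (may be empty), or a single "|"-joined string.
#' @param free_reason Optional free-text reason.
#' @param context_needed Non-negative integer count of surrounding sentences
#'   consulted.
#' @param eval_time_ms Optional non-negative evaluation time in milliseconds.
#' @param annotator_id Annotator identifier.
#' @return A one-row tibble with class-checked fields; `reason_tags` is stored
#'   as a "|"-joined string (`""` when empty) so annotation tables serialize
#'   to flat CSV/JSONL.
#' @export
annotation_record <- function(sentence_id, label, reason_tags = character(0),
                              free_reason = NA_character_, context_needed = 0L,
                              eval_time_ms = NA_integer_, annotator_id = "anon") {
  tags <- parse_reason_tags(reason_tags)
  rec <- tibble::tibble(
    sentence_id = as.character(sentence_id),
    label = as.character(label),
    reason_tags = paste(tags, collapse = "|"),
    free_reason = as.character(free_reason),
    context_needed = as.integer(context_needed),
    eval_time_ms = as.integer(eval_time_ms),
    annotator_id = as.character(annotator_id)
  )
  check_annotation_fields(rec)
  rec
}

parse_reason_tags <- function(x) {
  if (length(x) == 0) return(character(0))
  x <- as.character(x)
  if (length(x) == 1 && grepl("|", x, fixed = TRUE)) x <- strsplit(x, "|", fixed = TRUE)[[1]]
  x[nzchar(x)]
}

check_annotation_fields <- function(a) {
  if (!(a$label %in% credibility_labels())) {
    cl_stop("credlift_unknown_label_error",
            "unknown credibility label '%s' (expected %s)",
            a$label, paste(credibility_labels(), collapse = "/"))
  }
  tags <- parse_reason_tags(a$reason_tags)
  bad <- setdiff(tags, reason_tag_vocabulary())
  if (length(bad) > 0) {
    cl_stop("credlift_unknown_reason_tag_error",
            "unknown reason tag(s): %s", paste(bad, collapse = ", "))
  }
  if (is.na(a$context_needed) || a$context_needed < 0) {
    cl_stop("credlift_parse_error", "context_needed must be a non-negative integer")
  }
  if (!is.na(a$eval_time_ms) && a$eval_time_ms < 0) {
    cl_stop("credlift_parse_error", "eval_time_ms must be non-negative")
  }
  invisible(a)
}

#' Validate an annotation record against a corpus
#'
#' Checks every record invariant (admissible label, reason tags within the
#' nine-item vocabulary, non-negative context/time counts) and that the
#' annotated sentence exists in the corpus. Validation is total: the record is
#' returned unchanged or a typed error is signalled; nothing is coerced
#' silently.
#'
#' @param a A one-row annotation tibble (see [annotation_record()]).
#' @param corpus_ids Character vector of known sentence ids.
#' @return The validated record, invisibly unchanged.
#' @export
validate_annotation <- function(a, corpus_ids) {
  a <- tibble::as_tibble(a)
  check_annotation_fields(a)
  if (!(a$sentence_id %in% corpus_ids)) {
    cl_stop("credlift_unknown_sentence_error",
            "sentence_id '%s' not present in the corpus", a$sentence_id)
  }
  a
}

#' Validate a table of annotations
#'
#' Row-wise [validate_annotation()] plus the table-level invariant that each
#' (sentence_id, annotator_id) pair is annotated at most once.
#'
#' @param annotations Tibble of annotation records.
#' @param corpus_ids Character vector of known sentence ids.
#' @return The validated tibble.
#' @export
validate_annotations <- function(annotations, corpus_ids) {
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) == 0) return(annotations)
  for (i in seq_len(nrow(annotations))) {
    validate_annotation(annotations[i, ], corpus_ids)
  }
  key <- paste(annotations$sentence_id, annotations$annotator_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- annotations$sentence_id[duplicated(key)]
    cl_stop("credlift_duplicate_annotation_error",
            "multiple annotations for (sentence, annotator): %s",
            paste(unique(dup), collapse = ", "))
  }
  annotations
}
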