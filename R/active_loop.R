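#' Simulated expert oracle reading gold labels
#'
#' Wraps a corpus carrying `gold_label` into the annotator contract used by
#' [run_loop()]: a deterministic function from sentence id to an annotation
#' record. Stands in for the medical expert when simulating the annotation
#' loop on labeled (synthetic or held-out) data.
#'
#' @param corpus A sentence corpus whose `gold_label` column is filled for
#'   every sentence the loop may request.
#' @param annotator_id Identifier stamped on every produced record.
#' @return A function `(sentence_id) -> annotation record` (one-row tibble).
#' @export
gold_oracle <- function(corpus, annotator_id = "oracle") {
  corpus <- as_sentence_corpus(corpus)
  gold <- stats::setNames(corpus$gold_label, corpus$sentence_id)
  function(sentence_id) {
    if (!(sentence_id %in% names(gold)) || is.na(gold[[sentence_id]])) {
      cl_stop("credlift_oracle_error",
              "oracle has no gold label for sentence '%s'", sentence_id)
    }
    annotation_record(sentence_id, gold[[sentence_id]],
                      annotator_id = annotator_id)
  }
}

#' Run the active-annotation assessment loop
#'
#' The five-step loop: (1) sentences are already encoded (`X`); (2) k-means
#' groups them and the `m` most central sentences per cluster become pivots;
#' (3) the oracle annotates the pivots (iteration 0); (4) clusters are scored
#' from the labels observed so far and all remaining sentences are reranked;
#' (5) the top `batch_size` of the ranking are annotated, triggering another
#' reranking — until the annotation budget is exhausted. Clustering is fit
#' once and never refit; annotated sentences are never re-requested.
#'
#' @param corpus A sentence corpus.
#' @param X Post-processed `embedding_matrix` aligned with the corpus.
#' @param oracle Annotator function `(sentence_id) -> annotation record`
#'   (see [gold_oracle()]).
#' @param budget Total number of sentences to annotate (`1 <= budget <= n`).
#' @param config A [ranking_config()].
#' @param k Cluster count; if `NULL`, chosen by [select_k_elbow()] over
#'   `k_range`.
#' @param k_range Candidate cluster counts for the elbow rule (default
#'   `2 .. min(20, n - 1)`).
#' @param fallback_prior `label_probs` used for clusters with no annotations
#'   before any label exists; once annotations accumulate, the overall
#'   empirical label distribution takes over as the fallback.
#' @return An `annotation_log`: tibble of (iteration, sentence_id, label,
#'   reason_tags, context_needed, eval_time_ms, annotator_id) in chronological
#'   order, with the config, seed, chosen `k` and the fitted `cluster_model`
#'   attached as attributes.
#' @export
run_loop <- function(corpus, X, oracle, budget, config = ranking_config(),
                     k = NULL, k_range = NULL,
                     fallback_prior = label_probs(1 / 3, 1 / 3, 1 / 3)) {
  corpus <- as_sentence_corpus(corpus)
  stopifnot(inherits(X, "embedding_matrix"))
  n <- nrow(corpus)
  if (budget <= 0) cl_stop("credlift_config_error", "budget must be positive")
  if (budget > n) cl_stop("credlift_config_error", "budget (%d) exceeds corpus size (%d)", budget, n)
  if (!X$postprocessed) {
    cl_stop("credlift_embedding_error", "run_loop expects post-processed embeddings")
  }
  if (!setequal(X$ids, corpus$sentence_id)) {
    cl_stop("credlift_embedding_error", "embedding ids do not match the corpus")
  }

  if (is.null(k)) {
    if (is.null(k_range)) k_range <- seq(2L, max(4L, min(20L, n - 1L)))
    k <- select_k_elbow(X, k_range, config$seed)$k
  }
  model <- fit_kmeans(X, k, config$seed)
  pivot_sets <- pivots(model, config$m)
  pivot_ids <- unlist(pivot_sets, use.names = FALSE)

  log_rows <- vector("list", budget)
  annotated <- character(0)
  n_logged <- 0
  iteration <- 0L

  annotate <- function(ids, iteration) {
    for (id in ids) {
      rec <- oracle(id)
      if (!identical(rec$sentence_id, id)) {
        cl_stop("credlift_oracle_error", "oracle returned a record for the wrong sentence")
      }
      n_logged <<- n_logged + 1
      log_rows[[n_logged]] <<- cbind(data.frame(iteration = iteration), as.data.frame(rec))
      annotated <<- c(annotated, id)
    }
  }

  annotate(utils::head(pivot_ids, budget), 0L)

  while (n_logged < budget) {
    iteration <- iteration + 1L
    labels_so_far <- vapply(log_rows[seq_len(n_logged)], `[[`, character(1), "label")
    ids_so_far <- vapply(log_rows[seq_len(n_logged)], `[[`, character(1), "sentence_id")
    overall <- estimate_probs(labels_so_far, fallback_prior)
    probs <- lapply(seq_len(k), function(j) {
      member <- names(model$assignment)[model$assignment == j]
      pool <- if (config$use_all_annotations) member else intersect(member, pivot_sets[[j]])
      estimate_probs(labels_so_far[ids_so_far %in% pool], fallback_prior = overall)
    })
    rk <- rank_corpus(model, probs, annotated_ids = annotated, config = config)
    take <- utils::head(rk$order, min(config$batch_size, budget - n_logged))
    annotate(take, iteration)
  }

  log <- tibble::as_tibble(do.call(rbind, log_rows))
  structure(log, class = c("annotation_log", class(log)),
            config = config, seed = config$seed, k = k, model = model)
}

#' Chronological annotation order of a log
#'
#' The sequence of sentence ids in the order the loop (or a human session)
#' annotated them — the "ranking" that the lift evaluation scores.
#'
#' @param log An `annotation_log` (or any tibble with `iteration` and
#'   `sentence_id` in chronological order).
#' @return Character vector of sentence ids.
#' @export
replay_annotations <- function(log) {
  log <- tibble::as_tibble(log)
  if (nrow(log) == 0) return(character(0))
  if (is.unsorted(log$iteration)) {
    cl_stop("credlift_log_error", "iteration indices must be non-decreasing")
  }
  if (anyDuplicated(log$sentence_id)) {
    cl_stop("credlift_log_error", "sentence '%s' annotated more than once",
            log$sentence_id[duplicated(log$sentence_id)][1])
  }
  log$sentence_id
}

#' Persist / load an annotation log as JSONL
#'
#' One JSON object per annotation in chronological order; the config snapshot
#' and seed travel in a leading header object (`"_header": true`).
#'
#' @param log An `annotation_log`.
#' @param path Output path.
#' @return `path` (write) or the reconstructed log tibble (read).
#' @export
write_annotation_log <- function(log, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  cfg <- attr(log, "config")
  header <- list(`_header` = TRUE, seed = attr(log, "seed"), k = attr(log, "k"),
                 config = if (is.null(cfg)) NULL else unclass(cfg))
  writeLines(jsonlite::toJSON(header, auto_unbox = TRUE, null = "null"), con, useBytes = TRUE)
  for (i in seq_len(nrow(log))) {
    row <- lapply(as.list(tibble::as_tibble(log)[i, ]), function(v) if (is.na(v)) NULL else v)
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null"), con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_annotation_log
#' @export
read_annotation_log <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) cl_stop("credlift_empty_file_error", "empty log file: %s", path)
  header <- jsonlite::fromJSON(lines[[1]])
  body <- lines[-1]
  cols <- c("iteration", "sentence_id", "label", "reason_tags", "free_reason",
            "context_needed", "eval_time_ms", "annotator_id")
  rows <- lapply(body, function(l) {
    rec <- jsonlite::fromJSON(l)
    vals <- lapply(cols, function(f) if (is.null(rec[[f]])) NA else rec[[f]])
    stats::setNames(vals, cols)
  })
  log <- tibble::as_tibble(do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE)))
  log$iteration <- as.integer(log$iteration)
  log$context_needed <- as.integer(log$context_needed)
  log$eval_time_ms <- as.integer(log$eval_time_ms)
  structure(log, class = c("annotation_log", class(log)),
            seed = header$seed, k = header$k)
}
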