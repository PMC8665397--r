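#' Per-cluster label probabilities
#'
#' Holds the estimated probability that a random sentence of a cluster is
#' credible (`p_c`), non-credible (`p_n`) or neutral (`p_u`), plus the number
#' of annotated sentences supporting the estimate.
#'
#' @param p_c,p_n,p_u Probabilities in \[0, 1\], summing to 1 (tolerance
#'   1e-12).
#' @param n_annotated Non-negative support count (0 for a prior).
#' @return An object of class `label_probs`.
#' @export
label_probs <- function(p_c, p_n, p_u, n_annotated = 0L) {
  vals <- c(p_c, p_n, p_u)
  if (any(vals < 0) || any(vals > 1) || abs(sum(vals) - 1) > 1e-12) {
    cl_stop("credlift_probs_error",
            "label probabilities must lie in [0,1] and sum to 1 (got %.15f)", sum(vals))
  }
  structure(list(p_c = p_c, p_n = p_n, p_u = p_u,
                 n_annotated = as.integer(n_annotated)),
            class = "label_probs")
}

#' @export
print.label_probs <- function(x, ...) {
  cat(sprintf("<label_probs> p_c=%.3f p_n=%.3f p_u=%.3f (n=%d)\n",
              x$p_c, x$p_n, x$p_u, x$n_annotated))
  invisible(x)
}

#' Estimate a cluster's label distribution from its annotations
#'
#' Empirical label fractions over the annotated sentences of one cluster.
#' With no annotations the supplied fallback prior is returned (support count
#' zero), which keeps unannotated clusters mid-ranked instead of artificially
#' first or last.
#'
#' @param labels Character vector of credibility labels observed in the
#'   cluster (may be empty).
#' @param fallback_prior A `label_probs` used when `labels` is empty.
#' @return A `label_probs`.
#' @export
#' @examples
#' estimate_probs(c("NONCRED", "NONCRED", "CRED", "NEU", "NONCRED"))
estimate_probs <- function(labels,
                           fallback_prior = label_probs(1 / 3, 1 / 3, 1 / 3)) {
  labels <- as.character(labels)
  bad <- setdiff(labels, credibility_labels())
  if (length(bad) > 0) {
    cl_stop("credlift_unknown_label_error", "unknown label(s): %s",
            paste(bad, collapse = ", "))
  }
  if (length(labels) == 0) {
    return(label_probs(fallback_prior$p_c, fallback_prior$p_n, fallback_prior$p_u,
                       n_annotated = 0L))
  }
  n <- length(labels)
  label_probs(sum(labels == "CRED") / n,
              sum(labels == "NONCRED") / n,
              sum(labels == "NEU") / n,
              n_annotated = n)
}

#' Ranking configuration
#'
#' @param w Neutral-penalty base of the cluster score, `> 1` (default 1.5).
#'   Larger `w` punishes neutral-heavy clusters harder.
#' @param m Pivot sentences annotated per cluster before the first reranking.
#' @param batch_size Sentences annotated per loop iteration between
#'   rerankings.
#' @param use_all_annotations If `TRUE` (default) cluster probabilities are
#'   re-estimated from every annotation in the cluster each round; if `FALSE`
#'   only the pivot annotations are used.
#' @param first_term `"logistic"` (default) scores the credibility contrast
#'   with the sigmoid of `p_n - p_c`; `"exp"` uses the unbounded
#'   `exp(p_n - p_c)` for sensitivity checks.
#' @param seed Integer seed for clustering and any stochastic step.
#' @return A `ranking_config` list.
#' @export
ranking_config <- function(w = 1.5, m = 5L, batch_size = 50L,
                           use_all_annotations = TRUE,
                           first_term = c("logistic", "exp"), seed = 1L) {
  if (w <= 1) cl_stop("credlift_config_error", "w must be > 1 (got %g)", w)
  if (m < 1 || batch_size < 1) {
    cl_stop("credlift_config_error", "m and batch_size must be positive")
  }
  structure(list(w = w, m = as.integer(m), batch_size = as.integer(batch_size),
                 use_all_annotations = isTRUE(use_all_annotations),
                 first_term = match.arg(first_term), seed = as.integer(seed)),
            class = "ranking_config")
}

#' Score a cluster from its label distribution
#'
#' The cluster priority score is
#' `logistic(p_n - p_c) + w^-(p_u + 1)`:
#' the first term rewards clusters whose annotated sentences skew
#' non-credible over credible (sigmoid of the contrast, so it saturates in
#' (0, 1)); the second penalizes neutral-heavy clusters, with base `w > 1`
#' controlling how hard. The score is strictly increasing in `p_n - p_c` at
#' fixed `p_u` and strictly decreasing in `p_u` at a fixed contrast, and lies
#' in `(0, 1 + 1/w)`.
#'
#' @param probs A `label_probs`.
#' @param w Neutral-penalty base, `> 1`.
#' @param first_term `"logistic"` (default) or `"exp"` (literal exponential
#'   contrast, unbounded; kept for sensitivity analysis).
#' @return An object of class `cluster_score` with `value`, `probs`,
#'   `w_used`.
#' @export
#' @examples
#' score_cluster(label_probs(p_c = 0.4, p_n = 0.5, p_u = 0.1), w = 1.5)
score_cluster <- function(probs, w, first_term = c("logistic", "exp")) {
  first_term <- match.arg(first_term)
  if (w <= 1) cl_stop("credlift_config_error", "w must be > 1 (got %g)", w)
  stopifnot(inherits(probs, "label_probs"))
  contrast <- probs$p_n - probs$p_c
  t1 <- if (first_term == "logistic") stats::plogis(contrast) else exp(contrast)
  value <- t1 + w^-(probs$p_u + 1)
  structure(list(value = value, probs = probs, w_used = w,
                 first_term = first_term),
            class = "cluster_score")
}

#' @export
print.cluster_score <- function(x, ...) {
  cat(sprintf("<cluster_score> %.6f (p_n=%.3f p_c=%.3f p_u=%.3f, w=%g)\n",
              x$value, x$probs$p_n, x$probs$p_c, x$probs$p_u, x$w_used))
  invisible(x)
}

#' Two-level reranking of the corpus
#'
#' Orders the not-yet-annotated sentences so that experts see likely
#' non-credible content first: clusters are sorted by descending score, and
#' within each cluster sentences are sorted by ascending cosine distance to
#' the centroid (most central — most representative — first). Ties break
#' deterministically: equal-score clusters by ascending cluster index, equal
#' distances by ascending sentence id.
#'
#' @param model A `cluster_model`.
#' @param probs_by_cluster List of `label_probs`, one per cluster (index
#'   1..k).
#' @param annotated_ids Character vector of sentence ids to exclude from the
#'   order (already annotated).
#' @param config A `ranking_config`.
#' @return An object of class `ranking`: `order` (sentence ids, highest
#'   priority first), `cluster_order`, `scores` (list of `cluster_score`),
#'   and a `table` tibble (rank, sentence_id, cluster, distance,
#'   cluster_score, p_c, p_n, p_u).
#' @export
rank_corpus <- function(model, probs_by_cluster, annotated_ids = character(0),
                        config = ranking_config()) {
  stopifnot(inherits(model, "cluster_model"))
  if (length(probs_by_cluster) != model$k) {
    cl_stop("credlift_probs_error",
            "need one label_probs per cluster (%d clusters, %d supplied)",
            model$k, length(probs_by_cluster))
  }
  scores <- lapply(probs_by_cluster, score_cluster, w = config$w,
                   first_term = config$first_term)
  values <- vapply(scores, `[[`, numeric(1), "value")
  cluster_order <- order(-values, seq_len(model$k))

  ids <- names(model$assignment)
  eligible <- setdiff(ids, annotated_ids)
  ord <- unlist(lapply(cluster_order, function(j) {
    member <- intersect(eligible, ids[model$assignment == j])
    member[order(model$distance[member], member)]
  }), use.names = FALSE)
  if (is.null(ord)) ord <- character(0)

  cl <- model$assignment[ord]
  tab <- tibble::tibble(
    rank = seq_along(ord),
    sentence_id = ord,
    cluster = as.integer(cl),
    distance = as.numeric(model$distance[ord]),
    cluster_score = values[cl],
    p_c = vapply(probs_by_cluster, `[[`, numeric(1), "p_c")[cl],
    p_n = vapply(probs_by_cluster, `[[`, numeric(1), "p_n")[cl],
    p_u = vapply(probs_by_cluster, `[[`, numeric(1), "p_u")[cl]
  )
  structure(list(order = ord, cluster_order = cluster_order,
                 scores = scores, table = tab),
            class = "ranking")
}

#' @export
print.ranking <- function(x, ...) {
  cat(sprintf("<ranking> %d sentences over %d clusters; head: %s\n",
              length(x$order), length(x$scores),
              paste(utils::head(x$order, 5), collapse = ", ")))
  invisible(x)
}

#' Export a ranking as CSV
#'
#' Writes the per-sentence ranking table (rank, sentence_id, cluster,
#' distance, cluster_score, p_c, p_n, p_u).
#'
#' @param ranking A `ranking`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "ranking"))
  utils::write.csv(as.data.frame(ranking$table), path, row.names = FALSE)
  invisible(path)
}
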