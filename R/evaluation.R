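resolve_gold <- function(gold) {
  if (is.data.frame(gold)) {
    gold <- stats::setNames(as.character(gold$gold_label), gold$sentence_id)
  }
  if (is.null(names(gold))) {
    cl_stop("credlift_eval_error", "gold labels must be a named vector or a corpus")
  }
  gold
}

#' Recall of non-credible sentences in the top of a ranking
#'
#' Fraction of all gold-`NONCRED` sentences found among the first `p`
#' positions of an annotation/ranking order. `gold` supplies the full-corpus
#' labels: either a named character vector (`sentence_id -> label`) or a
#' corpus tibble with a `gold_label` column; the corpus size `N` and the
#' non-credible total are taken from it, so sentences missing from a
#' truncated `order` simply count as not yet reviewed.
#'
#' @param order Character vector of sentence ids, highest priority first.
#' @param gold Gold labels for the whole corpus (named vector or corpus).
#' @param p Review depth: number of top sentences considered, `1 <= p <= N`.
#' @return Recall in \[0, 1\].
#' @export
recall_at <- function(order, gold, p) {
  gold <- resolve_gold(gold)
  N <- length(gold)
  if (p < 1 || p > N) cl_stop("credlift_eval_error", "p must be in [1, N=%d]; got %g", N, p)
  nn_ids <- names(gold)[!is.na(gold) & gold == "NONCRED"]
  if (length(nn_ids) == 0) {
    cl_stop("credlift_eval_error", "no gold-NONCRED sentences: recall undefined")
  }
  sum(utils::head(order, p) %in% nn_ids) / length(nn_ids)
}

#' Lift of a ranking at review depth p
#'
#' `lift = (N / p) * recall@p`: how many times more non-credible sentences an
#' expert reviewing the top `p` of the ranking encounters than under a random
#' review order. Random review gives lift 1 in expectation; the perfect
#' ranking attains `N / Nn` once all `Nn` non-credible sentences fit in the
#' top `p = Nn`; `lift@N = 1` exactly for every order.
#'
#' @inheritParams recall_at
#' @return Non-negative lift value.
#' @export
#' @examples
#' gold <- setNames(rep(c("NONCRED", "CRED"), c(2, 8)), paste0("s", 1:10))
#' lift_at(paste0("s", 1:10), gold, p = 2)  # perfect order: 10/2 * 1 = 5
lift_at <- function(order, gold, p) {
  gold <- resolve_gold(gold)
  (length(gold) / p) * recall_at(order, gold, p)
}

#' Lift curve over a percentile grid
#'
#' Evaluates recall and lift at a grid of review percentiles (defaults
#' 1/5/10/20/40/100%), mapping each percentile to the review count
#' `max(1, round(pct/100 * N))`.
#'
#' @inheritParams recall_at
#' @param percentiles Numeric vector of percentages in (0, 100].
#' @return A `lift_curve`: list with `N`, `Nn` and a `points` tibble
#'   (percentile, p, recall, lift).
#' @export
lift_curve <- function(order, gold, percentiles = c(1, 5, 10, 20, 40, 100)) {
  gold <- resolve_gold(gold)
  N <- length(gold)
  ps <- pmax(1, pmin(N, round(percentiles / 100 * N)))
  pts <- tibble::tibble(
    percentile = percentiles,
    p = as.integer(ps),
    recall = vapply(ps, function(p) recall_at(order, gold, p), numeric(1)),
    lift = vapply(ps, function(p) lift_at(order, gold, p), numeric(1))
  )
  structure(list(N = N, Nn = sum(!is.na(gold) & gold == "NONCRED"), points = pts),
            class = "lift_curve")
}

#' @export
print.lift_curve <- function(x, ...) {
  cat(sprintf("<lift_curve> N=%d, non-credible=%d\n", x$N, x$Nn))
  print(x$points)
  invisible(x)
}

#' Monte Carlo lift of uniformly random review orders
#'
#' Draws `n_permutations` seeded uniform random orders of the corpus and
#' evaluates lift at depth `p` for each. The expected lift of a random order
#' is exactly 1 at every depth, so the mean here is the empirical baseline a
#' prioritization method must beat.
#'
#' @inheritParams recall_at
#' @param n_permutations Number of random orders (>= 1).
#' @param seed Integer seed; results are deterministic given it.
#' @return List with `mean`, `sd` and the per-permutation `values`.
#' @export
random_baseline_lift <- function(gold, p, n_permutations, seed) {
  gold <- resolve_gold(gold)
  if (n_permutations < 1) cl_stop("credlift_eval_error", "n_permutations must be >= 1")
  ids <- names(gold)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  values <- vapply(seq_len(n_permutations), function(i) {
    lift_at(sample(ids), gold, p)
  }, numeric(1))
  list(mean = mean(values), sd = stats::sd(values), values = values)
}

#' Context-need statistics by label
#'
#' Tabulates how many surrounding sentences annotators consulted
#' (`context_needed`), bucketed as 0 / 1 / 2 / 3 / >3, for each label and
#' overall — the diagnostic that shows whether single sentences are a
#' self-sufficient annotation unit.
#'
#' @param annotations Tibble of annotation records with `label` and
#'   `context_needed`.
#' @return Tibble (label, context_bucket, count, percent); `label = "ALL"`
#'   rows aggregate across labels. Empty input yields an empty tibble.
#' @export
context_stats <- function(annotations) {
  annotations <- tibble::as_tibble(annotations)
  empty <- tibble::tibble(label = character(0), context_bucket = character(0),
                          count = integer(0), percent = numeric(0))
  if (nrow(annotations) == 0) return(empty)
  buckets <- c("0", "1", "2", "3", ">3")
  bucket_of <- function(v) ifelse(v > 3, ">3", as.character(v))
  one_group <- function(label, sub) {
    b <- factor(bucket_of(sub$context_needed), levels = buckets)
    counts <- table(b)
    keep <- counts > 0
    tibble::tibble(label = label, context_bucket = names(counts)[keep],
                   count = as.integer(counts[keep]),
                   percent = 100 * as.integer(counts[keep]) / nrow(sub))
  }
  groups <- lapply(sort(unique(annotations$label)), function(l) {
    one_group(l, annotations[annotations$label == l, ])
  })
  do.call(rbind, c(list(one_group("ALL", annotations)), groups))
}

#' Label distribution by topic
#'
#' Per-topic counts and proportions of the three credibility labels, the
#' descriptive view of how credible/non-credible/neutral content spreads
#' across topics.
#'
#' @param corpus A sentence corpus; labels come from `gold_label` unless
#'   `annotations` is supplied.
#' @param annotations Optional annotation tibble; its labels (joined on
#'   `sentence_id`) replace `gold_label`.
#' @return Tibble (topic, label, n, proportion); proportions sum to 1 within
#'   each topic.
#' @export
label_distribution <- function(corpus, annotations = NULL) {
  corpus <- as_sentence_corpus(corpus)
  labels <- corpus$gold_label
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    labels <- stats::setNames(annotations$label,
                              annotations$sentence_id)[corpus$sentence_id]
  }
  keep <- !is.na(labels)
  df <- data.frame(topic = corpus$topic[keep], label = labels[keep])
  if (nrow(df) == 0) {
    return(tibble::tibble(topic = character(0), label = character(0),
                          n = integer(0), proportion = numeric(0)))
  }
  counts <- as.data.frame(table(topic = df$topic, label = df$label),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0, ]
  totals <- tapply(df$label, df$topic, length)
  out <- tibble::tibble(topic = counts$topic, label = counts$label,
                        n = as.integer(counts$Freq),
                        proportion = counts$Freq / as.numeric(totals[counts$topic]))
  out[order(out$topic, out$label), ]
}
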