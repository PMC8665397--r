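#' Parameters of the synthetic labeled-corpus generator
#'
#' The generator emulates the statistical structure active annotation
#' exploits in real medical web text: sentences fall into semantic clusters
#' (Gaussian blobs in embedding space), credibility labels follow a global
#' prior in which credible content is at least twice as frequent as
#' non-credible and neutral stays under ~30%, and the non-credible mass is
#' concentrated in a minority of clusters (recurring misinformation claim
#' categories). A designated `enrichment` fraction of clusters carries
#' `enriched_p_n` non-credible probability; the generator solves the residual
#' non-credible probability of the remaining clusters so the marginal label
#' frequencies match `label_prior`.
#'
#' @param n Corpus size (default 2000, a single-topic-sized batch).
#' @param n_clusters Number of semantic clusters (default 12).
#' @param dim Embedding dimensionality (default 16).
#' @param label_prior Numeric `c(p_c, p_n, p_u)` marginal label prior
#'   (default `c(0.55, 0.18, 0.27)`).
#' @param enrichment Fraction of clusters designated misinformation-enriched
#'   (default 0.2).
#' @param enriched_p_n Non-credible probability inside enriched clusters
#'   (default 0.6); must exceed the prior `p_n`.
#' @param cluster_spread Within-cluster standard deviation (default 0.3).
#' @param separation Between-centroid scale (default 1.0).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A validated `generator_params` list, including the solved
#'   `residual_p_n` and the per-cluster-type label distributions.
#' @export
generator_params <- function(n = 2000L, n_clusters = 12L, dim = 16L,
                             label_prior = c(p_c = 0.55, p_n = 0.18, p_u = 0.27),
                             enrichment = 0.2, enriched_p_n = 0.6,
                             cluster_spread = 0.3, separation = 1.0, seed = 1L) {
  if (abs(sum(label_prior) - 1) > 1e-9) {
    cl_stop("credlift_param_error", "label_prior must sum to 1")
  }
  p_c <- label_prior[[1]]; p_n <- label_prior[[2]]; p_u <- label_prior[[3]]
  if (enriched_p_n <= p_n || enriched_p_n > 1) {
    cl_stop("credlift_param_error",
            "enriched_p_n must lie in (label prior p_n, 1]")
  }
  n_enriched <- round(enrichment * n_clusters)
  f_e <- n_enriched / n_clusters
  residual_p_n <- (p_n - f_e * enriched_p_n) / max(1 - f_e, .Machine$double.eps)
  if (n_enriched < n_clusters && residual_p_n < 0) {
    cl_stop("credlift_param_error",
            "infeasible parameters: residual non-enriched p_n would be %.4f < 0",
            residual_p_n)
  }
  split_rest <- function(pn_cluster) {
    rest <- 1 - pn_cluster
    c(p_c = rest * p_c / (p_c + p_u), p_n = pn_cluster, p_u = rest * p_u / (p_c + p_u))
  }
  structure(list(
    n = as.integer(n), n_clusters = as.integer(n_clusters), dim = as.integer(dim),
    label_prior = c(p_c = p_c, p_n = p_n, p_u = p_u),
    enrichment = enrichment, enriched_p_n = enriched_p_n,
    n_enriched = as.integer(n_enriched), residual_p_n = residual_p_n,
    enriched_dist = split_rest(enriched_p_n),
    residual_dist = split_rest(residual_p_n),
    cluster_spread = cluster_spread, separation = separation,
    seed = as.integer(seed)
  ), class = "generator_params")
}

#' Generate a labeled synthetic corpus with embeddings
#'
#' Draws `n_clusters` centroids at scale `separation`, places sentences
#' around them as isotropic Gaussians at `cluster_spread`, and assigns each
#' sentence a gold credibility label from its cluster's distribution
#' (enriched or residual; see [generator_params()]). Text fields are
#' placeholder strings; the point of this generator is the embedding-space
#' and label structure, not language.
#'
#' @param params A [generator_params()].
#' @return List with `corpus` (sentence tibble with `gold_label`),
#'   `embeddings` (`embedding_matrix`, not post-processed), and
#'   `true_cluster` (named integer vector of generating cluster indices).
#' @export
generate_vector_corpus <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  k <- params$n_clusters
  centroids <- matrix(stats::rnorm(k * params$dim, sd = params$separation),
                      nrow = k)
  enriched <- sample.int(k, params$n_enriched)
  membership <- sample.int(k, params$n, replace = TRUE)
  vectors <- centroids[membership, , drop = FALSE] +
    matrix(stats::rnorm(params$n * params$dim, sd = params$cluster_spread),
           nrow = params$n)

  labels <- character(params$n)
  lab_values <- c("CRED", "NONCRED", "NEU")
  for (j in seq_len(k)) {
    idx <- which(membership == j)
    dist <- if (j %in% enriched) params$enriched_dist else params$residual_dist
    labels[idx] <- sample(lab_values, length(idx), replace = TRUE, prob = dist)
  }

  ids <- sprintf("s%05d", seq_len(params$n))
  corpus <- as_sentence_corpus(tibble::tibble(
    sentence_id = ids,
    text = sprintf("synthetic sentence %d (cluster %d)", seq_len(params$n), membership),
    topic = sprintf("topic_%02d", membership),
    source_id = NA_character_,
    gold_label = labels
  ))
  list(
    corpus = corpus,
    embeddings = embedding_matrix(ids, vectors, backend = "synthetic_gaussian"),
    true_cluster = stats::setNames(membership, ids),
    enriched_clusters = sort(enriched)
  )
}

#' Default template bank for the text-mode generator
#'
#' A small bank of seeded sentence templates grouped into claim-category-like
#' topics, each tagged with a gold label. Wording is deliberately abstract
#' (drug/therapy/marker placeholders) so no realistic medical misinformation
#' is produced; within-topic templates share vocabulary so the
#' hash-projection encoder places them close together.
#'
#' @return Tibble (template_id, topic, label, text) where `text` contains a
#'   `{mod}` slot filled with a per-sentence variant word.
#' @export
default_template_bank <- function() {
  tibble::tibble(
    template_id = sprintf("t%02d", 1:12),
    topic = rep(c("therapy_alpha", "supplement_beta", "marker_gamma", "lifestyle_delta"),
                each = 3),
    label = rep(c("CRED", "NONCRED", "NEU"), times = 4),
    text = c(
      "therapy alpha lowers marker levels in {mod} controlled trials",
      "therapy alpha secretly harms every {mod} patient who takes it",
      "what do {mod} patients think about therapy alpha",
      "supplement beta shows no measurable {mod} benefit in trials",
      "supplement beta cures every {mod} chronic disease instantly",
      "the {mod} supplement beta report was published yesterday",
      "marker gamma predicts {mod} cardiovascular risk in cohort studies",
      "ignore your {mod} marker gamma results doctors hide the truth",
      "how is the {mod} marker gamma test performed",
      "regular {mod} exercise and diet reduce long term risk",
      "skipping all {mod} checkups keeps you healthier than doctors admit",
      "the {mod} lifestyle survey closes next week"
    )
  )
}

#' Generate a labeled synthetic text corpus
#'
#' Samples templates from a bank (template choice weighted so labels follow
#' `params$label_prior`), fills the `{mod}` slot with a seeded variant word,
#' and tags each sentence with its template's topic and gold label. Suitable
#' for end-to-end runs through [hash_projection_backend()].
#'
#' @param params A [generator_params()] (uses `n`, `label_prior`, `seed`).
#' @param template_bank Tibble with columns `template_id`, `topic`, `label`,
#'   `text` (see [default_template_bank()]).
#' @return A sentence corpus tibble with `gold_label` and a `template_id`
#'   attribute recording provenance.
#' @export
generate_text_corpus <- function(params = generator_params(),
                                 template_bank = default_template_bank()) {
  template_bank <- tibble::as_tibble(template_bank)
  if (nrow(template_bank) == 0) {
    cl_stop("credlift_param_error", "template bank is empty")
  }
  bad <- setdiff(template_bank$label, credibility_labels())
  if (length(bad) > 0) {
    cl_stop("credlift_unknown_label_error", "template bank has unknown label(s): %s",
            paste(bad, collapse = ", "))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  prior <- params$label_prior
  lab_weight <- c(CRED = prior[["p_c"]], NONCRED = prior[["p_n"]], NEU = prior[["p_u"]])
  per_label_count <- table(factor(template_bank$label, levels = names(lab_weight)))
  w <- lab_weight[template_bank$label] / pmax(as.numeric(per_label_count[template_bank$label]), 1)
  tpl_idx <- sample.int(nrow(template_bank), params$n, replace = TRUE, prob = w)

  mods <- c("recent", "large", "small", "new", "older", "local", "major", "minor")
  mod <- sample(mods, params$n, replace = TRUE)
  texts <- vapply(seq_len(params$n), function(i) {
    sub("{mod}", mod[i], template_bank$text[tpl_idx[i]], fixed = TRUE)
  }, character(1))

  corpus <- as_sentence_corpus(tibble::tibble(
    sentence_id = sprintf("s%05d", seq_len(params$n)),
    text = texts,
    topic = template_bank$topic[tpl_idx],
    source_id = template_bank$template_id[tpl_idx],
    gold_label = template_bank$label[tpl_idx]
  ))
  attr(corpus, "template_id") <- template_bank$template_id[tpl_idx]
  corpus
}
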