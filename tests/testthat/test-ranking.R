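test_that("estimate_probs counts labels and falls back to the prior", {
  p <- estimate_probs(c("NONCRED", "NONCRED", "CRED", "NEU", "NONCRED"))
  expect_equal(c(p$p_n, p$p_c, p$p_u), c(0.6, 0.2, 0.2))
  expect_equal(p$n_annotated, 5L)

  prior <- label_probs(0.55, 0.18, 0.27)
  p0 <- estimate_probs(character(0), fallback_prior = prior)
  expect_equal(c(p0$p_c, p0$p_n, p0$p_u), c(0.55, 0.18, 0.27))
  expect_equal(p0$n_annotated, 0L)

  # p_u is whatever the annotated fractions leave over
  p2 <- estimate_probs(rep(c("NONCRED", "CRED", "NEU"), c(5, 4, 1)))
  expect_equal(p2$p_u, 1 - p2$p_n - p2$p_c)
  expect_equal(p2$p_u, 0.1)

  expect_error(estimate_probs("MAYBE"), class = "credlift_unknown_label_error")
  expect_error(label_probs(0.5, 0.5, 0.5), class = "credlift_probs_error")
})

test_that("cluster score matches its closed form and the worked comparison", {
  # frozen from an independent high-precision evaluation of
  # logistic(0.1) + 1.5^-(p_u + 1)
  hi <- score_cluster(label_probs(p_c = 0.4, p_n = 0.5, p_u = 0.1), w = 1.5)
  lo <- score_cluster(label_probs(p_c = 0.3, p_n = 0.4, p_u = 0.3), w = 1.5)
  expect_equal(hi$value, 1.16515552134042, tolerance = 1e-12)
  expect_equal(lo$value, 1.11529084967598, tolerance = 1e-12)
  expect_gt(hi$value, lo$value)

  # same contrast, no neutral: value = logistic(0) + 1/w = 0.5 + 1/w exactly
  for (w in c(1.2, 1.5, 3)) {
    tie <- score_cluster(label_probs(0.5, 0.5, 0), w = w)
    expect_equal(tie$value, 0.5 + 1 / w, tolerance = 1e-14)
  }

  expect_error(score_cluster(label_probs(1, 0, 0), w = 1),
               class = "credlift_config_error")

  # the literal exponential reading preserves the worked-example ordering
  hi_e <- score_cluster(label_probs(0.4, 0.5, 0.1), w = 1.5, first_term = "exp")
  lo_e <- score_cluster(label_probs(0.3, 0.4, 0.3), w = 1.5, first_term = "exp")
  expect_gt(hi_e$value, lo_e$value)
})

test_that("without the neutral penalty the worked-example clusters tie", {
  first_term_only <- function(p_n, p_c) plogis(p_n - p_c)
  expect_equal(first_term_only(0.5, 0.4), first_term_only(0.4, 0.3),
               tolerance = 1e-15)
})

test_that("score is monotone: up in the contrast, down in the neutral share", {
  for (w in c(1.1, 1.5, 3)) {
    # increasing p_n - p_c at fixed p_u
    p_u <- 0.2
    contrasts <- seq(-0.8, 0.8, by = 0.1)
    vals <- vapply(contrasts, function(d) {
      rest <- 1 - p_u
      score_cluster(label_probs((rest - d) / 2, (rest + d) / 2, p_u), w)$value
    }, numeric(1))
    expect_true(all(diff(vals) > 0))

    # increasing p_u at fixed contrast
    d <- 0.1
    pus <- seq(0, 0.8, by = 0.1)
    vals_u <- vapply(pus, function(p_u) {
      rest <- 1 - p_u
      score_cluster(label_probs((rest - d) / 2, (rest + d) / 2, p_u), w)$value
    }, numeric(1))
    expect_true(all(diff(vals_u) < 0))

    # bound: value in (0, 1 + 1/w)
    expect_true(all(vals > 0 & vals < 1 + 1 / w))
    expect_true(all(vals_u > 0 & vals_u < 1 + 1 / w))
  }
})

test_that("rank_corpus applies the two-level sort and exclusion rule", {
  model <- structure(list(
    k = 2L, centroids = diag(2),
    assignment = c(a = 1L, b = 1L, c = 2L),
    distance = c(a = 0.2, b = 0.1, c = 0.4),
    inertia = 0, seed = 1L
  ), class = "cluster_model")
  probs <- list(label_probs(0.1, 0.8, 0.1),   # high score
                label_probs(0.8, 0.1, 0.1))   # low score
  rk <- rank_corpus(model, probs)
  expect_identical(rk$order, c("b", "a", "c"))

  rk2 <- rank_corpus(model, probs, annotated_ids = "b")
  expect_identical(rk2$order, c("a", "c"))

  expect_error(rank_corpus(model, probs[1]), class = "credlift_probs_error")
})

test_that("rank_corpus agrees with a brute-force sort on random instances", {
  set.seed(31)
  n <- 30; k <- 4
  ids <- sprintf("r%02d", sample(n))  # shuffled ids exercise tie-breaking
  assignment <- stats::setNames(sample(k, n, replace = TRUE), ids)
  assignment[1:k] <- 1:k  # every cluster non-empty
  distance <- stats::setNames(round(runif(n), 2), ids)  # rounding forces ties
  model <- structure(list(k = as.integer(k), centroids = diag(k),
                          assignment = assignment, distance = distance,
                          inertia = 1, seed = 1L), class = "cluster_model")
  probs <- lapply(1:k, function(j) {
    x <- c(runif(3)); x <- x / sum(x)
    label_probs(x[1], x[2], x[3])
  })
  rk <- rank_corpus(model, probs, config = ranking_config(w = 1.5))

  # independent oracle: direct formula + single order() call
  score <- vapply(probs, function(p) {
    1 / (1 + exp(-(p$p_n - p$p_c))) + 1.5^-(p$p_u + 1)
  }, numeric(1))
  cl <- as.integer(assignment[ids])
  expected <- ids[order(-score[cl], cl, distance[ids], ids)]
  expect_identical(rk$order, expected)

  # stability: identical inputs, identical order
  expect_identical(rank_corpus(model, probs, config = ranking_config())$order,
                   rk$order)
})
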