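mk_gold <- function(labels) stats::setNames(labels, paste0("g", seq_along(labels)))

test_that("recall and lift match hand counts on the worked instance", {
  # N = 10, non-credible sitting at ranks 1, 2, 5, 9 of the order
  labels <- rep("CRED", 10)
  labels[c(1, 2, 5, 9)] <- "NONCRED"
  gold <- mk_gold(labels)
  order <- names(gold)  # identity order puts them at those ranks
  expect_equal(recall_at(order, gold, 5), 3 / 4)
  expect_equal(lift_at(order, gold, 5), (10 / 5) * 0.75)

  expect_equal(recall_at(order, gold, 10), 1.0)
  no_top <- c(names(gold)[c(3, 4, 6)], names(gold)[-c(3, 4, 6)])
  expect_equal(recall_at(no_top, gold, 3), 0.0)

  expect_error(recall_at(order, gold, 11), class = "credlift_eval_error")
  expect_error(recall_at(order, mk_gold(rep("CRED", 4)), 2),
               class = "credlift_eval_error")
})

test_that("lift identities: lift@N = 1 and the perfect order attains N/Nn", {
  set.seed(17)
  for (i in 1:5) {
    N <- sample(10:40, 1)
    labels <- sample(c("CRED", "NONCRED", "NEU"), N, replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
    if (!any(labels == "NONCRED")) labels[1] <- "NONCRED"
    gold <- mk_gold(labels)
    any_order <- sample(names(gold))
    expect_equal(lift_at(any_order, gold, N), 1.0, tolerance = 1e-12)

    Nn <- sum(labels == "NONCRED")
    perfect <- c(names(gold)[labels == "NONCRED"], names(gold)[labels != "NONCRED"])
    expect_equal(lift_at(perfect, gold, Nn), N / Nn, tolerance = 1e-12)
  }
})

test_that("lift agrees with the independent brute-force count on random instances", {
  set.seed(23)
  for (i in 1:20) {
    N <- sample(5:50, 1)
    labels <- sample(c("CRED", "NONCRED", "NEU"), N, replace = TRUE)
    if (!any(labels == "NONCRED")) labels[N] <- "NONCRED"
    gold <- mk_gold(labels)
    order <- sample(names(gold))
    for (p in unique(c(1, sample(N, min(5, N)), N))) {
      expect_equal(lift_at(order, gold, p), brute_lift(order, gold, p),
                   tolerance = 1e-12)
    }
  }
})

test_that("the perfect order maximizes lift over all orders (exhaustive, small N)", {
  labels <- c("NONCRED", "CRED", "NONCRED", "CRED", "NEU", "CRED")
  gold <- mk_gold(labels)
  ids <- names(gold)
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  perfect <- c(ids[labels == "NONCRED"], ids[labels != "NONCRED"])
  for (p in 1:6) {
    best <- max(apply(perms, 1, function(ix) lift_at(ids[ix], gold, p)))
    expect_equal(lift_at(perfect, gold, p), best, tolerance = 1e-12)
  }
})

test_that("random orders have mean lift 1 (Monte Carlo within 3 SE)", {
  set.seed(41)
  labels <- sample(rep(c("NONCRED", "CRED", "NEU"), c(36, 110, 54)))
  gold <- mk_gold(labels)
  bl <- random_baseline_lift(gold, p = 20, n_permutations = 400, seed = 13)
  se <- bl$sd / sqrt(length(bl$values))
  expect_lt(abs(bl$mean - 1), 3 * se)

  # reproducible given the seed
  bl2 <- random_baseline_lift(gold, p = 20, n_permutations = 400, seed = 13)
  expect_identical(bl$values, bl2$values)

  # all sentences non-credible: recall = p/N, lift identically 1
  allnc <- mk_gold(rep("NONCRED", 15))
  one <- random_baseline_lift(allnc, p = 4, n_permutations = 10, seed = 1)
  expect_true(all(abs(one$values - 1) < 1e-12))
})

test_that("context statistics bucket and percentage correctly", {
  ann <- rbind(
    annotation_record("s1", "NONCRED", context_needed = 0L),
    annotation_record("s2", "NONCRED", context_needed = 0L, annotator_id = "b"),
    annotation_record("s3", "CRED", context_needed = 1L),
    annotation_record("s4", "NEU", context_needed = 2L)
  )
  tab <- context_stats(ann)
  all_rows <- tab[tab$label == "ALL", ]
  expect_identical(all_rows$context_bucket, c("0", "1", "2"))
  expect_identical(all_rows$count, c(2L, 1L, 1L))
  expect_equal(all_rows$percent, c(50, 25, 25))
  nc <- tab[tab$label == "NONCRED", ]
  expect_equal(nc$percent, 100)

  deep <- context_stats(annotation_record("s1", "CRED", context_needed = 7L))
  expect_identical(deep$context_bucket[deep$label == "ALL"], ">3")

  expect_equal(nrow(context_stats(ann[0, ])), 0)
})

test_that("label distributions are per-topic proportions summing to one", {
  corp <- as_sentence_corpus(tibble::tibble(
    sentence_id = paste0("s", 1:7),
    text = paste("sentence", 1:7),
    topic = c(rep("statins", 4), rep("vaccines", 3)),
    gold_label = c("CRED", "CRED", "NONCRED", "NEU", "CRED", "NONCRED", "NONCRED")
  ))
  dist <- label_distribution(corp)
  st <- dist[dist$topic == "statins", ]
  expect_equal(st$proportion[st$label == "CRED"], 0.5)
  expect_equal(st$proportion[st$label == "NONCRED"], 0.25)
  expect_equal(st$proportion[st$label == "NEU"], 0.25)
  sums <- tapply(dist$proportion, dist$topic, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  # annotations override gold labels
  ann <- rbind(annotation_record("s1", "NEU"), annotation_record("s5", "NONCRED"))
  dist2 <- label_distribution(corp, annotations = ann)
  expect_equal(sum(dist2$n), 2L)
  expect_true(all(abs(tapply(dist2$proportion, dist2$topic, sum) - 1) < 1e-12))
})
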