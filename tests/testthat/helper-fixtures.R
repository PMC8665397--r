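# Small fixtures built in code; no files on disk.

toy_corpus <- function(n = 3) {
  as_sentence_corpus(tibble::tibble(
    sentence_id = paste0("s", seq_len(n)),
    text = paste("toy sentence number", seq_len(n)),
    topic = "toy_topic",
    source_id = NA_character_,
    gold_label = rep_len(c("CRED", "NONCRED", "NEU"), n)
  ))
}

# k well-separated Gaussian blobs; separation is in units of the spread
blob_embeddings <- function(n, k, d, seed, spread = 0.05, separation = 5) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), nrow = k)
  centers <- centers / sqrt(rowSums(centers^2)) * separation
  member <- rep_len(seq_len(k), n)
  V <- centers[member, ] + matrix(rnorm(n * d, sd = spread), nrow = n)
  list(
    X = embedding_matrix(sprintf("b%04d", seq_len(n)), V, backend = "blob"),
    member = member
  )
}

# all permutations of 1..n (recursive; used only for tiny n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}

# independent brute-force lift: explicit count over the top-p prefix
brute_lift <- function(order, gold, p) {
  nn <- names(gold)[gold == "NONCRED"]
  hits <- 0
  for (id in order[seq_len(min(p, length(order)))]) {
    if (id %in% nn) hits <- hits + 1
  }
  (length(gold) / p) * (hits / length(nn))
}
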