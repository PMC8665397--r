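# credlift

Active annotation for medical sentence credibility: cluster a sentence
corpus in embedding space, score clusters from partial expert labels, and
rerank the un-annotated sentences so that likely **non-credible** content
reaches the expert first. Includes a simulated expert-in-the-loop annotation
loop, lift/recall ranking evaluation, annotation-protocol data structures
(CRED/NONCRED/NEU labels, a nine-item reason-tag vocabulary, context-need
statistics), and a synthetic labeled-corpus generator so everything runs
fully offline.

## Who this is for

Teams building expert-labeled corpora of medical (or other specialist) web
text, where annotator time is expensive and the label of interest —
non-credible content — is rare. Instead of reviewing sentences in arbitrary
order, the expert reviews a ranking that concentrates probable
non-credible sentences at the top, typically finding substantially more of
them per hour of review.

## The method

1. **Embed** each sentence with a pluggable encoder; post-process the
   matrix by subtracting the corpus mean and removing the first principal
   component (strips dominant non-semantic variation).
2. **Cluster** the normalized vectors with k-means (kmeans++ seeding;
   cluster count `k` by the elbow rule) and take the `m` most central
   *pivot* sentences per cluster.
3. **Annotate** the pivots (expert, or a simulated oracle reading gold
   labels).
4. **Score** each cluster from its observed label fractions
   `p_c, p_n, p_u` (credible / non-credible / neutral):

   `score = sigmoid(p_n − p_c) + w^−(p_u + 1)`, with `w > 1` (default 1.5).

   The sigmoid rewards a non-credible-over-credible contrast; the second
   term penalizes neutral-heavy clusters.
5. **Rerank** all remaining sentences — clusters by descending score,
   sentences within a cluster by ascending cosine distance to the
   centroid — annotate the next batch, and repeat.

Prioritization quality is evaluated with **lift**:
`lift@p = (N / p) · recall@p`, the factor by which the top `p` of the
ranking beats random review (baseline 1).

## Worked example

Simulate the loop on a synthetic corpus of 2000 sentences (18%
non-credible, concentrated in a fifth of the 12 semantic clusters) with a
budget of 400 expert annotations:

```r
library(credlift)

g   <- generate_vector_corpus(generator_params(seed = 7))
X   <- postprocess_embeddings(g$embeddings)
log <- run_loop(g$corpus, X, gold_oracle(g$corpus), budget = 400,
                ranking_config(seed = 7), k = 12)

gold <- setNames(g$corpus$gold_label, g$corpus$sentence_id)
lift_curve(replay_annotations(log), gold, percentiles = c(1, 5, 10, 20))
#> <lift_curve> N=2000, non-credible=323
#> # A tibble: 4 × 4
#>   percentile     p  recall  lift
#>        <dbl> <int>   <dbl> <dbl>
#> 1          1    20 0.00310 0.310
#> 2          5   100 0.102   2.04
#> 3         10   200 0.285   2.85
#> 4         20   400 0.579   2.89
```

Reading the table: after reviewing 10% of the corpus in the loop's order,
the expert has seen 28.5% of all non-credible sentences — 2.85× what random
review delivers (`random_baseline_lift()` on the same corpus gives 1.000).
The low value at 1% is the pivot phase: the first 60 annotations are
cluster centers chosen for coverage, not yet informed by any labels.

The cluster score behaves as designed — with `w = 1.5`, a cluster at
`p_n = 0.5, p_c = 0.4` outranks one at `p_n = 0.4, p_c = 0.3` (equal
contrast, heavier neutral share):

```r
score_cluster(label_probs(p_c = 0.4, p_n = 0.5, p_u = 0.1), w = 1.5)
#> <cluster_score> 1.165156 (p_n=0.500 p_c=0.400 p_u=0.100, w=1.5)
```

A thin CLI wraps the same functions
(`exec/credlift generate | simulate | evaluate`); see the file header for
usage, and `vignettes/active-annotation.Rmd` for the full methods account.

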