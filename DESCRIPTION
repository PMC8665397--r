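Package: credlift
Title: Active Annotation and Lift Evaluation for Medical Sentence Credibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prioritizing expert annotation of medical sentences by
    credibility. Sentences are embedded with a pluggable encoder, post-processed
    by mean subtraction and first-principal-component removal, grouped with
    k-means (cluster count chosen by the elbow method), and scored from partial
    expert labels so that clusters rich in non-credible content rise to the top
    of the annotation queue. Includes a simulated expert-in-the-loop annotation
    loop, recall/lift ranking evaluation, descriptive annotation statistics,
    and a synthetic labeled-corpus generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
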