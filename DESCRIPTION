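Package: minicolearn
Title: Reward-Gated Clustered Synaptic Plasticity in Cortical Minicolumns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for trial-and-error pattern learning by abstract
    pyramidal neurons whose basal dendrites carry random synaptic clusters.
    A cluster is a small set of distinct input sources with an integer
    weight; its weight is potentiated when all (or at least G) of its
    sources are coincidently active while the cell is fired apically and a
    positive or neutral reward arrives, and weakened on punishment.
    Networks of minicolumns (one layer-5 learner plus optional layer-2/3
    cells per column) classify synthetic one-dimensional input patterns by
    winner-take-all over summed active-cluster weights. Includes exact
    combinatorial selection-capacity calculations, a synthetic pattern
    generator for bar-like objects, a worked concept-extraction demo, and
    seeded, reproducible experiment sweeps with run-level CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
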