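Package: skrdmkcf
Title: Synergistic Kruskal-RFE Feature Selection and Distributed
    Multi-Kernel Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis pipeline for high-dimensional tabular
    biomedical data. Stage one ranks features by a weighted combination of
    variance and a Kruskal-Wallis-type rank separability statistic and prunes
    them by recursive feature elimination driven by linear support vector
    machine weights, selecting the subset that maximizes a joint
    relevance/accuracy/efficiency objective. Stage two classifies the reduced
    data with a multi-kernel support vector machine (convex combination of
    linear, polynomial and radial basis kernels on a shared landmark basis)
    trained by consensus ADMM across simulated compute nodes. Includes a
    seeded synthetic-data generator emulating four clinical data archetypes,
    evaluation metrics (confusion-matrix metrics, feature reduction ratio,
    relevance score, timing instrumentation), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
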