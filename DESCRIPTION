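Package: phonofluency
Title: Phonological Network Verbal Fluency Scoring and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores phonological verbal-fluency response streams with graded
    edit-distance fluency measures (weighted edit, running edit, syllable
    neighbours, errors), builds participant-level phonological networks over
    the five-slot Mandarin syllable schema (onset, glide, nucleus, coda,
    tone), and computes component-weighted network statistics (clustering
    coefficient, degree assortativity, component counts, hop distributions).
    Includes outlier-exclusion quality control, cohort-level descriptive
    reporting, and a synthetic-cohort generator with known ground-truth
    search-strategy mixtures for end-to-end pipeline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    stringr,
    readr,
    igraph,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
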