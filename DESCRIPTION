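Package: socioscan
Title: Social Network Analysis of Behavioural Scan Data in Human-Wildlife Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing instantaneous scan-sampling data from wild animal
    groups that split their time between anthropogenic and natural contexts.
    Builds half-weight association index (HWI) networks per context and data type
    (proximity within 1 m, directed affiliative interactions), corrects unequal
    sampling effort across contexts by monthly-matched random subsampling,
    fits permutation-based linear regressions of road presence on life-history
    and network predictors with sequential stopping, compares per-individual
    network metrics across contexts with randomization tests, detects community
    structure with the walktrap algorithm, and ships a synthetic scan-data
    generator with known ground truth for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
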