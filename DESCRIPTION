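Package: oncoamp
Title: Amplicon-Driven Candidate Oncogene Discovery from SNP-Array, qPCR
    and Expression Data
Version: 0.9.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying candidate oncogenes in
    focally amplified chromosomal regions of tumours, modelled on the
    osteosarcoma 17p11.2-p12 amplicon. Includes relative-quantification
    (delta-delta-Ct) qPCR gene dosage and cohort screening, absolute integer
    copy-number calling from SNP-array LRR/BAF intensities with aneuploidy
    correction, GISTIC-style G-score scanning for recurrently amplified
    regions with a cyclic-shift permutation null and Benjamini-Hochberg FDR,
    and integration of copy number with expression to rank genes by
    overexpression-given-amplification and a Pearson correlation filter.
    A seeded synthetic-cohort generator with known ground truth makes every
    stage testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    data.table,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
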