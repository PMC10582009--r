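Package: erosure
Title: Genomic Erosion Metrics for Conservation Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-variant-calling population-genomic analyses for monitoring
    genomic erosion in wild populations: PLINK-style scanning-window detection
    of runs of homozygosity (ROH) with F_ROH and ROH-length dating of
    inbreeding events; per-individual heterozygosity, windowed nucleotide
    diversity and Weir-Cockerham / Hudson F_ST; genetic-load accounting
    (impact-stratified carrier counts, synonymous-normalised totals, realised
    load, and the R_xy frequency ratio with block-jackknife intervals);
    Z-transformed F_ST selection scans with gene intersection; and the
    three-level genetic-diversity indicators (delta-H, Ne, delta-F_ST)
    classified as Acceptable, Warning or Alarm. Includes a seeded
    Balding-Nichols cohort simulator with planted ROH and programmed temporal
    change for validation, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
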