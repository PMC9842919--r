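Package: bundlekit
Title: Streamline Bundle Clustering and Cohort Statistics for Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population studies of white-matter microstructure with
    diffusion tensor imaging. Implements multi-subject streamline bundle
    clustering (Ward agglomeration on flip-invariant streamline distances,
    cross-subset label matching, consensus segmentation over repeated random
    partitions), tract rasterization and per-tract fractional anisotropy and
    volume extraction, diffusion tensor fitting with FA/MD/AD/RD scalar maps,
    a simplified skeleton projection, scan-to-scan head-motion summaries,
    intracranial-volume matched pair construction, mean-centered multiple
    regression with permutation inference (Freedman-Lane, max-statistic and
    threshold-free cluster enhancement corrections), Benjamini-Hochberg family
    correction and standard effect sizes. A synthetic-data layer generates
    geometric streamline phantoms, diffusion-weighted volumes and covariate
    cohorts so the full pipeline can be exercised end to end without subject
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
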