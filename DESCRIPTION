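Package: tfcoverage
Title: Coverage Auditing and Prioritization of Transcription Factor ChIP-seq Compendia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Audits the coverage of transcription factor (TF) ChIP-seq
    compendia over the space of biologically relevant TF-sample pairs.
    Calls per-TF expression thresholds by fitting a one-step function
    (StepMiner-style) to RNA-seq values across cell lines, enumerates
    expressed-but-unmeasured TF-sample pairs, quantifies inequality of
    experiment counts with Gini coefficients and Lorenz curves, computes
    annual regulatory-TF and GWAS-SNP cover ratios from peak/promoter and
    peak/SNP overlaps, simulates alternative acquisition orders scored by
    trajectory AUC, and prioritizes unmeasured pairs with high knockout
    impact ("hidden gems"). Ships a synthetic-world generator with planted
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
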