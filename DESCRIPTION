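Package: methylentropy
Title: Entropy-Based CpG Selection and Case/Control Classification for
    DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects informative CpG sites from DNA methylation beta-value
    matrices by combining a per-CpG linear p-value prefilter with discretized
    Shannon-entropy ranking, and classifies case/control status (multiple
    sclerosis versus healthy controls) with a single-hidden-layer neural
    network trained by scaled conjugate gradient, controlling for age, sex
    and smoking status. Includes a synthetic methylation-cohort generator
    with planted differentially methylated CpGs, volatility
    (standard-deviation) baseline selectors, resampling control experiments
    with confidence intervals and permutation comparisons, and readers and
    writers for the pipeline's tabular artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
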