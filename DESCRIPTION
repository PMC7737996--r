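Package: iphplc
Title: Immunoprecipitation HPLC Protein Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative comparative protein-expression analysis for
    immunoprecipitation high-performance liquid chromatography (IP-HPLC)
    screens. Reads UV-detector chromatograms (time vs milli-absorbance),
    performs baseline correction, peak-window detection and trapezoidal
    integration, subtracts the negative-control antibody background,
    converts net peak areas to square-root expression levels, aggregates
    replicate treated/control ratios under a standard-deviation
    convergence rule, classifies expression changes into the
    minimal/slight/significant/marked bins, runs housekeeping-protein
    quality control, and summarizes an antibody panel grouped into
    signaling-pathway categories as line graphs and circular star plots.
    Includes a synthetic-chromatogram generator with exact ground truth
    (area-parameterized exponentially modified Gaussian peaks, baseline
    drift, detector noise, multiplicative replicate variation) for
    validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
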