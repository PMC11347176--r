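Package: dzkit
Title: Doped-Pool Selection Analysis and Kinetics for Catalytic DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing in vitro selection (reselection) experiments
    on deoxyribozymes built from doped libraries: simulation of partially
    mutagenized pools and selection rounds, a native desk-scale read-processing
    chain (orientation, primer clipping, pair merging, length filtering, unique
    counting), per-position conservation profiles and information content,
    pairwise covariation with a doping-model Monte Carlo null, double and
    triple mutant-cycle scoring, secondary-structure stem bookkeeping with
    exact Poisson-binomial pairing nulls and imino-proton signal expectations,
    and enzyme-kinetic statistics (Michaelis-Menten, Hill cooperativity,
    signal-to-noise, turnover counting, detection limits). All user-facing
    functions take data frames and return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
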