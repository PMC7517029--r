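Package: epitransient
Title: Entropy-Based Characterization of Epidemic Transients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing the transient phase of an epidemic
    through the timing of its first infection maximum D and the preceding
    inflection time L, and for comparing infection curves against the
    log-normal reference family selected by the principle of maximum
    entropy dissipation.  Implements the first-order (Gibrat-type)
    infection model, the classical SIR model without demography, and an
    SIS model with vaccination and treatment feedback controls, all
    integrated with an adaptive Runge-Kutta scheme with dense output;
    Shannon-type entropies of infection curves (plain, normalized and
    truncated), the entropy-error decomposition against a reference
    curve, and matching of a computed curve to the log-normal family by
    entropy or variance equalization.  Results are returned as tibbles
    and fitted matches support broom-style tidy() and glance().
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    numDeriv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
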