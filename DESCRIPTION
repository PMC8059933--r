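Package: gcjoint
Title: Joint Models of Longitudinal Glucocorticoid Trajectories and Survival
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how individual trajectories of fecal
    glucocorticoid (fGC) concentrations relate to adult survival in wild
    primate populations. Provides a synthetic-cohort generator that emulates
    sparse, irregular hormone sampling of adult female baboons; construction
    of environmental, social and storage covariates (seasonality, rainfall
    anomalies, temperature windows, proportional dominance rank) and of
    dyadic sociality indices from grooming records; a linear mixed-effects
    submodel of log fGC with individual random intercepts and age slopes;
    a Bayesian shared-parameter joint model coupling that trajectory to a
    proportional-hazards submodel with a B-spline log baseline hazard, left
    truncation and yearly time-varying covariates, under current-value,
    current-slope or cumulative (area-under-the-curve) association
    structures; and dynamic conditional survival prediction for hypothetical
    individuals with specified hormone histories.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    splines,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
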