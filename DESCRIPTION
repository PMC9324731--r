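Package: cserecall
Title: Entropy-Based Construct Specification Equations and Rasch Metrology
    for Word-List Recall Tests
Version: 0.1.0
Authors@R:
    person("cserecall", "maintainers", email = "maintainers@cserecall.org",
           role = c("aut", "cre"))
Description: Metrological analysis of word-list memory tests such as the
    RAVLT immediate-recall trial. Fits the dichotomous Rasch model to binary
    recall matrices by joint maximum likelihood, separating person memory
    ability from item (word) difficulty on a common logit scale with
    standard uncertainties; computes Brillouin-entropy explanatory variables
    for serial position effects (primacy, mid-range, recency) and word
    frequency; builds construct specification equations for task difficulty
    by principal component regression; diagnoses multidimensionality through
    principal component analysis of standardized Rasch residuals (contrasts,
    variance decomposition, disattenuated correlations, Linacre checklist);
    and predicts residual-contrast loadings theoretically from the
    sensitivity of the logistic response integrated over a cohort ability
    distribution. A synthetic-cohort generator simulates recall matrices
    with group-specific ability distributions and serial-position difficulty
    shifts, and a command-line interface ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
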