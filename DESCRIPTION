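Package: phenoplate
Title: Micro-Cultivation Growth-Curve Phenotyping for Yeast Chemical Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 96-well micro-cultivation growth screens of
    yeast expressing heterologous membrane transporters (e.g. plant PIP
    aquaporins). Provides optical-density nonlinearity calibration with a
    zero-intercept quartic, blank correction, growth-curve smoothing and
    log-ratio transformation, nonparametric extraction of lag (lambda),
    maximum specific growth rate (mu) and carrying capacity (kappa), the
    dynamic Phi measuring point (growth rate below 5% of maximum) with
    area-under-curve (AUC) and relative-AUC fitness statistics,
    four-parameter logistic dose-response fitting with treatment
    concentration selection, two-phase exponential fitting of spheroplast
    osmotic-shock bursting traces, screen comparison statistics (ANOVA with
    Fisher's LSD versus a control, Tukey HSD with compact letter display),
    and a synthetic plate-reader simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
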