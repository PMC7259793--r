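Package: parextrap
Title: Bayesian Regression Models of Parabola Extrapolation Under a Bimodal Prior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how observers extrapolate noisy parabolas when the
    quadratic parameter is drawn from a bimodal Gaussian-mixture prior. Implements the
    generative model of the four-dot extrapolation task, closed-form posterior and
    posterior-predictive distributions for five regression models (prior regression,
    maximum-likelihood regression, maximum-a-posteriori regression, full Bayesian
    regression, and Bayesian regression with trial-by-trial noise estimation), two
    decision rules (probability matching and squared-loss Bayesian decision theory)
    with motor-noise convolution, fitting-free model comparison by summed log
    likelihood and Bayesian random-effects analysis, response-variance decomposition
    into unimodal and bimodal components, dominant-mode conditioning, a synthetic
    observer simulator, and readers/writers for the 11-column per-participant trial
    file format.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
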