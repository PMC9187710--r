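Package: dynclicks
Title: Dynamic Click-Train Evidence Accumulation: Behavioral Models and
    Neural Encoding Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis tools for the dynamic clicks task, a
    two-alternative auditory decision task in which a hidden environmental
    state switches stochastically at a fixed hazard rate while Poisson
    click trains stream from each side.  Implements the leaky evidence
    accumulation model with sensory adaptation (analytic forward moments,
    choice likelihood with lapse, maximum-likelihood fitting with
    Hessian-based uncertainty), an analytic posterior over the latent
    accumulator obtained as the normalized product of the forward Gaussian
    and a choice-constrained backward Gaussian mixture, behavioral assays
    (ideal-observer log-odds, psychometric and chronometric curves,
    psychophysical reverse correlation), and neural encoding analyses
    (causally smoothed firing rates, side-selectivity classification and
    choice-AUC timecourses, evidence-tuning maps with rank-1 singular value
    decomposition into a temporal gain and a single tuning curve, and
    detection of model-predicted changes of mind with state-change
    triggered responses and d-prime permutation statistics).  A synthetic
    data generator produces task trials, model-driven choices, and
    accumulator-tuned spike trains so that the full pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
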