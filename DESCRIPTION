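Package: olfactr
Title: Analysis and Simulation of Automated Olfactory Behavior Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing automated rodent olfactory behavior
    experiments driven by an olfactometer and a nose-poke chamber. Provides
    a 1-ms resolution event-log data model with on/off interval pairing, a
    virtual olfactometer (flow and dilution arithmetic, constant-total-flow
    valve logic, synthesized photo-ionization detector traces), schedule
    builders for habituation/dis-habituation, cross-habituation, detection
    threshold, odor preference, two-choice and Go/No-Go paradigms, the
    behavioral statistics these assays rely on (normalized port
    investigation, session-to-session differences, success rates,
    attraction/aversion indices, just-noticeable-difference thresholds),
    Weibull psychometric function fitting for threshold estimation, and a
    generative virtual mouse so every analysis can be exercised end-to-end
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
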