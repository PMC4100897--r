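Package: riskmle
Title: Structural Estimation and Model Judging for Risky Lottery Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maximum likelihood estimation of expected utility, rank-dependent
    utility, and choice-level EUT/RDU mixture models of binary lottery choice
    under five stochastic error specifications (Fechner probit/logit,
    contextual utility probit/logit, and the Luce strict-utility error), with
    cluster-robust sandwich inference, Wald tests, information criteria, Vuong
    and Clarke non-nested tests, and leave-one-subject-out cross-validated
    out-of-sample log-likelihood. Ships the Holt-Laury multiple price list
    design at arbitrary payout scales, a forward choice simulator, and
    parameter-recovery tooling so the full estimate-then-judge pipeline can be
    exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
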