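Package: lindleyLS
Title: Load-Sharing System Lifetimes with Lindley-Distributed Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood inference for equal load-sharing parallel
    systems whose component lifetimes follow the Lindley distribution.
    Provides the Lindley distribution primitives (density, distribution,
    quantile via the Lambert W function, hazard, random generation, and the
    closed-form one-sample maximum-likelihood estimate), the stage-wise
    gap-time likelihood of the load-sharing model, a per-stage
    expectation-maximization (EM) estimator with closed-form E- and M-steps,
    an instrumented Newton-Raphson baseline that exposes its sensitivity to
    starting values, a seeded simulator for sequential-minima gap-time data,
    and sensitivity experiments contrasting the two estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
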