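Package: rsmga
Title: Statistical Medium Optimization with Plackett-Burman Screening,
    Response Surfaces and a Genetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design-of-experiments tools for fermentation medium
    optimization: construction and analysis of two-level Plackett-Burman
    screening designs (concentration effects, dummy-column error variance,
    one- or two-tailed t-tests), five-level central composite designs with
    full second-order response-surface regression and ANOVA, and
    bound-constrained maximization of fitted quadratic surfaces with a
    seeded real-coded genetic algorithm (rank scaling, stochastic universal
    sampling, scattered crossover, elitism). Companion enzymology
    calculators cover purification tables (specific activity, yield, fold),
    Michaelis-Menten kinetics by Lineweaver-Burk or direct nonlinear
    least squares, and relative-activity tables. Seeded synthetic-data
    generators make every pipeline stage testable, and bundled fixtures
    reproduce a published cholesterol oxidase optimization study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    withr,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
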