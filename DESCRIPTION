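Package: maillardkin
Title: Multiresponse Kinetic Modelling of the Maillard Reaction in UHT-Heated Milk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiresponse kinetic analysis of the Maillard reaction
    network in milk heated at ultra-high temperature (110-140 degrees C).
    Builds mass-action reaction networks (lactose + lysine through the Amadori
    compound lactulosyllysine to alpha-dicarbonyls and the advanced glycation
    end-products CML and CEL), integrates the stiff ODE system with 'deSolve',
    estimates rate constants per temperature and reparametrized-Arrhenius
    activation energies globally by the Box-Draper determinant criterion,
    reports 95% highest-posterior-density intervals, identifiability flags and
    parameter correlation matrices, discriminates between candidate reaction
    networks, and generates replicate-level synthetic datasets emulating the
    laboratory heating design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    yaml,
    jsonlite,
    generics,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
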