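Package: crisprdyn
Title: Bifurcation Analysis of Virus-Host Coevolution with CRISPR-Like Adaptive Immunity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lotka-Volterra-type models of coevolution between lytic viruses and
    microbial hosts carrying a heritable adaptive immunity system such as
    CRISPR-Cas. Implements two- and three-component variants (Malthusian and
    logistic host growth, constant or virus-load-dependent immunity), together
    with equilibrium finding by scalar reduction and multivariate Newton
    polishing, eigenvalue stability classification, localization of
    transcritical, Hopf, saddle-node and Bogdanov-Takens bifurcations,
    numerically assessed Hopf supercriticality, time integration with a
    conservation monitor for the Hamiltonian special case, and classification
    of long-run dynamical regimes (stable equilibrium, limit cycle,
    quasi-chaotic oscillations) backed by peak statistics and a Benettin-type
    largest Lyapunov exponent estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
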