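Package: hetosc
Title: Collocation-Based Reduction of Heterogeneous Neural Oscillator
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates effectively infinite, all-to-all coupled populations
    of heterogeneous relaxation oscillators (a two-variable reduction of the
    pre-Botzinger complex respiratory model) using a small number of
    judiciously chosen neurons.  Collocation nodes and coupling weights for
    each heterogeneous parameter are taken from probability quadrature rules
    (Gauss-Legendre, probabilists' Gauss-Hermite, composite midpoint,
    inverse-CDF sampling, Monte Carlo); several heterogeneous parameters are
    handled through full tensor-product or Smolyak sparse grids.  Provides
    high-accuracy measurement of the collective oscillation period via
    Poincare sections, fixed-point solving with analytic Jacobians, Hopf
    bifurcation location by eigenvalue bisection, two-parameter Hopf curves,
    synchrony break-up detection, and reproducible convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    data.table,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
NeedsCompilation: yes
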