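Package: fracldg
Title: Local Discontinuous Galerkin Solvers for Fractional-Order Growth
    and Logistic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solves fractional-order (Liouville-Caputo) linear growth and
    nonlinear logistic population equations with a local discontinuous
    Galerkin (LDG) method on shifted Legendre element bases, marching
    element by element with upwind numerical fluxes.  The nonlinear
    logistic term is handled either by exact Galerkin triple products
    (direct computation) or by the product-approximation technique.
    Includes exact Mittag-Leffler reference solutions, fractional
    Adams-Bashforth-Moulton (PECE) and L1 finite-difference baseline
    integrators, and convergence-table machinery (estimated orders of
    convergence under mesh doubling), together with broom-style tidiers
    and ggplot2 plotting for solution objects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    ggplot2,
    jsonlite,
    optparse,
    pracma,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
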