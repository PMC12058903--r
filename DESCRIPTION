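Package: optidisp
Title: Species Range Dynamics Under Phenotype-Optimal Dispersal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic simulation of species range evolution when
    individuals combine random (diffusive) dispersal with matching habitat
    choice, modelled as advection along the gradient of the environmental
    trait optimum scaled by phenotype-environment mismatch. Implements the
    coupled reaction-advection-diffusion equations for population density,
    trait mean and trait variance on one- and two-dimensional habitats, a
    phenotype-resolved reference simulator used to validate the Gaussian
    moment closure, closed-form and root-finding analytics for the adapted
    homogeneous equilibrium and critical environmental gradients, scenario
    generators (linear optima, abrupt periodic optimum shifts, fragmented
    carrying-capacity landscapes), and trajectory diagnostics (effective
    range edges, travelling-wave speed and amplitude, adaptation times,
    extinction classification).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
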