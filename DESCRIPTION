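Package: scalepatterns
Title: Stochastic and Reaction-Diffusion Models of Scale-by-Scale Skin
    Color Patterning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the post-hatching color dynamics of lizard skin scales
    on polygonal lattices. Provides scale-lattice construction (regular
    hexagonal and Voronoi), a 16-rule stochastic cellular automaton with
    Bayesian rule inference, a two-parameter Lenz-Ising model with
    Metropolis dynamics and pseudo-likelihood fitting, three-component
    reaction-diffusion solvers (discrete per-scale, 2D continuous with
    reduced boundary diffusion, and 3D continuous on curvilinear grids)
    with logistic domain growth, CIELAB color-to-concentration transforms
    built from linear stability analysis, neighborhood and scale-by-scale
    error metrics, Gaussian-process Bayesian optimization of model
    parameters, skin-geometry uncertainty experiments, and Lyapunov
    sensitivity analysis. Includes synthetic-data generators (lattices,
    patterns, growth curves, normal maps, matched point sets) that emulate
    the statistical structure of photometric scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deSolve,
    EBImage,
    jsonlite,
    png,
    MASS,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
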