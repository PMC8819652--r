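Package: qensdiff
Title: Diffusion of Self-Crowded Disordered Proteins from Quasi-Elastic
    Neutron Scattering and Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-models and fits quasi-elastic neutron scattering (QENS)
    spectra of small intrinsically disordered proteins to extract center-of-mass
    and internal diffusion coefficients, converts between diffusion coefficients
    and hydrodynamic or structural radii under sphere, ellipsoid (Perrin),
    empirical IDP, and fractal scaling models, applies colloidal crowding
    scaling laws, and analyses multi-chain trajectories for finite-size
    corrected diffusion, Green-Kubo viscosity, transient clustering, and the
    elastic incoherent structure factor.  Ships seeded synthetic-data
    generators (backscattering-like spectra, Brownian chain ensembles,
    sphere-confined hydrogen motion, pressure-tensor series) so the full
    analysis chain is testable against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
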