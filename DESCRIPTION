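Package: porehull
Title: Pore Geometry of Hydrogels from Single-Particle Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs micron-scale pores of hydrogels from the
    trajectories of fluorescent tracer beads undergoing confined Brownian
    motion. Each track's position cloud is turned into a convex-hull pore
    model with volume, surface area, Feret diameter (with bead-diameter
    correction) and sphericity; ensemble mean-squared-displacement (MSD)
    curves yield diffusion lengths and diffusion exponents; 3D pore models
    can be flattened into simulated 2D SEM-like sections under a pore-volume
    budget and compared to cross-sectional measurements; flattened pores are
    laid out as pseudo-2D pore maps by fixed-gap or front-chain circle
    packing. A seeded confined-diffusion simulator (free, sphere, cylinder,
    box, convex polyhedron) provides ground-truth trajectories, and a
    Flory-Rehner equilibrium-swelling calculator gives the nanometre mesh
    size between crosslinks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
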