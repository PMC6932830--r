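Package: biofilmsim
Title: Individual-Based Simulation of Microbial Biofilm Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained three-dimensional individual-based model (IbM) of
    microbial communities with an emphasis on biofilms. Spherical microbial
    agents grow by Monod or energy-limited kinetics, divide, die, and excrete
    extracellular polymeric substances (EPS); they are coupled to voxelised
    solute fields solved by an explicit diffusion-advection-reaction scheme
    with pH speciation by charge balance and gas-liquid transfer, to a
    chemostat bulk-liquid mass balance, and to soft-sphere discrete element
    mechanics (Hookean contact, van der Waals EPS adhesion, fluid drag) relaxed
    to mechanical equilibrium by velocity-Verlet integration. A multi-timescale
    driver couples the biological, diffusion and mechanical processes through
    pseudo-steady-state (frozen state) approximations, and morphology
    observables (height map, surface roughness, area density, floc equivalent
    diameter, box-counting fractal dimension) summarise the emergent community.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
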