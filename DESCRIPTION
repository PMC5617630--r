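Package: auxinpattern
Title: Auxin Transport and PIN1 Polarity Dynamics on Cell Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates self-organized auxin patterning on polygonal cell
    networks via PIN1 polarization feedback, the mechanism underlying organ
    initiation at the shoot apical meristem. Cells produce auxin, which is
    transported passively and actively between neighbors; a cell's auxin
    level generates a signal that polarizes PIN1 efflux carriers in
    neighboring cells toward it (up-the-gradient feedback), so auxin maxima
    form spontaneously. A radial KANADI/REVOLUTA expression prepattern,
    computed from Hill kinetics, can repress the polarizing signal and
    restrict maxima to the low-expression boundary annulus between the two
    domains. Includes seeded synthetic tissue-template generators (Voronoi
    disc, periodic ring), adaptive Runge-Kutta integration of the coupled
    reaction-transport system, peak detection and boundary-restriction
    statistics, and an end-to-end pipeline with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
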