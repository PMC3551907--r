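Package: percnet
Title: Percolation Centrality and Targeted Immunization on Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for time-dependent, node-state-aware centrality analysis
    on networks. Implements percolation centrality, which weights the
    geodesics counted by betweenness centrality with the percolation
    (infection) states of their source nodes, in shortest-path,
    source-target (ramp-weighted) and current-flow (random-walk) forms,
    together with hop distance to the percolated set. Also provides a
    discrete-time susceptible-infected contagion simulator, a targeted
    immunization experiment harness comparing centrality-based intervention
    strategies over (percolated-fraction, immunized-fraction) grids,
    brute-force reference implementations used as test oracles, and
    generators for truncated power-law (scale-free) and Erdos-Renyi
    networks plus canonical small fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Matrix,
    MASS,
    stats,
    utils,
    withr
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
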