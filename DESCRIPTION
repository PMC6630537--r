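Package: inflanet
Title: Agent-Based Inflammation Simulation and Transfer-Entropy Communication Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tissue inflammation driven by mechanical strain and/or
    pathogens with a multi-layer agent-based model (epithelial lattice,
    diffusing TNF/TGF cytokine fields, motile macrophages and fibroblasts,
    random-walking pathogens), and infers cell-cell communication from the
    resulting trajectories: turning-angle series, pairwise transfer entropy
    between macrophage and fibroblast angle series, quartile-thresholded
    bipartite "TE networks", and the time course of the fibroblast-to-macrophage
    eigenvector-centrality ratio (Fc/Mc) over the inflammation episode.
    Includes synthetic coupled-process and random-walk fixtures with known
    ground truth for calibrating the inference pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
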