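Package: covrecon
Title: Covariance-Based Reconstruction of Differential Metabolic Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the COVRECON strategy for inferring changes in metabolic
    regulation between two biological conditions from steady-state metabolomics
    covariance data. A genome-scale metabolic model (SBML, BIGG-style JSON, or
    KEGG reaction records) is reduced to a weighted directed metabolite graph;
    cost-bounded shortest superpathways between measured metabolites define the
    sparsity structure of the system Jacobian. The Lyapunov equation linking the
    Jacobian, the concentration covariance matrix, and the stochastic fluctuation
    matrix is vectorized into an overdetermined linear system, and a regression-loss
    scan over Jacobian positions ranks interactions by how well allowing a single
    entry to differ between conditions explains both covariance matrices. An L-p
    optimization baseline, mass-action synthetic model generators (exact Lyapunov
    and Euler-Maruyama covariance generation), replicability evaluation, and
    circular differential-interaction plots are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'inverse-jacobian.R'
    'kinetic-models.R'
    'lyapunov.R'
    'model-io.R'
    'sbml.R'
    'sim-network.R'
    'utils.R'
    'workflow.R'
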