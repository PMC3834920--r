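Package: ermsel
Title: Replacement-Method Descriptor Selection and ANN Refinement for
    Penetration-Enhancer QSAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variable-subset selection for quantitative structure-activity
    relationship (QSAR) models of chemical penetration enhancers. Implements
    the replacement method (RM), its forced-move variant (MRM) and the
    enhanced replacement method (ERM, the sequence RM-MRM-RM) for choosing a
    fixed-size subset of molecular descriptors that minimises the residual
    standard deviation of a multiple linear model of the flux enhancement
    ratio, alongside forward-stepwise and backward-elimination selection
    gated by the partial F-ratio and an exhaustive-enumeration oracle.
    A small feed-forward neural network (one hidden layer, two sigmoid
    units) with min-max scaling onto [0.1, 0.9] refines the selected linear
    model. A synthetic descriptor-table generator with correlated Gaussian
    descriptor pools and a sparse true linear signal supports testing and
    method comparison without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'descriptorTable.R'
    'linearModel.R'
    'subsetSearch.R'
    'annModel.R'
    'syntheticData.R'
    'pipeline.R'
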