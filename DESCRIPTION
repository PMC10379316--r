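Package: frozencarp
Title: Frozen-Storage Quality Degradation Modelling for Common Carp Fillets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the degradation of five biochemical quality indicators of
    common carp (Cyprinus carpio) fillets during frozen storage at 261, 253 and
    245 K: thiobarbituric acid reactive substances (TBARS), free fatty acids
    (FFA), salt-soluble protein (SSP), Ca2+-ATPase activity and total
    sulfhydryl (SH) content. Provides the published 253 K measurement series
    and initial/final anchor values as built-in fixtures, a seeded first-order
    kinetic simulator for the unpublished temperature series, the delta-from-
    baseline transform and min-max normalization used for network training, a
    from-scratch Gaussian radial basis function network with greedy incremental
    center selection and least-squares output weights, a neuron-count/spread
    hyperparameter scan, and validation via signed relative errors, mean
    squared error, coefficients of determination and Pearson correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
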