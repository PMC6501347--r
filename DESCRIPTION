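Package: enmspec
Title: Elastic Network Spectra of Proteins with a Convolutional Surrogate
Version: 0.1.0
Authors@R:
    person("enmspec", "developers", email = "enmspec@example.org",
           role = c("aut", "cre"))
Description: Computes the low-energy fluctuation spectrum of coarse-grained
    protein elastic network models (anisotropic network model and the
    beta-Gaussian model with effective C-beta centroids reduced to a
    C-alpha-only quadratic form), encodes C-alpha traces as
    rotation/translation-invariant Coulomb matrices, and trains a
    convolutional network surrogate that predicts the ten lowest non-zero
    eigenvalues directly from the descriptor.  Includes decoy construction
    by window sliding with sequence-reversal augmentation, repeated k-fold
    cross-validation with paired direct/reversed folds, a non-informative
    baseline, and residue-pruning schemes that extend the fixed-size
    surrogate to longer chains and expose mechanically relevant (hinge)
    residues.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
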