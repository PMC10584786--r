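Package: qradbrain
Title: Quantum-Annealing Feature Selection and a Variational Quantum
    Classifier for Brain-Tumor Radiomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable radiomic classification pipeline for
    differentiating ring-enhancing brain lesions (large metastases versus
    high-grade gliomas) on contrast-enhanced T1 MRI. Provides a minimal
    IBSI-style radiomic feature extractor (shape, first-order, and
    co-occurrence/run-length/size-zone texture statistics over an original,
    Laplacian-of-Gaussian and Haar-wavelet filter bank), mutual-information
    and conditional-mutual-information feature selection posed as a
    quadratic unconstrained binary optimization (QUBO) and solved by
    exhaustive enumeration or simulated annealing, a 2-qubit
    amplitude-encoded variational quantum classifier trained with Adam and
    parameter-shift gradients on a dense state-vector simulator, and
    Shapley-value attribution of the trained classifier with an exact
    enumeration oracle and a Kernel SHAP estimator. A synthetic-data module
    generates ring-enhancing lesion volumes and planted feature tables so
    that every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
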