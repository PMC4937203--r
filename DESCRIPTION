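Package: kronstat
Title: Estimation and Inference for High-Dimensional Transposable Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing high-dimensional transposable data: N
    independent subject-level r x c matrices (e.g. genes x tissues) whose
    elements follow a Kronecker-product dependence structure
    Cov(Xij, Xlm) = (SigmaR)_il (SigmaC)_jm. Provides mean-matrix
    estimation and U-statistic tests of mean conservation across column
    groups that remain valid when the number of rows greatly exceeds the
    number of subjects, unbiased estimators of the trace functionals of
    the row and column covariance matrices, Stein-type shrinkage
    estimators of both covariance matrices with data-driven intensities
    and guaranteed invertibility, sphericity and identity covariance
    tests (including all-pairs scans with false discovery rate control),
    and a matrix-variate simulator with Gaussian and heavy-tailed noise
    used for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
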