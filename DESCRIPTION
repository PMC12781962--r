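Package: dsamonitor
Title: Early Post-Transplant DSA Trajectory Classification and
    Monitoring-Day Optimisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying early post-transplant donor-specific
    antibody (DSA) kinetics after HLA-incompatible kidney transplantation.
    Simulates labelled total-DSA MFI trajectories over the first 50
    post-transplant days with the four canonical dynamic patterns (fast
    and slow modulation, rise to sustained, sustained) plus a no-response
    group; preprocesses sparse per-DSA measurements into daily total-DSA
    series by summation and linear interpolation; classifies trajectories
    by dynamic time warping (DTW) distance to per-group mean centroids;
    and searches for minimal sets of monitoring days that preserve
    classification accuracy, including section-based day reduction,
    greedy day-combination search, and comparison against published
    clinical monitoring regimens.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
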