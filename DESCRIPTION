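Package: stopsignal
Title: Stop-Signal Task Simulation, SSRT Estimation and Inferential Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates stop-signal task (SST) cohorts under the independent
    horse-race model with the adaptive one-up/one-down staircase used in
    emotional-stop-signal studies, estimates stop-signal reaction times
    (SSRT) by the consensus integration method with go-omission replacement,
    and runs the accompanying inferential battery: mixed-design and
    repeated-measures ANOVAs with partial eta squared and Bonferroni post
    hocs, paired t and chi-squared tests, default-prior (JZS/g-prior) Bayes
    factors, repeated-measures power analysis, and the SSRT-index regression
    with standardized-residual outlier pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
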