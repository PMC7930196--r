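Package: mitotempo
Title: Time-Dependent Substitution Rates and Coalescence Dating from
    Ancient and Modern Mitogenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the tempo of human mitochondrial DNA
    evolution from serially sampled (ancient and modern) complete
    mitogenomes. Represents mitogenomes as rCRS-relative variant profiles
    with the usual hypervariable-indel and hotspot exclusions, bins ancient
    samples into dated periods with phylogenetically matched modern
    counterparts, estimates pairwise substitution rates per period with
    exact Poisson intervals, tests for time dependency of the rate by
    regression, models the persistence of transient polymorphisms under
    neutrality, and computes rho-statistic coalescence ages under
    alternative clock calibrations with most-divergent-lineage selection.
    A serial-sampling coalescent and genealogy simulator provides
    tip-dated synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
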