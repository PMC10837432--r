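Package: isopulse
Title: Stable-Isotope Pulse-Chase Tracing of Sponge-Derived Nutrients in
    Coral Holobionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-label (13C/15N) stable-isotope
    pulse-chase experiments tracing sponge-derived dissolved matter into
    coral hosts and their Symbiodiniaceae. Provides exact tracer arithmetic
    (delta notation, isotope ratios, atom fractions, excess incorporation and
    incorporation rates, molar C:N), baseline handling for enriched versus
    control specimens, Symbiodiniaceae cell-density estimation, from-scratch
    permutational statistics (distance-based PERMANOVA with unique
    permutations, pairwise tests with Bonferroni correction, tie-corrected
    Kruskal-Wallis with exact small-sample p, Welch's t), and a seeded
    compartmental simulator of the pulse/rinse/chase timeline that emits
    analysis-ready sample tables together with latent ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
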