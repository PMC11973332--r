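Package: fragrec
Title: Fragment Recruitment Profiling and DNA Fragmentation Bias Modelling
        for Metagenomes
Version: 0.1.0
Authors@R: person("Maarten", "Devos", email = "maarten.devos@example.org",
        role = c("aut", "cre"))
Description: Tools for taxonomic profiling of short- and long-read shotgun
        metagenomes by fragment recruitment plotting against a custom
        reference-genome database: best-hit filtering with reproducible
        tie-breaking, species retention by read count and breadth of
        coverage, coverage-gap fingerprints, subspecies read ratios,
        read-count and base-weighted relative abundances, and a minimum
        read-length sweep. Includes an analytic model of amplicon target
        intactness under uniform DNA fragmentation, I = (S - L + 1)/S,
        linking species-specific DNA fragment size to the bias between
        shotgun and full-length 16S rRNA gene amplicon relative
        abundances, plus a seeded synthetic-community generator (genomes,
        subspecies variants, fragments, reads, amplicon counts) so the
        whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
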