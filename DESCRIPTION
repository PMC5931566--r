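Package: idptools
Title: Disorder Annotation and Composition Analysis of Heat-Resistant Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for annotating intrinsic disorder in protein
    sets such as heat-resistant (boiling-soluble) proteomes. Provides
    per-residue disorder prediction with two self-contained predictor
    families (charge-hydropathy unfoldability and pairwise-energy
    estimation), import of externally computed score tracks,
    longest-disordered-region and percent-disorder summaries,
    multi-predictor consensus IDP calling, amino-acid composition
    enrichment with bootstrap confidence intervals, theoretical pI and
    molecular weight, disorder-versus-length regression, category
    frequency tables, and a seed-reproducible synthetic proteome
    generator with planted disordered regions and ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
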