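Package: barcodegap
Title: DNA Barcode Gap Species Delimitation and Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting cryptic species from aligned COI DNA
    barcodes and characterising their population history. Implements
    haplotype collapsing with length/ambiguity filters, screening of
    nuclear mitochondrial pseudogenes (numts) by in-frame stop codons and
    transversion excess, model-corrected pairwise distances up to a
    constrained GTR+I, histogram barcode-gap detection with threshold
    clustering, monophyly and posterior-support evaluation on
    support-annotated trees, Bayes-factor model comparison, consolidation
    of putative species by multispecies-coalescent speciation posteriors,
    per-population diversity and neutrality statistics (Tajima's D,
    Fu & Li's D* and F*, Fu's Fs, R2) with coalescent-simulation null
    distributions, exact tests of population differentiation, AMOVA,
    mismatch-distribution expansion fitting and molecular dating of
    demographic expansions, and a coalescent synthetic-data generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings
Config/testthat/edition: 3
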