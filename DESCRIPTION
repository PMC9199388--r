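Package: endofish
Title: Taxon-Specific FISH Probe Design and Quantification of Endohyphal
    Bacteria from Fluorescence Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Designs taxon-specific 25-mer oligonucleotide probes for
    fluorescence in situ hybridization (FISH) from target, host and
    background nucleotide sequences using k-mer uniqueness, melting
    temperature, an edit-distance (Levenshtein) off-target screen and
    structural filters (self-complementary 4-mers, G-quadruplex motifs);
    and quantifies endohyphal bacteria in multi-channel fluorescence
    micrographs via maximum-intensity Z projection, set-wise min-max
    normalization, adaptive-threshold mycelial masking, difference-of-
    Gaussian blob detection, density normalization per 100 square
    micrometres, transect counting along hyphae and Welch's t-test
    comparisons across culture conditions. Includes deterministic
    synthetic-data generators with machine-readable ground truth for
    both pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
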