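Package: fungidel
Title: Design and In Silico Verification of Fungal Gene Deletion Constructs
Version: 0.1.0
Authors@R:
    person("FGSC", "Tools", email = "tools@example.org", role = c("aut", "cre"))
Description: Genome-scale design of gene-replacement (knockout) cassettes for
    filamentous fungi. Extracts 0.6-1 kb homology flanks around annotated open
    reading frames, designs the constrained 5f/5r/3f/3r primer quartet with
    positional windows around the start and stop codons, attaches marker- and
    vector-complementary tails, and simulates construct assembly by yeast
    recombinational cloning or fusion PCR. Verification support includes in
    silico PCR product prediction, diagnostic assays that distinguish wild-type,
    null, heterokaryon and diploid genotypes by product size or restriction
    digest, and a decision procedure for essentiality calling by heterokaryon
    rescue. Ships a transcription of a published Aspergillus nidulans kinome
    deletion dataset with summary statistics, and a deterministic synthetic
    genome generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
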