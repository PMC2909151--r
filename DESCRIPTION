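Package: matdiv
Title: Mating-Type Linked Marker Diversity, Neutrality Tests and
    Frequency-Dependent Selection Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for clone-based allele calling at a
    mating-type (MAT A) linked marker in dikaryotic basidiomycetes,
    haplotype phasing of IUPAC-coded genotype sequences by allele-count
    minimisation, per-locus and per-group molecular diversity and
    neutrality statistics (segregating sites, k, pi, Watterson's theta,
    Tajima's D, Fu and Li's D* and F*), a multilocus two-taxon HKA test
    with a coalescent-simulated null distribution, and a within-dikaryon
    allele-divergence test. Includes a forward Wright-Fisher simulator of
    negative frequency-dependent selection at a MAT locus with a linked
    marker, unlinked neutral loci, founder bottlenecks and PCR-error clone
    reads, which generates all pipeline inputs synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
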