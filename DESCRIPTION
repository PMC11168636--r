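Package: aukmhc
Title: MHC Class II B Amplicon Genotyping, Diversity and Mate-Choice Analysis
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studies of major histocompatibility complex (MHC)
    class II B exon-2 diversity in wild bird populations genotyped by
    replicated amplicon sequencing. Provides a synthetic-data generator
    emulating a duplicated-locus MHC study design (skewed allele-frequency
    spectrum, up to four alleles per individual, replicated sequencing runs
    with substitution/indel errors and chimeras), an allele-calling quality
    control pipeline (quality and length filters, error-variant
    consolidation, chimera removal, replicate concordance, per-amplicon
    frequency and read-depth thresholds, open-reading-frame validation),
    population-genetic summaries (segregating sites, nucleotide diversity,
    Watterson's theta, sliding-window Tajima's D), a modified Nei-Gojobori
    dN/dS Z-test of positive selection on peptide-binding-region codons,
    and Monte Carlo re-pairing randomization tests of MHC-dependent mate
    choice with Bonferroni control and sample-size sensitivity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
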