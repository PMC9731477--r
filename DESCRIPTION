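Package: flipflopr
Title: Analysis and Simulation of the Yeast Chromosome XIV Flip/Flop
    Inversion Polymorphism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a recurrent inversion polymorphism in which a
    24-kb region flanked by two near-identical 4.2-kb inverted repeats (IRs)
    occurs in two orientations (REF and INV) in Saccharomyces populations.
    Provides a parametric coordinate model of the locus; seeded generators for
    strain populations, sequencing reads, genetic crosses (including a
    mechanistic crossover-viability filter derived from isochromosome
    formation in REF/INV heterozygotes), four-parent intercrosses and genome
    annotations; orientation genotyping from assemblies, long reads and an
    in-silico PCR panel; crossover mapping and complete-linkage-disequilibrium
    analysis of segregant genotype matrices; nucleotide diversity, distance
    trees, Fitch minimum-change counting and a concerted-evolution index; a
    resampling test for centromere proximity of gene families; a forward
    simulator of IR homogenization by gene conversion with probabilistic
    crossover resolution (inversion toggling); and a spore-marker transmission
    test for meiotic drive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
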