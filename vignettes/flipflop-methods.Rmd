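---
title: "Models and methods behind flipflopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flipflopr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flipflopr)
```

# The system being modelled

`flipflopr` studies a balanced inversion polymorphism: a ~24-kb "flip/flop"
(FF) region on a yeast chromosome, flanked by two ~4.2-kb inverted-repeat
copies (IRL on the left, IRR on the right, IRR centromere-proximal), that
occurs in two orientations. REF matches the reference genome; INV is the
reverse complement of the FF interior. Because the two IR copies are
near-identical and inverted relative to each other, non-allelic homologous
recombination (NAHR) between them can invert the region, and gene
conversion between them homogenizes their sequences (concerted evolution).

Three consequences of this architecture drive the package's analyses:

1. **Orientation genotyping.** The inversion moves the single-copy genes
   just inside the FF boundaries to the opposite ends of the region, so
   marker adjacency across each IR diagnoses orientation (the four-reaction
   PCR panel; assembly anchor adjacency; IR-spanning long reads).
2. **Recombination suppression in REF/INV heterozygotes.** A single
   crossover inside FF between opposite orientations produces two
   isochromosomes — an acentric hairpin of two left arms and a dicentric
   hairpin of two right arms — so only even numbers of FF crossovers yield
   viable gametes. Suppression is emergent, not imposed.
3. **Inversion toggling.** Gene conversion between the IRs occasionally
   resolves as a crossover (literature value ~4%), flipping the region;
   orientation therefore toggles recurrently on phylogenies.

# The locus model

`build_default_layout()` is parametric rather than tied to genome
coordinates: IR length 4,200 bp, FF length 24,000 bp, 5,000 bp single-copy
flanks (total 42,400 bp), and a centromere placed so that the IRR midpoint
sits ~28 kb from it (the proximal copy; the distal copy is then ~58 kb
away). Each IR carries a tRNA gene at its outer edge plus a "centroid"
sporulation gene and a transmembrane-protein gene; the repeat proper starts
10 bp downstream of the tRNA gene and ends 217 bp after the transmembrane
gene's stop codon. Overriding `ir_length` down to 74 bp models the minimal
tRNA-only repeat found outside this genus. Internal coordinates are 0-based
half-open (BED convention); printed reports are 1-based inclusive.

`realize_reference()` draws an i.i.d. sequence at a requested GC content
(default 0.38, yeast-like) and copies `revcomp(IRL)` onto IRR, so realized
repeats are exact reverse complements. `apply_orientation()`
reverse-complements the FF interior in place (an involution) and mirrors
FF-internal annotations.

One consequence worth stating: with *exact* inverted repeats, every
junction window around a single IR/single-copy boundary in an INV genome is
the reverse complement of a REF junction window. A double-stranded read
covering one boundary therefore cannot reveal orientation; an informative
read must span a whole IR and anchor in single-copy sequence on both sides.
`call_orientation_reads()` is built around this constraint, and reads
shorter than the IR correctly yield AMBIGUOUS. (Real IR copies differ at
~2% of sites, which gives real pipelines an extra signal this idealized
model deliberately omits.)

# The meiosis model

Crossovers along a gamete chromatid follow a stationary gamma renewal
process: mean `co_rate` crossovers per chromosome (default 1.5 on an 800-kb
chromosome, a chromosome-XIV-scale genetic length) with inter-crossover
distances Gamma-distributed with shape `interference_shape` (default 5).
Shape 1 recovers an interference-free Poisson process. We first built the
Poisson model and found it overproduces closely spaced double crossovers by
orders of magnitude relative to real meiosis: about a quarter of simulated
four-parent intercrosses acquired a viable FF double crossover that patched
foreign material into an inverted haplotype, splitting the complete-LD
block that real data show intact. Crossover interference is a
well-established feature of yeast meiosis (interference shapes of roughly
3–10 are typical estimates), and with shape 5 the probability of two
crossovers within a 24-kb window is negligible while the marginal crossover
density stays uniform (the renewal process is started stationary with a
burn-in well left of the chromosome). The Poisson null remains available as
`interference_shape = 1`.

Viability is decided per gamete by `classify_meiosis_products()`: segments
are joined by coordinate algebra honouring each haplotype's FF orientation;
with opposite orientations and an odd number of crossovers strictly inside
FF the products carry 0 and 2 centromeres and are discarded, otherwise both
products are balanced. Crossovers landing inside an IR are flagged as NAHR
(an inversion outcome, not an isochromosome) and never count toward FF
parity. The simulation uses a two-strand, per-gamete model — each sampled
gamete draws its own crossovers and inviable chromatids are resampled —
rather than a full four-chromatid bivalent; the quantities analysed
(genotypes of viable segregants, crossover positions) are identical in
distribution at this level. With multiple crossovers of odd FF parity the
reported product segment lists describe the gross hairpin structure set by
the unpaired exchange; interior reciprocal patches are not itemized.

The four-parent intercross emulates a multi-parent advanced intercross:
four founder haplotypes (one INV by default), `generations = 12` rounds of
random mating in a finite diploid population (default 200 diploids — the
real population scheme is not public, so this is an explicit emulation),
then 175 genotyped segregants. Haplotypes are tracked as blocks of parental
origin over private-SNP positions, not as sequences; each founder
contributes private sites both genome-wide and inside FF so the FF linkage
pattern is observable. The genotype coding is observational: a marker shows
its owner's letter only where the segregant carries the private allele, and
`NA` otherwise.

# Crossover calling and complete LD

`call_crossovers()` calls one event per switch of parental origin between
consecutive informative markers; `NA` markers widen the interval. Events
are tagged `FF` only when the whole marker interval lies inside the FF
region — an interval straddling the boundary cannot demonstrate an
FF-interior exchange — and FF events of one segregant within
`max_pair_span` (default the FF length) pair up as double crossovers. The
default marker spacing of the generator is 2 kb, the resolution scale of
the sequenced segregant panels this emulates; markedly coarser maps blur
boundary events into the FF region.

Two sites are in complete LD when their private-allele presence vectors are
identical across segregants; classes are the transitive closure. The
default is strict (identity over all segregants; sites with `NA` cannot
pair unless `min_shared` is relaxed), matching the "identical in all
segregants" reading of the published analysis.

# Diversity, parsimony, concerted evolution

Pseudochromosomes write substitutions and deletions (never insertions) onto
the reference, preserving length, so per-strain sequences stack into an
alignment without an MSA step. π is the mean pairwise p-distance with
pairwise deletion of gap/`N` columns; the reported spread is the sample
standard deviation **across pairs** (a sliding-window mode is provided for
comparison, since either convention is seen in the literature). Percent
identity uses global alignment with free terminal gaps (match +1, mismatch
−1, linear gap −2) and excludes terminal-gap columns from the denominator,
which reduces to Hamming identity for equal-length homologs. Distance trees
use neighbor-joining (`ape::nj`); minimum inversion-event counts use a
Fitch small-parsimony pass on the (arbitrarily rooted) tree, validated in
the tests against exhaustive enumeration of ancestral labelings and against
an independent library implementation. The concerted-evolution index is the
fraction of (IRL, IRR) pairs that are mutual nearest neighbours in the
distance matrix, with ties counted conservatively as not mutual.

# Centromere-proximity resampling test

The observed median nearest-centromere distance of a k-gene family
(midpoint-to-midpoint by default; edge-to-edge available) is compared with
medians of random k-subsets drawn uniformly without replacement from all
annotated genes. The empirical P is the *strictly smaller* count divided by
`n_sims`, so `p * n_sims` is exactly an integer — the convention that turns
3 smaller medians in 1,000,000 simulations into P = 3×10⁻⁶. A conservative
`(count+1)/(n+1)` estimator is available. `exhaustive_p()` enumerates all
subsets on small instances and serves as the oracle; under uniform gene
placement the empirical P is checked to be approximately Uniform(0,1)
across replicate synthetic genomes (Kolmogorov–Smirnov, α = 0.01).
Genes on centromere-less scaffolds are excluded with a warning.

# Toggling simulator

Each generation both IR copies mutate independently (Jukes–Cantor
single-nucleotide changes at rate `mu` per site; no indels); with
probability `g` a gene conversion overwrites one copy (chosen uniformly)
with the other over the conversion tract, and with probability `c = 0.04`
the conversion also flips orientation. The default tract model is
whole-repeat overwrite, because the real repeats are homogenized across
their full length including intergenic sequence; geometric tracts (mean
`mean_tract`) are available for realism studies. Between conversions the
copies diverge at ≈ 2μ per site per generation (`1 − exp(−2μt)` ignoring
back-mutation; accurate for small μt and checked against simulation within
binomial error); a whole-repeat conversion resets identity to exactly 1.
Neither `g` nor `mu` is estimated in the source study, so defaults are
order-of-magnitude placeholders and all checks are property-based.
`run_species_tree()` runs the same dynamics along a rooted tree with branch
lengths in generations: high conversion yields a concerted pattern
(within-strain copies are mutual nearest neighbours), no conversion yields
orthologous clustering, and recorded flips always bound the Fitch count of
tip orientations from above.

# Meiotic drive test

Spore-autonomous fluorescent markers sit between IRR and the centromere, so
acentric/dicentric products discard both markers symmetrically and the
viability filter cannot bias the viable-spore ratio — the design rationale
of the original experiment. Drive is modelled as a transmission-probability
shift (0.5 + d for the GFP haplotype); a spore-killing mode is provided and
reduces to the same binomial at the count level. `drive_test()` is an exact
binomial test up to 10,000 spores and a continuity-corrected normal
approximation above, with a Wilson score interval either way. At 50,000
spores per cross the test's type-I error calibrates to ~5% at α = 0.05 and
its power at d = 0.05 exceeds 0.99.

# What the generators do and do not emulate

The generators reproduce the *structure* the analyses rely on: junction
topology, emergent crossover suppression, private-allele linkage,
centromere-biased gene placement, concerted IR evolution, Mendelian or
driven transmission. They deliberately omit: sequencing error by default
(orientation calling is junction-topological; an error rate is available),
divergence between the IR copies themselves, insertions and structural
variants other than deletions, mobile-element interruptions of the IRs,
population-genetic dynamics in the toggling model (single lineages, no
Wright–Fisher layer), and tetrad structure in spore counting (monad-style
counts only). Passing tests therefore demonstrate correctness of the
methods on data with the assumed structure, not robustness to artifacts of
real sequencing.

# Numerical conventions and problem sizes

* Percentages in tabulations round half away from zero, reproducing the
  published 39/50/11, 35/65 and 29/71 splits from their integer counts.
* PCR: primers must match their final 3 bases exactly; at most
  `max_mismatch` (default 0) elsewhere; products at most `max_product`
  (default 10 kb, generous for long-extension protocols) with convergent
  3' ends.
* Seeds: every generator takes an explicit integer seed and is
  reproducible; truth tables accompany every simulated dataset.
* The test-suite and acceptance-script problem sizes (1,000-segregant
  crosses, 175-segregant 12-generation intercross, 10,000-generation
  toggling runs, 20,000 Monte-Carlo permutations against exhaustive
  enumeration of C(40,4) subsets, 1,000 null drive simulations of 50,000
  spores) are chosen so every stochastic check has comfortable statistical
  margin while the whole suite runs in about a minute on one CPU.

# Known limitations

* Read-level orientation calling requires reads spanning a full IR because
  the simulated IR copies are exact reverse complements; real pipelines can
  also exploit paralogous sequence variants between the copies.
* The hairpin segment lists for odd-parity multi-crossover meioses describe
  the gross product structure, not interior patch mosaics.
* The four-parent mating scheme is a generic random-mating emulation; real
  multi-parent panels have bespoke crossing designs.
* `exhaustive_p()` enumerates subsets dense in memory via `combn`; its
  budget guard (default 2×10⁵ subsets) should be respected.
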