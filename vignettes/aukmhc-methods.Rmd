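---
title: "Methods: amplicon MHC genotyping, diversity, selection and mate choice"
author: "aukmhc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplicon MHC genotyping, diversity, selection and mate choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aukmhc)
```

# Scope and model

`aukmhc` implements the analysis chain of a replicated amplicon study of an
MHC class II B exon-2 fragment in a wild bird population: a ~298-bp
hypervariable fragment encoding the peptide-binding groove, amplified from
(at least) two duplicated loci so that an individual carries one to four
distinguishable alleles with locus assignment unresolved. The package
covers allele-calling quality control, diversity and selection statistics
on the allele alignment, and Monte Carlo tests of MHC-dependent mate
choice. Wet-lab concerns (primer design, barcoding, base-calling) and
site-by-site Bayesian selection or recombination screening are out of
scope.

All stochastic components take explicit integer seeds and are exactly
reproducible; all file formats are plain text (FASTA, TSV with `#`
metadata comments, JSON masks) with 0-based half-open coordinates.

# The synthetic world

The generator exists so that every downstream stage can be tested against
known ground truth. Its defaults state the study design it emulates; they
are fixed, not fitted.

**Allele pool.** `generate_allele_pool()` draws a random stop-free
ancestral sequence and derives each allele by substituting at a shared set
of polymorphic sites: a fraction `variable_fraction = 0.30` of positions
may vary, and each allele carries the site's alternative base with
probability `site_mut_prob = 0.10`. These two values were chosen once so
that a 99-allele, 298-nt pool reproduces the observed *scale* of a real
class II exon-2 alignment — on the order of 85–90 segregating sites and
14–16 mean pairwise differences — rather than the ~75% pairwise divergence
of independent random sequences. Sequences are guaranteed distinct and
free of stop codons in the configured frame (the trailing partial codon of
a 298-nt fragment is ignored); an infeasible request (more distinct
stop-free sequences than the sequence space holds, or than the
polymorphism model can place) raises an error rather than silently
truncating. The PBR mask samples `round(pbr_fraction * n_codons)` codons
uniformly; the default fraction 0.25 approximates the share of
antigen-contact residues in a class II beta-1 domain.

**Genotypes.** Allele frequencies are rank-geometric: the frequency of the
rank-*r* allele is proportional to `skew^r`. The default decay is solved
numerically (`solve_freq_skew()`) so that the four most common alleles
carry 35% of draws, the skew reported for the emulated study system; pools
too small for that share to be meaningful fall back to near-uniform. Each
individual draws two alleles per locus (two loci by default) independently
with replacement, and stores the *set* of distinct alleles — the only
observable quantity when duplicated loci cannot be separated. The
locus-resolved draws are kept as a hidden attribute for tests only. A
consequence worth knowing: with independent draws from this spectrum the
mean number of distinct alleles per individual is ~3.4, higher than the ~2
reported in real data, where homozygosity is inflated by processes
(population structure, locus-specific frequencies) that the generator
deliberately does not model. Population labels default to the three-colony
99:12:29 design; sex is assigned independently at a 0.5 ratio.

**Pairing.** `form_pairs()` draws a uniform perfect matching in random
mode. Assortative/disassortative regimes visit males in random order and
let each choose among the remaining females with probability proportional
to `exp(±strength × metric)` — a greedy sampler, not an exact Gibbs
matching; `strength = 0` reduces every mode to random exactly (same code
path), which the tests assert.

**Reads.** `simulate_reads()` gives every true allele a Poisson depth per
run around `depth_mean` (no overdispersion — no information to calibrate
one), passes each read through an independent per-base error channel
(substitutions at 0.5%, indel events at 1% by default, matching the
filtering defaults downstream), and aggregates identical reads into
variants. Individuals with at least two alleles also receive one PCR
chimera per run — a single-breakpoint prefix+suffix splice of two of their
alleles at relative template abundance `chimera_fraction` — and the
chimeric template is sequenced through the *same* error channel as any
other molecule. This channel consistency matters: at realistic per-base
rates only ~1% of 298-nt reads are error-free, so an artificially exact
chimera would out-depth the error-decimated exact reads of a true allele
and absorb it during consolidation, a simulator artifact rather than a
property of amplicon sequencing. Multi-breakpoint chimeras and
platform-specific (homopolymer) error spectra are not modelled. Per-variant
mean Phred qualities are drawn high (≈37 ± 1.5, floored at 31) so the
quality filter does not interact with the error model; quality filtering is
exercised by hand-built fixtures instead.

What a green recovery test establishes, therefore, is that the QC rules
remove the *modelled* artifact classes at the stated rates and depths — not
that they would remove Ion Torrent homopolymer errors, barcode bleed-over
or contamination, none of which are simulated.

# Quality control

`qc_config()` encodes the filter constants: mean Phred < 30 removal
(strict inequality), strict amplicon length (298 nt — "anomalous length" is
interpreted as any deviation, since no tolerance window is stated for the
emulated pipeline), substitution/indel error budgets, 1% minimum
per-amplicon frequency (inclusive), 5% chimera parent-frequency floor
(inclusive), ≥ 200 reads for variants of singly sequenced individuals
(inclusive), at most 4 alleles per individual.

**Consolidation.** Within an amplicon (one individual × run), a variant
merges into a deeper variant when it differs by at most
`max(1, floor(0.005 · L))` substitutions and `max(1, floor(0.01 · L))`
indel bases — 1 substitution and 2 indel bases at L = 298, matching the
granularity of default Ion Torrent amplicon filtering. Parents are
processed from most to least abundant; merged depth accrues to the parent,
so total amplicon depth is conserved (asserted). Equal-length variants use
Hamming distance; unequal lengths fall back to a global pairwise alignment
(Biostrings) whose mismatch and indel-width counts feed the same budgets.

**Chimera removal.** A variant is removed when two *distinct, deeper*
parents, each at amplicon frequency ≥ 5%, reconstruct it exactly as
`p1[0:b] + p2[b:]` for some breakpoint. The parent-frequency floor
implements the "most abundant ones" qualifier: a splice of two 3% parents
is deliberately retained. The 5% threshold is read as a floor on *parent
variant frequency* (the natural reading for chimera formation); a per-site
substitution-frequency reading exists but is not implemented.

**Replicate logic.** Depths are summed per (individual, sequence) across
runs. Individuals sequenced in a single run keep only variants with
≥ 200 summed reads; individuals sequenced twice keep variants present in
both runs *or* reaching that depth. The both-runs-OR-depth rule generalizes
the stated single-run rule to the replicated case (only the single-run case
is stated explicitly in the emulated protocol). Surviving variants must
pass the 1% frequency floor (relative to the individual's total combined
depth), be of expected length and translate without stop codons
(pseudogene exclusion); the deepest four are kept, ties broken
lexicographically by sequence for reproducibility. Rejection of an
individual is a typed return value, not an exception.

Monotonicity (raising the frequency floor never yields more alleles),
idempotence (re-calling called genotypes is a no-op) and depth conservation
are property-tested.

# Diversity statistics

`popgen_summary()` computes, over distinct alleles by default (the
convention matching an allele-deposit alignment; `distinct = FALSE` uses
all rows): *h* (distinct sequences), *S* (columns with ≥ 2 observed
nucleotide states), *η* (observed states − 1, summed), *K* (mean pairwise
difference count), *π* (per-site pairwise diversity) and Watterson's
*θ*<sub>W</sub> = *S*/(*a*<sub>*n*</sub> · *L*<sub>eff</sub>).

Missing data (`N`, `-`) conventions are explicit because published tables
rarely state them and *π* is sensitive to the effective length: under
`complete_deletion` (default, the convention of classical DNA polymorphism
software) columns containing any missing value are dropped and
*L*<sub>eff</sub> is the retained count; under `pairwise_deletion` each
pair is normalized by its own valid sites and *L*<sub>eff</sub> counts
columns with ≥ 2 observations; under `none` the full length is used. On
gap-free input all conventions coincide and *π* · *L*<sub>eff</sub> = *K*
exactly (asserted).

`tajimas_d()` uses the 1989 variance constants
(*a*<sub>1</sub>, *a*<sub>2</sub>, *b*<sub>1</sub>, *b*<sub>2</sub>,
*c*<sub>1</sub>, *c*<sub>2</sub>, *e*<sub>1</sub>, *e*<sub>2</sub>)
computed from *n* and *S*; *D* is undefined (`NA`, never 0) when *S* = 0.
Windowed mode slides `[start, start + 25)` in 5-nt steps (0-based
half-open, full windows only) and reports per-window *S*, *π* and *D*. The
test suite verifies both against an independently coded constants
calculator and a brute-force site/pair enumeration oracle, to 1e-10.

# Selection

`ng_site_counts()` splits each codon position's one potential site into
synonymous/nonsynonymous fractions with mutation paths weighted
transition : transversion = 2*R* : 1, so the *expected* ts/tv ratio of the
process is *R*; *R* = 0.5 recovers the unmodified equal-weight counting
(one transition vs two transversions per position), and *R* defaults to 2.0
— a typical empirical value, chosen here because the emulated analysis
names the modified method without stating its ratio. Mutations through
stop codons are excluded with per-position renormalization; *N* + *S* = 3
for every sense codon and every *R* (asserted over all 61 codons).

`ng_pairwise()` counts observed differences per codon averaged over
shortest mutational paths with equal weights, excluding paths through
stops (falling back to all paths if none survive), pools counts over the
codon subset, and applies Jukes–Cantor; *p* ≥ 3/4 is reported as `NA`
(saturated) rather than a number. `z_test_positive_selection()` averages
pairwise *d*N and *d*S over all unordered pairs (the overall-average
behaviour of the classical implementation), estimates the SE of
*d*N − *d*S by resampling codon columns with replacement (default 1000
replicates, seeded), and reports the one-tailed normal upper-tail p. The
codon-bootstrap (rather than an analytic variance) was chosen because it
is simple to verify and matches common practice; codon-pair difference
counts are memoized, making the 99-allele × 4851-pair case tractable.

The default PBR mask (`inst/extdata/pbr_mask_default.json`) lists the
classical human DRB beta-1 antigen-contact positions restricted to the
first 99 codons, as 0-based codon indices. It is labelled an
interpretation: exact PBR coordinates are alignment- and study-specific,
and the mask file is meant to be replaced.

# Mate choice

Six canonical tests: absolute heterozygosity difference; band-sharing
2*F*<sub>ab</sub>/(*F*<sub>a</sub>+*F*<sub>b</sub>); additive and maximum
amino-acid dissimilarity, each in whole-fragment and PBR contexts. With
loci unresolved, heterozygosity is the distinct-allele count (1–4), and
amino-acid metrics aggregate over *all* cross-mate allele combinations
(identical alleles contributing 0); a best-match locus assignment would
require locus resolution the data cannot provide. Whether shared-allele
zeros should enter the additive metric is genuinely open; the
all-combinations convention is documented rather than asserted as the only
reading.

The *signed* heterozygosity difference is retained (`het_diff_signed`)
because it documents an algebraic identity: the mean over pairs of
(*h*<sub>male</sub> − *h*<sub>female</sub>) equals
mean(*h*<sub>males</sub>) − mean(*h*<sub>females</sub>) and is therefore
*exactly* invariant under any re-pairing — its permutation p is always 1.
This is property-tested to machine precision and motivates the absolute
difference as the default testable quantity.

`randomization_test()` permutes the female list against the fixed male
list (uniform perfect matchings, resampling without replacement), B =
10,000 by default, and reports the observed mean, the 2.5%/97.5% empirical
percentiles of the null means, and the two-sided empirical p
2·min(*r*<sub>low</sub>, *r*<sub>high</sub>)/(B+1) with
*r* = 1 + tie-inclusive tail counts, capped at 1 — an add-one formulation
that can never return 0 and counts ties as extreme. Only complete pairs
enter; an unpaired individual is excluded. `run_all_tests()` applies the
Bonferroni family alpha 0.05/6 ≈ 0.008 and labels directions (band-sharing
above the upper tail = assortative; a dissimilarity metric above the upper
tail = disassortative). `sensitivity_curve()` subsamples pairs without
replacement over a grid of sample sizes and reports the proportion of
subsamples reproducing the full-data significance verdict; at the full
sample size the only subsample is the data itself, so concordance is 1 by
definition.

# Numerical choices and degenerate inputs

* Seeds: every generator and test takes an explicit seed; derived seeds
  stay below 2^31.
* Ties: allele-cap truncation orders by depth then sequence; permutation
  ties count as extreme; quantiles use R's default type 7.
* Degenerate inputs: single-allele pools yield singleton genotypes;
  constant metrics yield p = 1 with a point-mass null; S = 0 alignments
  yield `NA` Tajima's D; saturated Jukes–Cantor proportions yield `NA`
  distances; stop-codon codons are rejected by the site counter.
* The pipeline manifest omits timestamps so reruns are byte-identical.

# Known limitations

* **Type-I calibration of the heterozygosity test is conservative.** Under
  random mating the six tests were calibrated over 500 seeded replicate
  colonies (44 pairs, B = 999): five tests reject at 4.4–6.0% at
  α = 0.05, inside the expected [3%, 7%] band, but the absolute
  heterozygosity difference rejects at ~2%. The cause is structural: in
  the stated synthetic world most individuals carry 3–4 alleles, so
  |Δhet| takes very few values, the null distribution of its mean has
  large atoms, and the tie-inclusive doubled-tail p is valid but
  conservative. The corresponding acceptance expectation is deliberately
  left failing rather than loosening the band or reshaping the generator.
* The generator's independent-draw genotypes overstate mean heterozygosity
  relative to real colonies (see above); population structure, linkage
  and locus-specific spectra are not modelled.
* Chimera detection assumes equal-length parents (post length filter) and
  single breakpoints.
* The dN/dS Z-test treats saturated pairs as missing in the bootstrap
  mean; heavily saturated alignments should be interpreted with care.
* Reproducing published diversity/selection values for a real allele
  deposit requires downloading those alleles and supplying the study's PBR
  mask; the package supports this (`read_fasta`, `popgen_summary`,
  `z_test_positive_selection`) but ships no third-party data.
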