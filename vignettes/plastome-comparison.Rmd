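---
title: "Comparing near-identical chloroplast genomes with plastcmp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing near-identical chloroplast genomes with plastcmp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastcmp)
```

# The problem

Land-plant chloroplast genomes (plastomes) are circular molecules of
roughly 120–160 kb with a conserved quadripartite layout: a large and a
small single-copy region (LSC, SSC) separated by two identical inverted
repeats (IRb, IRa). Within a species, two plastomes — say, from two
ecotypes of a grass — differ by only a handful of substitutions and
indels, yet those few differences carry real information: they supply
diagnostic markers for breeding pools, they date the split between
maternal lineages, and their distribution across the genome
(single-copy vs repeat, coding vs noncoding, homopolymer-adjacent or
not) reflects the mutational and repair biology of the organelle.

`plastcmp` implements that comparative analysis end to end for a pair
of annotated plastomes: quadripartite structure detection,
mononucleotide microsatellite census with a region-bias test, pairwise
SNP/indel calling with full classification, synonymous-divergence and
molecular-clock estimation, and short-read confirmation of variants and
predicted C-to-U RNA-editing sites. A seeded simulator generates
plastome pairs and read pools with complete ground truth, so every
stage is testable without external downloads.

# Structure detection and coordinate conventions

`detect_quadripartite()` searches for the maximal pair of disjoint,
**exactly** reverse-complementary repeats. Real plastome IR copies are
homogenised by copy correction and are exact duplicates in practice, so
exact matching is both adequate and far easier to verify than a
mismatch-tolerant detector (which is out of scope). The search seeds
31-mer matches between the doubled genome and its reverse complement —
doubling handles repeats that span the arbitrary linearisation point of
a circular record — extends them along diagonals, and keeps the longest
disjoint pair. `min_ir_length` defaults to 1,000 bp: plastome IRs are
20–30 kb, while chance reverse-complement repeats hundreds of bases
long essentially never occur, so the default suppresses short
palindromes without risking the true repeat. Two co-maximal candidate
pairs raise an explicit ambiguity error rather than an arbitrary pick.

The longer single-copy arc is labelled LSC, and the canonical rotation
places its first base at position 1 with segments ordered LSC, IRb,
SSC, IRa. One convention applies throughout the package: coordinates
are **1-based inclusive**, in code and in every report (the natural
convention in R and the one used by the marker tables this package
emits). Features spanning the circular origin are represented with an
end coordinate beyond the genome length ("unwrapped"), which lets the
junction-duplication report treat all four IR boundaries uniformly.

Per-nucleotide rates and stratum lengths always count the inverted
repeat **once**: a variant or microsatellite present in both copies is
one event biologically (the copies are not independent observations),
and the reported single-copy and IR substitution rates use
single-IR-copy denominators accordingly. Positions in IRa are collapsed
onto their IRb mirror by `mirror_ir_position()`.

# Microsatellite census

`scan_homopolymers()` reports every maximal single-base run at or above
a minimum length, merging runs that span the circular origin. Two
length conventions coexist deliberately: marker tables use runs of
**10 bp or more** (the length at which mononucleotide repeats become
practical genotyping markers), while the distributional analysis uses
**5 bp or more** in size classes 5, 6, 7, 8, 9, 10+ — short runs are
abundant enough to expose region biases that the rare long runs cannot.
Complementary bases are merged into the classes A/T and G/C for
reporting, but an A-run abutting a T-run remains two records: they are
distinct mutational units.

The goodness-of-fit test (`goodness_of_fit()`, Pearson chi-square via
`chisq.test`) compares observed run counts per stratum with
expectations proportional to stratum lengths, the IR counted once. The
null is deliberately length-proportional rather than
composition-adjusted: the scientific question is whether runs are
distributed as if sequence location did not matter, and a significant
departure *despite* the GC differences between regions is part of the
result. A composition-adjusted expectation can be formed by the user
from the per-stratum rates if desired. Per-size-class tests are emitted
on either margin (single-copy vs IR, or coding vs noncoding — the
one-dimensional strata); **no multiple-testing correction** is applied
across size classes, and outputs say so. Expected counts below 5 set a
`low_expected` flag instead of silently trusting the asymptotic
chi-square.

# Pairwise alignment and variant calling

Two conspecific plastomes are >99.8% identical, so the aligner is an
anchor-and-chain design: exact matches seeded by 20-mers unique in both
sequences, chained by longest-increasing-subsequence to the
highest-coverage co-linear chain, with the short inter-anchor gaps
closed by affine global alignment (`Biostrings::pairwiseAlignment`;
match 1, mismatch −2, gap open −4, gap extend −1 — near-identical
input is insensitive to these values, which are recorded in the run
manifest). Equal-length micro-gaps (≤ 8 bp) between exact anchors are
substitution runs by construction and are paired directly. An anchor
chain covering less than half of either genome aborts with a
"too divergent" error: this tool is for near-identical pairs, and a
half-covered chain means the input violates that premise.

Because no 20-mer inside a 22.7 kb repeat is unique, whole plastomes
are compared in **IR-reduced** form: LSC + IRb + SSC, with IRa dropped
(`compare_plastomes()`). This is the same single-IR-copy convention
used for rates; variants inside IRb are flagged as present in both
copies.

Variant representation follows the population-genetics conventions:
one SNP per mismatch column (adjacent substitutions stay separate
SNPs, never multi-nucleotide events, so transition/transversion counts
add up), one indel per maximal gap run, indels **left-normalised** to
their leftmost equivalent placement within repetitive context. Allele
strings contain only the inserted or deleted bases; the VCF writer adds
the anchor base back, as VCF requires, and documents the two
conventions side by side. `apply_variants()` reconstructs the query
from the reference exactly — a round-trip identity exercised heavily in
the tests.

Classification is strand-aware: coding effects translate the affected
codon with the plastid/bacterial code (translation table 11), honouring
GCG/GTG start-codon overrides (plastid *rpl2* and *rps19* use non-ATG
starts, translated as Met at position 1 only), and codons carrying two
substitutions are translated **jointly** while each SNP still counts
separately in the transition/transversion tally — this keeps the
summary table's columns internally consistent. An indel is
homopolymer-associated when the allele plus its flanks contains a
single-base run of at least `min_run = 5` bp after applying the indel
in either direction; 5 bp is where replication slippage becomes the
dominant indel mechanism in organellar genomes.

# Synonymous divergence and the clock

`extract_codon_alignment()` splices single-copy CDS out of the genome
alignment (IR genes excluded by default — they evolve under copy
correction and would bias a single-copy rate), drops codons that
overlap alignment gaps, excludes terminal stops, and refuses internal
stops with an error naming the gene and codon: an internal stop means
the annotation's frame is wrong, and a silent workaround would poison
the estimate.

`estimate_ds_dn()` provides two counting methods. **NG86** weights all
mutations equally and corrects with Jukes–Cantor; it is simple enough
to verify against exhaustive per-codon enumeration and serves as the
internal oracle. **YN00** (the default) estimates the
transition/transversion rate ratio kappa from fourfold-degenerate plus
nondegenerate positions via the K80 estimator, weights per-codon site
counts by kappa and by the observed codon usage (each codon occurrence
contributes its own weighted sites), and corrects the synonymous and
nonsynonymous classes with K80 distances. This is the published
weighting scheme with one simplification: the distance correction
assumes equal base frequencies (K80) rather than fitting HKY with F3x4
codon frequencies. At plastome-scale divergence (dS of order 10⁻³) the
correction term is nearly linear and the difference is far inside the
method's own uncertainty. Pathways between codons differing at more
than one position are averaged over stop-free orderings in both
methods. When kappa = 1 and transitions make up exactly a third of
differences the two methods coincide analytically — a property the
test suite constructs and checks.

`clock_age()` converts dS to years under a calibration interval,
defaulting to 2.1–2.9 × 10⁻⁹ synonymous substitutions per site per
year (the grass chloroplast single-copy range). The default formula is
`t = dS/r`; the per-lineage alternative `t = dS/(2r)` is selectable and
recorded in the output. The choice is genuinely open in the literature
— published intervals for conspecific plastome pairs match the
magnitude of `dS/r` — so the formula is an explicit, logged parameter
rather than a hidden assumption.

# Short-read confirmation

`align_reads()` is an ungapped, k-mer-seeded aligner allowing **at most
one substitution** per read, the reporting condition of the
confirmation protocol this stage models. Each read's two halves seed
candidate placements against the doubled genome (pigeonhole: with ≤ 1
mismatch at least one half matches exactly), both strands are searched,
and reads with several equally good placements — inevitable in the IR —
are counted once at the first placement in coordinate order and
flagged. That multi-mapping policy is deterministic and documented; its
visible consequence is that the second IR copy receives no coverage, so
genome-wide breadth saturates near (genome − IR)/genome rather than
100%. Indel-aware read alignment is deliberately not implemented: pool
indel evidence under a 1-mismatch ungapped model is marginal, and the
package documents this as a simplification rather than emitting
unreliable calls.

`call_pool_variants()` reports positions with depth strictly greater
than 4 (threshold ≥ 5) where a non-reference base reaches an allele
frequency of 0.8 (configurable; the protocol this models does not state
its threshold, so the default is an explicit stand-in, not an inference
of anyone's intent). Sites where every covering read differs are
flagged invariant. `verify_editing()` checks predicted C-to-U editing
sites strand-awarely — a minus-strand gene's edited reads show A on the
forward strand — and calls a site supported at ≥ 1 editing read with
depth ≥ 4.

# What the simulator emulates, and what it does not

`generate_plastome()` defaults are the study conditions of a
switchgrass-like plastome: LSC 81,729 bp, IR 22,704 bp, SSC 12,540 bp
(139,677 bp total); GC 33.1% (LSC), 36.4% (SSC), 44.0% (IR), with
planted ORF codon composition following the host region's GC so the
regional targets hold; intact ORFs on both strands (IR genes
automatically duplicated into IRa by construction); homopolymers
planted at 1.0/kb in single-copy noncoding versus 0.2/kb in IR
noncoding sequence with a shifted-geometric length distribution (mean
7 bp, truncated at 15).

`mutate_genome()` plants substitutions at 1.23 × 10⁻³ per bp in
single-copy sequence with the IR damped by a factor 0.072 — plastome
IRs evolve an order of magnitude more slowly than single-copy DNA, and
the factor reproduces an IR rate near 9 × 10⁻⁵ — with kappa = 1.1
(an expected transition:transversion count ratio near 0.55), and
indels at 4 × 10⁻⁴ per bp of which 74% are slippage events at existing
homopolymer runs, longer runs preferentially (selection weight ∝
length², since slippage rates rise steeply with run length); random
indel lengths are geometric, truncated at 50 bp. IR mutations are
mirrored into both copies, matching real IR homogenisation, and the
derived genome is rebuilt as LSC′ + IRb′ + SSC′ + revcomp(IRb′) so the
quadripartite invariant survives mutation.

Three deliberate departures from a fully agnostic mutation process keep
the simulations analysable and mimic selection: substitutions that
would create an internal stop codon in a planted CDS are resampled
(purifying selection in miniature — and a codon alignment with random
internal stops would be rejected by design); indels are restricted to
noncoding positions (intra-species plastome indels are found almost
exclusively in noncoding sequence); and a 60 bp zone around each region
junction is kept mutation-free so the derived genome's IR stays maximal
at exactly the planted boundaries. The generator also forces the bases
flanking the planted IR copies to be non-complementary — otherwise the
detector would, correctly, report a repeat one base longer than
intended.

What the simulator does **not** emulate, and what passing tests
therefore cannot show about real data: rearrangements, gene loss and IR
boundary shifts between the two genomes; heteroplasmy and
within-individual variation; sequencing-quality structure in reads
(qualities are constant, errors uniform); nuclear-plastid transfer
contamination in read pools; and real codon usage or amino-acid
composition (ORFs are random within GC constraints). Tests against the
simulator validate the machinery under the stated statistical
conditions, not the biology of any particular species.

# Numerical and degenerate-input choices

* Left-normalisation shifts indels base by base while the preceding
  reference base equals the allele's last base; ties inside perfect
  repeats therefore resolve to the leftmost placement, making calls
  comparable across alignments.
* `gc_fraction()` excludes N from the denominator and raises an error
  on an all-N span rather than returning 0/0.
* Saturated distance corrections (log argument ≤ 0) raise a
  "saturation" error; identical inputs return exact zeros.
* kappa estimation falls back to 1 when the fourfold + nondegenerate
  positions carry no differences (kappa is then unidentifiable and 1
  is the neutral weight).
* The ambiguity between equally long repeat pairs, an empty stratum in
  the rate table, malformed FASTQ records, and editing sites outside
  the genome all fail loudly with specific messages.

# Problem sizes in the test suite

The suite exercises the scanner-vs-oracle identity on 1,000 random
sequences up to 50 kb, the alignment round-trip on 1,000 simulated
pairs of 0.5–2 kb at plastome-like divergence, detection on dozens of
constructed genomes of 5–10 kb under random rotations, the
goodness-of-fit type-I error on 1,000 null draws at a total of 150
runs, read-based variant recovery on 500 planted sites at ~12×
coverage of a 60 kb genome, and dS recovery on 10,000-codon
alignments. Full-scale (139,677 bp) runs are exercised by the analysis
scripts and the acceptance script. These sizes were chosen so each
property is tested well inside its asymptotic regime while the whole
suite stays comfortably interactive.

# Known limitations

* IR detection is exact-match only; a genome whose repeat copies have
  diverged would be reported as having shorter flanking exact repeats.
* The aligner assumes co-linearity; an inversion between the genomes
  surfaces as a "too divergent" error, not as a rearrangement call.
* YN00-style counting uses the K80 correction (equal base
  frequencies), not the full HKY/F3x4 machinery; at the divergence
  scales this package targets the difference is negligible, but at
  dS ≫ 0.1 a dedicated codon-model package should be used.
* Read alignment is ungapped with ≤ 1 mismatch; reads spanning indels
  simply fail to align, so pool calls are substitution sites only.
* The GenBank reader handles the feature subset relevant to plastomes
  (CDS/tRNA/rRNA with join/complement locations and /gene qualifiers);
  it is not a general GenBank parser.
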