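---
title: "Comparative plastome analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
`plastomeCompare`: what each stage computes, the exact statistical
conventions it locks in, what the synthetic-data generator emulates, and
where the design was genuinely open and a choice had to be made.

# The analysis

Land-plant chloroplast genomes are circular molecules of roughly
120–160 kb with a conserved quadripartite architecture: a large and a
small single-copy region (LSC, SSC) separated by two identical inverted
repeats (IRb, IRa). Congeneric plastomes are highly collinear, so
comparative studies reduce to a standard battery: partition lengths and
GC content per genome, the genes sitting on the four single-copy/IR
junctions, per-region divergence to nominate mutational hotspots as
candidate DNA barcodes, a census of chloroplast microsatellites
(cpSSRs), and a phylogeny from the IR-stripped whole-genome alignment.
`plastomeCompare` implements that battery end to end on annotated
GenBank records.

## Quadripartite partitioning

`detectIR()` searches for the longest pair of disjoint intervals whose
sequences are exact reverse complements. The match is exact
(0 mismatches) and extension stops at the first mismatch: within a
genus the two IR copies are effectively identical because gene
conversion homogenizes them, and treating them as exact duplicates is
what makes "remove one IR copy" a well-defined operation downstream.
Detection is seed-and-extend (31-mer probes tiled every `minIrLen/2`,
maximal extension by binary search on common-stretch length), so it is
linear-ish in genome size and handles IR pairs spanning the sequence
origin. The canonical orientation places position 0 at the first LSC
base downstream of IRa (the *trnH* side); ties between equally long
candidate pairs resolve to the leftmost start. Genomes with no repeat
of at least `minIrLen` (default 1000 bp, well below any true plastome
IR but above incidental repeats) raise a "no quadripartite structure"
error rather than guessing.

## Divergence statistics

Each homologous region — exon-concatenated CDS, intron, or intergenic
spacer, with one IR copy removed and aligned length strictly greater
than 150 bp — is aligned across taxa and summarized per region:

* **S**, nucleotide substitutions: columns with no gap and at least two
  distinct bases. Columns containing any gap are excluded from
  substitution counting; a gap-adjacent substitution therefore counts
  only through the gap term.
* **I**, indel events: distinct maximal gap runs keyed by their
  (start, end) column coordinates. A run shared by several taxa at
  identical coordinates counts once; runs at different coordinates
  count separately. Whether a shared-but-shifted gap should count once
  is genuinely ambiguous; the distinct-coordinates rule is locked and
  regression-tested.
* **G**, total indel length: the sum of event lengths.
* **V**, variable positions: `V = S + (number of columns containing at
  least one gap)`. When events do not overlap across taxa this equals
  `S + G`, the identity the bundled published tables satisfy on all
  128 rows.
* **P**, percent variability: `P = 100 (S + I) / L`, rounded half-up to
  two decimals. Half-up rounding (2.857 → 2.86) is required to
  reproduce the published values exactly; R's default banker's rounding
  is not used.

Hotspot screening applies a strict inequality, `P > 2.0%`. On the
bundled noncoding table this yields exactly the eight published
hotspots (minimum 2.05). One bundled-table footnote: the source prose
quotes a noncoding maximum of 2.85% while its own table prints 2.86 for
the trnW–trnP spacer; the table value is the one the formula
reproduces, and it is treated as authoritative here.

## Alignment

The built-in aligner is deterministic progressive alignment: affine-gap
global pairwise alignment (match +1, mismatch −1, gap open −4, gap
extend −1, computed by Biostrings' dynamic programming) of every
sequence against a center sequence (the longest; ties by input order),
merged center-star style into a single gap pattern. For the
low-divergence regions of congeneric plastomes this is fully adequate
and requires no external binaries, which keeps results bit-reproducible
across machines. An external `mafft` can be substituted via
`alignRegion(..., method = "mafft")`; its output is parsed from FASTA
and used identically.

## cpSSR detection

`findSSRs()` reports maximal perfect tandem repeats of unit length 1–6
with unit-count minima 10/6/4/4/3/3 (mono through hexa), the standard
perfect-search parameterization for chloroplast surveys. Conventions
that the published locus tables imply and the implementation locks in:

* a run generated by a smaller unit is reported only under that unit
  (motif must not be a power of a shorter string), so poly-A is never
  also "AA";
* the motif is reported in observed phase — ATT and TTA label distinct
  loci;
* a trailing partial unit counts toward the locus length but not the
  unit count;
* runs containing N break at the N;
* only the plus strand of the canonical orientation is scanned, and
  loci starting in IRa are dropped, so each IR-duplicated locus is
  reported once (from IRb);
* overlaps between loci of different unit lengths are resolved in favor
  of the smaller unit: the larger-unit run is trimmed to the
  non-overlapping remainder and re-checked against the minima. This
  policy is underdetermined by any published table; it is stated here
  and shared, as the contract, by the brute-force enumerator the test
  suite uses as an oracle.

Cross-species matching keys on (context name, motif, occurrence rank
within context) rather than coordinates, because coordinates shift
between genomes while context names do not.

The published census that the fixture tests reproduce contains two
internal inconsistencies worth knowing about: the quoted 56.36%
T-share among mononucleotides is inconsistent with the table's own row
counts (30 of 55 = 54.55%, given one C locus), and the quoted
per-region proportions (89.09% / 14.55%) are the LSC and SSC counts
divided by the 55 mononucleotides rather than all 58 loci. The package
reports counts from the locus table and proportions of the total (they
sum to 100%); the A-share (24/55 = 43.64%) is consistent in both
readings.

## Concatenation and tree

The IR-stripped concatenation is assembled by joining the per-region
alignments column-wise. Its summary reuses the divergence conventions
(gaps are countable for V/I/G) and adds parsimony-informative sites:
columns with at least two base states each present in at least two
taxa, with gaps ignored — a column with states {A, A, −, −} is not
informative. The gap convention for PI sites is not standardized in the
literature; ignoring gaps is the common DnaSP-style choice and is
documented rather than configurable.

Distances are Jukes–Cantor, `d = −(3/4) ln(1 − (4/3)p)`, with pairwise
deletion (columns gapped in either member of a pair are dropped for
that pair); `p ≥ 0.75` is an error naming the offending pair. Tree
estimation is neighbor joining (ape's implementation) with
column-resampling bootstrap: each replicate resamples alignment columns
with replacement, rebuilds the JC69+NJ tree, and supports are the
percentage of replicates containing each internal bipartition of the
full-data tree. Maximum-likelihood search and model selection are
deliberately out of scope; `writePhylipAlignment()` and FASTA export
feed external ML tools, and NJ+bootstrap serves as the package's own
testable estimator. One consequence of using ape's NJ: negative branch
lengths, when the input is far from additive, are returned as ape
produces them rather than clamped to zero; on additive and
near-additive inputs (the package's use case) this does not arise.

# The synthetic-data generator

`simConfig()`/`simulatePlastomes()` generate annotated quadripartite
plastomes evolved along a known tree, providing ground truth for every
pipeline stage. The default configuration is the package's fixed study
condition, chosen once:

* **Scale.** LSC 20 kb, IR 6 kb, SSC 4 kb — about one quarter of real
  plastome dimensions, so the full pipeline (including bootstrap) runs
  in about a minute. The gene template uses real plastome gene names
  and structural motifs: *rps19* spanning J_LB with a 120 bp IR
  overhang and an abutting `rps19_like` at J_LA 14 bp upstream of
  *trnH*; *ycf1* spanning J_SA with a 1 kb overhang mirrored as
  `ycf1_like` at J_SB; an eight-gene duplicated block inside the IR;
  eight single-intron genes and two two-intron genes (*ycf3*, *clpP*);
  planted non-ATG start codons (GTG *rps19*, ATC *psbI*, ATT *psbT*,
  ACG *ndhD*).
* **Tree.** A fixed 11-taxon topology shaped like the classic
  congeneric pattern: two five-species clades plus one early-diverging
  lineage. Branch lengths (terminal 0.0012–0.0042, internal
  0.0008–0.0021 substitutions/site) are deliberately about four times
  deeper than a typical congeneric plastome dataset: the genome is four
  times smaller, and scaling depth inversely with length keeps the
  absolute information content (roughly a thousand variable sites in
  the concatenation) comparable to the real thing, which is what the
  recovery tests need.
* **Rates.** Substitution counts per branch and region are Poisson
  (branch length × region length × multiplier) with Jukes–Cantor base
  changes. Category defaults: coding 0.4, introns 0.8, spacers 1.4;
  seven designated hotspot spacers carry multipliers 4–6.5. Indels
  (rate 0.08 events per noncoding site per unit branch length,
  geometric lengths with mean 2.5, capped at 10 bp) are confined to the
  interior of noncoding regions in the single-copy zones; SSR loci
  undergo whole-unit slippage at 8 expected events per repeat unit per
  unit branch length. All randomness derives from the configured seed;
  a fixed seed gives byte-identical output files.
* **IR homogenization is perfect.** Every substitution falling in
  either IR copy is mirrored into the other, and the IR is indel-free,
  so `seq(IRa) = revcomp(seq(IRb))` holds exactly at every node. This
  matches the treatment of the IR as a single duplicated locus and
  keeps exact-match IR detection valid throughout.
* **What it does not emulate.** Indels never touch coding sequence
  (real plastomes do contain rare in-frame coding indels — the
  simulator trades that realism for exact annotation bookkeeping);
  SSR loci evolve by slippage only, with point substitutions excluded
  from the repeat tract; there is no IR expansion/contraction, no
  rearrangement, no base-composition skew, and no trans-spliced gene
  (*rps12*-style annotations are not generated, and region extraction
  simply treats each annotated location cluster independently). Passing
  the recovery tests therefore demonstrates correctness of the
  pipeline's bookkeeping and statistics under the stated model, not
  robustness to assembly or annotation error in real data.

The junction flanks of the planted genome are pinned to specific bases
and held fixed during evolution, so that the maximal exact
reverse-complement pair remains exactly the planted IR at every node —
otherwise detection would, correctly, extend the IR by the few bases
that happen to match by chance (a 1-in-4 event per boundary), and the
planted partition would stop being well-defined ground truth.

# Other design decisions

* Internal coordinates are 0-based half-open everywhere; GenBank I/O
  converts to and from 1-based inclusive, and origin-wrapping features
  are encoded as a single part with `end > length`.
* Sequences are uppercased on read and U is mapped to T.
* Incomplete IR duplicates (`_like` names) are excluded from the unique
  gene census and from spacer delimitation. The latter follows the
  published region inventories, which list a trnN–ndhF spacer across
  J_SB even though `ycf1_like` sits inside it.
* tRNA and rRNA gene bodies delimit spacers but are not emitted as
  divergence regions themselves: published coding tables list CDS only,
  while rRNA-flanked spacers do appear in the noncoding tables.
* The >150 bp region filter applies to aligned length (strictly
  greater), after alignment, not to raw length.
* The published comparison tables ship as plain-TSV fixtures and are
  the primary regression surface for the formula conventions, since the
  underlying sequence data are external downloads.
* The command-line surface is a thin wrapper
  (`inst/scripts/plastome-compare.R`); the package functions are the
  interface of record.

# Problem sizes used in testing

The test suite and the acceptance script run everything at the
simulator's default quarter scale: 11 genomes of 36 kb, ~70 homologous
regions, a ~29 kb concatenation, 50–100 bootstrap replicates, 100
random 2 kb sequences for the SSR oracle comparison, and 20 random
additive matrices (n ≤ 12) for the NJ property. These sizes were chosen
so the whole suite exercises every stage in a few minutes while leaving
the statistics (hundreds of variable sites, dozens of SSR loci) far
from degenerate.

# Known limitations

* Exact IR matching will report a shorter IR on genomes whose copies
  truly differ (rare within a genus); a mismatch-tolerant extension is
  not implemented.
* Center-star alignment degrades on highly divergent or
  rearrangement-bearing regions; for cross-genus work, route alignment
  through `mafft`.
* NJ+bootstrap is a desk-scale surrogate for ML inference, not a
  replacement; exports are provided for RAxML-class tools.
* GenBank parsing covers the gene/CDS/tRNA/rRNA subset the analysis
  consumes (including `complement(join(...))`); it is not a general
  flat-file reader.
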