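---
title: "Comparative analysis of small circular plasmid families"
author: "circplasmid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of small circular plasmid families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Several extremely halophilic archaea — most prominently the square-shaped
*Haloquadratum walsbyi* — carry families of small (~6 kb) circular plasmids
with a striking shared architecture: a high-GC block of three forward genes
(F1–F3) with overlapping stop/start codons, an AT-rich central region, and
four closely spaced reverse genes (R4–R7). Members of such a family from
geographically distant hypersaline sites show pairwise nucleotide
identities of roughly 61–79%, much higher over the forward block than over
the remainder. Individual members may carry extra cargo (e.g., an AT-rich
methyltransferase gene) or an interrupted gene whose reading frame a −1
programmed ribosomal frameshift — or a single-base insertion — would
restore. Regulatory evidence is thin and has to be squeezed from sequence:
degenerate promoter motifs, a rare Shine–Dalgarno-like RBS, inverted
repeats upstream of gene starts, and conserved intergenic sequence islands
(CIS). Finally, such plasmids are abundant in brine metaviromes, so a
family member can be reconstructed purely from environmental reads by
iterative recruitment and reassembly.

`circplasmid` implements that entire comparative workflow for circular
replicons, plus a synthetic plasmid-family generator with recorded ground
truth so that every stage can be validated end to end without any
downloads.

# Coordinates and the central data type

All coordinates are 1-based and inclusive. `CircularSeq` stores a replicon
with explicit topology; on circular sequences a feature may span the
origin, written as `end < start`, and `subseqCirc()` / `featureSpanLength()`
implement the wrap arithmetic. Feature tables are plain data frames (a
`GRanges` cannot carry `end < start` intervals), validated by
`validateFeatures()`; GFF3 output encodes an origin-spanning feature as
two part-lines sharing an `ID`, and `readGff3()` reassembles them.

# Annotation

`findOrfs()` calls complete CDS on both strands in all six frames of the
origin-doubled sequence, so origin-spanning genes are first-class; ORF
calls are deduplicated by genomic stop coordinate (on circular sequences
whose length is not a multiple of 3, the same genomic stop appears in two
frames of the doubled string). Within one stop-bounded frame segment the
longest ATG-initiated ORF is reported by default (`prefer_atg = TRUE`):
haloarchaeal transcripts are largely leaderless with a strong ATG
initiator preference, and GTG is associated with poorly expressed genes,
so preferring a slightly shorter ATG variant over a GTG extension gives
start calls that are stable across a plasmid family. Set
`prefer_atg = FALSE` for the raw longest-ORF convention.

Six-frame calling over a gene-dense, high-GC replicon inevitably produces
nested and antisense ORFs (stop codons are AT-rich, so high-GC frames run
long). Two remedies are provided. For a single plasmid,
`filterNestedOrfs()` resolves overlaps greedily by protein length. With a
family, `assignFamilies()` resolves them by *conservation*: proteins are
clustered across plasmids by reciprocal best identity (global alignment,
BLOSUM62, gap open 11 / extend 1; edges require at least 30% identity
between proteins whose length ratio is at least 0.6), and per plasmid the
ORFs kept are chosen greedily by how many plasmids their cluster spans,
then by length. Consistent presence across the family is precisely the
evidence on which weakly supported genes (such as F1) are annotated in
practice. Clusters are then ordered by consensus position and labeled
F1..F3 left-to-right on the forward strand and R4..R7 right-to-left on the
reverse strand; genes without a cross-plasmid cluster are `other`.

`detectOperons()` groups same-strand genes whose CDS overlap (the 1-nt
stop/start overlaps of the forward block) or whose gap is at most 30 nt,
the average intergenic distance of the reverse block. `proteinStats()`
computes pI by bisection on the Henderson–Hasselbalch net charge with
EMBOSS-style pKa values (N-term 8.6, C-term 3.6, K 10.8, R 12.5, H 6.5,
D 3.9, E 4.1, C 8.5, Y 10.1); the charge is strictly decreasing in pH so
the root is unique, and `charge(pI) = 0` to 1e-4 is enforced by test.
Identity percentages divide identical columns by alignment columns between
the first and last column where both sequences have residues, so internal
gaps count and terminal overhangs do not; this convention is stated here
because published identity ranges rarely define theirs.

# Comparison: alignment, distances, trees

`circularAlign()` first finds the rotation of the second replicon
maximizing an exact 12-mer offset vote, optionally trying the reverse
complement (`orient = "auto"`, used when comparing assemblies of unknown
strand), then computes a global affine-gap alignment (match +1, mismatch
−1, gap open 5, extend 1; a gap of length L costs 5 + L). The package's
alignment scores are validated against an independent plain-R Gotoh
implementation and, at tiny sizes, against exhaustive path enumeration.

`progressiveMsa()` rotation-normalizes all sequences against the first and
delegates multiple alignment to MAFFT (run deterministically); with
exactly two sequences the package's own pairwise aligner is used.
`distFromMsa()` gives 1 − identity per pair (columns gapped in all
sequences dropped; per pair, columns where at least one sequence has a
residue count in the denominator, so a strain-specific insertion registers
as distance). `njTree()` is canonical neighbor-joining (via \pkg{ape})
with support values from resampling alignment columns (default 100
replicates, seed-deterministic); negative branch lengths are clamped to
zero with a warning. `regionSimilarity()` maps a reference-coordinate
interval to alignment columns and averages pairwise identity there — this
is how the two-tier similarity structure (forward block vs remainder) is
quantified.

# Compositional segmentation

`gcProfileSegment()` works on the mean-detrended cumulative GC excess
(+1 for G/C, −1 for A/T). Recursive splitting at the maximum deviation
from the current segment's chord decides *how many* breakpoints the curve
supports: a split is accepted when its deviation exceeds a threshold
calibrated per sequence by residue permutation (95th percentile of the
maximal deviation over shuffled copies, so compositionally homogeneous
sequences yield a breakpoint in only ~5% of runs), with the threshold
scaled by the square root of segment length (the null scaling of a random
walk's maximal deviation). Breakpoint *positions* are then re-estimated:
piecewise-constant least squares on the windowed GC series (window 200,
step 50 by default) places the knots — mean-shift estimation is much
better conditioned than locating a weak slope corner on a noisy cumulative
curve — and a local continuous two-line segmented regression on the
cumulative curve polishes each knot at nucleotide resolution. On synthetic
plasmids this localizes the block boundaries to well within 150 nt; the
raw chord-deviation position alone missed the weaker (AT-rich center to
reverse block) corner by 200–400 nt.

# Regulatory elements

`scanIupac()` matches degenerate IUPAC patterns (the haloarchaeal promoter
consensus `SRNNRNNNTTWW` being the motivating case) on both strands with
circular wrap; `N` never counts as a mismatch, other degenerate letters
must match their set. Background hit counts follow the closed-form
per-position probability under an i.i.d. base model, which the tests check
to ±3 standard errors. `promoterPositionalFilter()` keeps hits whose motif
center falls a configurable distance upstream of a gene start on the gene
strand (default −30..−20 nt, around the −27/−28 center reported for
haloarchaeal promoters). `findRbs()` scans a short window upstream of a
start codon for the best match to `GGAGGTGA` (at most 1 mismatch by
default); the reported offset is the number of nucleotides strictly
between the motif's 3' end and the start codon, so the family's
characteristic `GGAGGCGA` four nucleotides before the F3 start reports
offset 4. `findInvertedRepeats()` returns maximal arm pairs (via
palindrome search) with arm length, loop length, mismatches and the
longest A/T run in the arm — the signature of the regulatory inverted
repeats just upstream of R4. `detectCis()` finds runs of at least 12
alignment columns that are intergenic in every plasmid and at least 90%
column-conserved (fraction of sequences agreeing with the column
consensus; gaps never agree); in the pipeline the intergenic mask comes
from the family-labeled gene set, not from every raw ORF call, since CIS
are defined relative to the annotated genes.

# Frameshift signatures

`findSlipperySites()` scans a CDS for heptamers of the canonical slippery
form X XXY YYZ (bases 1–3 identical; 4–6 identical and A/T; 7 not G)
anchored so that codons 2–4 and 5–7 are in the zero frame, tolerating a
configurable number of deviations (default 1, the permissive reading used
for halovirus-like sites). Each site is paired with the best stem-loop
whose 5' arm begins 2–12 nt downstream. `hairpinEnergy()` finds the
minimum-free-energy *single* hairpin (contiguous stem of Watson–Crick or
G:U pairs, terminal loop of at least 3 nt) by dynamic programming with
nearest-neighbor stacking energies: the Watson–Crick stack table is the
Turner-lab 10-parameter set, stacks involving G:U use a two-level
approximation (−1.4 kcal/mol with one wobble pair, −0.5 with two), and
hairpin-loop initiation penalties follow the Turner length table with
Jacobson–Stockmayer extrapolation beyond 9 nt. Multiloops and bulges are
deliberately out of scope — the object of interest is a short stem-loop
just downstream of a slippery site — and the DP is verified against
exhaustive stem enumeration. `internalStops()` and
`rescueOrfByInsertion()` complete the pseudogene analysis: the rescue
scans every insertion of every base up to just past the first internal
stop (later insertions cannot remove it) and reports those restoring an
end-to-end frame with a protein length within 10% of the family consensus.
Within a homopolymer run all insertion points are equivalent, so a cluster
of adjacent rescue positions is the expected, correct signature.

# Spacer matching

`matchSpacers()` is a seed-and-extend search: an exact 8-mer shared
between spacer and plasmid strand gates a local affine alignment
(match +2, mismatch −3, gap open 5, extend 2) against the origin-doubled
plasmid. The acceptance thresholds (span ≥ 30 nt, identity ≥ 72%) were
calibrated on null simulations — random spacers of matched composition
against 6-kb plasmids — to keep false positives below 1% per
spacer–plasmid comparison while comfortably admitting the published
moderate-similarity protospacers (the weakest spans 33 nt at 88%
identity). `translateCompare()` translates the matched region in the frame
of the overlapping annotated gene and the spacer in its best frame,
rendering stop codons as `*` so a spacer spanning a stop/start junction of
consecutive genes displays both.

# Recruitment, assembly, closure

`recruitReads()` recruits a read when a 15-mer seed extends to an
alignment covering at least 80% of the read at 90% identity or better
(reads overhanging a linear contig's end are accepted on the overlapping
segment, ≥ 25 nt, so contigs can grow). `assembleReads()` is a
deterministic de Bruijn assembler over canonicalized read k-mers (default
k = 31) with singleton-coverage pruning and unitig extraction; a contig
assembled from a circular template carries an exact k−1 terminal
self-overlap, which `iterativeClosure()` uses as its closure criterion
(the overlap is then trimmed). The closure loop mirrors the metavirome
reconstruction procedure: recruit against a (possibly diverged, ~70%
identity in round 1) seed reference, reassemble the recruited reads, take
the longest contig as the new reference, and repeat until closure or until
two rounds without growth. Consensus polishing is implicit in the
coverage-pruned graph rather than a separate pileup step.

# The synthetic family generator

`generateAncestor()` builds one ~6.2-kb ancestor with the canonical
architecture (44-nt intergenic head; F1/F2/F3 of 99/297/570 aa with 1-nt
stop/start overlaps; 1000-nt AT-rich center; R7/R6/R5/R4 of
109/278/214/115 aa, 30–34-nt gaps, R4 ending exactly at the origin so its
upstream region is the head) and plants, at recorded coordinates: a
conserved head island containing an overlapping, oppositely oriented
promoter pair (both matching `SRNNRNNNTTWW`, centered −27 from the F1
start and −22 from the R4 start) inside an inverted repeat with 8-nt arms;
`GGAGGCGA` 4 nt upstream of the F3 start (spacer fixed so the annotated
start cannot drift); two conserved islands in the central region and one
in the R7–R6 gap; and a slippery heptamer `G GGA AAC` with a 10-bp
GC-stem / 4-nt-loop hairpin 6 nt downstream inside R6. Regional GC
(0.55 / 0.42 / 0.51) is achieved by biased codon sampling plus a
correction loop that flips only unprotected bases, rejects flips creating
in-frame stops, and homogenizes composition within 200-nt windows to ±2 GC
points — giving the sharp inter-region profile transitions these plasmids
actually display.

`evolveFamily()` evolves the ancestor along a guide tree (default
`((A,B),(C,D),E)` with branch lengths chosen so the family lands in the
observed identity band) with region-specific per-site substitution rates
(forward block 0.8/unit, remainder 3.1/unit) and a 2.5-fold weight on
synonymous third codon positions (mean gene rate preserved), which keeps
protein-level conservation realistic relative to nucleotide divergence.
Planted elements, start/stop codons and the head are protected;
substitutions that would create an in-frame stop are redrawn. Indels
(geometric, mean 3 nt) are placed only in free intergenic zones, at the
leaf stage, with all truth coordinates remapped exactly. Leaf C gains an
AT-rich methylase-like gene cassette mid-center; leaf D receives a
single-base deletion immediately 3' of the slippery heptamer — at the
slippage site, as at the real locus — creating a premature stop (the
deletion point moves a few unprotected positions downstream in the rare
case the frameshifted tail happens to be stop-free).

What the generator deliberately does **not** emulate: genuine codon usage
and amino-acid composition (proteins are random-codon, so pI values are
arbitrary and motif background statistics are i.i.d.-like),
rearrangements (the family is collinear by construction), shared indel
history along internal branches (indels are per-leaf), quality-score
error models, and real metavirome community structure. Passing the
synthetic checks therefore demonstrates the pipeline's correctness on the
family's architecture and divergence structure, not performance on
arbitrary real metagenomes.

# Validation sizes and determinism

Every stochastic routine takes an explicit seed; identical seeds give
byte-identical sequences, reads, and reports, and the pipeline's output
bundle is reproducible file-for-file. The test suite validates, among
others: alignment scores against an independent Gotoh oracle on 1000
random instances of up to 12 residues (the oracle itself against
exhaustive enumeration up to 6); NJ against 100 additive matrices from
random 5–8-taxon trees and the planted sister pair across 100 generated
families; boundary recovery within 150 nt on 100 plasmids with a ~5%
calibrated null rate; recovery of the planted RBS, inverted repeat,
promoter pair, slippery site and CIS islands across replicate families;
exact circular reconstruction from 30× error-free reads seeded with a
diverged relative; and insertion-rescue localization within the
homopolymer run of a planted deletion in 100 constructed cases. Simulation
counts in the routine test suite are scaled to keep a full run in the
tens of minutes on one core; `scripts/acceptance.R` recomputes the
headline quantities from scratch at the package's default study
conditions.

# Known limitations

The deposited sequences of the real plasmid family are not redistributed
with the package; the acceptance checks that reproduce their published
lengths, GC values, identity band, RBS offsets, AT-rich region, internal
stop and hairpin energy run only when those public FASTA records are
placed under `inst/extdata/accessions/` (see the README). The hairpin
model is single-stem only, and its G:U stacking is approximate: reported
ΔG values are comparable within the package, and to full folding programs
only to within a couple of kcal/mol. `assignFamilies()` assumes a roughly
collinear family; it does not attempt rearrangement-aware orthology. The
assembler is a desk-scale tool for single small replicons plus decoys,
not a general metagenome assembler.
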