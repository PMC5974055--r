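# circplasmid

Comparative genomics of small circular plasmid families, built around the
PL6 family of ~6-kb plasmids carried by the square haloarchaeon
*Haloquadratum walsbyi*. Replicons of this family share a fixed
architecture — a high-GC forward gene block (F1–F3, transcribed as an
operon with overlapping stop/start codons), an AT-rich central region,
and four closely spaced reverse genes (R4–R7) — while diverging to 61–79%
pairwise nucleotide identity across isolates and metavirome assemblies
from distant hypersaline sites.

The package implements the full analysis such a family calls for:

* **Circular sequence handling** — 1-based inclusive coordinates with
  origin wrap (`CircularSeq`, `subseqCirc`, `rotate`), FASTA/GFF3/newick
  I/O with origin-spanning features encoded as standard two-part GFF3.
* **Annotation** — six-frame circular ORF calling (`findOrfs`), operon
  detection by stop/start overlap or ≤30-nt spacing, conservation-aware
  gene-family assignment with synteny labels F1..R7 (`assignFamilies`),
  protein length / identity / isoelectric-point tables.
* **Comparison** — rotation-aware global alignment (`circularAlign`),
  family MSA, distance matrices, neighbor-joining trees with bootstrap
  support (`njTree`), and region-restricted similarity
  (`regionSimilarity`) for the two-tier divergence structure.
* **Composition** — exact GC (`regionGC`), circular sliding windows, and
  GC-profile segmentation (`gcProfileSegment`): the detrended cumulative
  GC-excess curve c(i) = Σ(±1) − i·mean is split recursively at maximal
  chord deviation against a permutation-calibrated threshold, and the
  breakpoints are localized by least squares on the windowed GC series.
* **Regulatory elements** — degenerate IUPAC scanning (`scanIupac`, e.g.
  the promoter consensus `SRNNRNNNTTWW`), positional promoter filtering,
  RBS search (`findRbs`; the family's `GGAGGCGA` sits 4 nt before the F3
  start), inverted repeats with AT-motif annotation, and conserved
  intergenic sequences from the family alignment (`detectCis`).
* **−1 frameshift signatures** — slippery heptamers (X XXY YYZ) in frame
  (`findSlipperySites`), nearest-neighbor stem-loop free energies by
  dynamic programming (`hairpinEnergy`), internal-stop mapping and
  single-base insertion rescue of interrupted genes
  (`rescueOrfByInsertion`).
* **CRISPR spacers** — seed-and-extend spacer/protospacer matching with
  translated comparisons (`matchSpacers`, `translateCompare`).
* **Read recruitment and assembly** — seeded read recruitment, a
  deterministic de Bruijn assembler, and iterative recruitment/reassembly
  to circular closure from a diverged seed reference
  (`iterativeClosure`), mirroring how a family member is reconstructed
  from metavirome reads.
* **Synthetic families with ground truth** — `generateAncestor` /
  `evolveFamily` build PL6-like plasmids with planted genes, regulatory
  elements, a slippery site + hairpin, a strain-specific gene insertion
  and a pseudogene lesion, all at recorded coordinates;
  `simulateReads` and `makeSpacerSet` complete the test bed.

`runAll()` orchestrates everything over a plasmid set and writes a report
bundle (summary, identity matrix, tree, GFF3 annotation, protein and
regulatory-element tables, spacer matches, recruitment log).

## Worked example

```r
library(circplasmid)

anc <- generateAncestor(seed = 7)      # one ~6.2-kb ancestral plasmid
fam <- evolveFamily(anc, seed = 7)     # a five-member family, with truth
res <- runAll(fam$seqs, out_dir = "family_report", seed = 1)

res$summary
#>   id length_nt gc_percent
#> A  A      6204       51.7
#> B  B      6203       51.8
#> C  C      7263       50.0
#> D  D      6203       51.7
#> E  E      6194       51.3

round(mean(res$identity[upper.tri(res$identity)]), 1)
#> [1] 67.1

ape::write.tree(res$tree)
#> [1] "(D:0.116367674,C:0.2079937651,((A:0.07452336824,B:0.06833377462)100:0.07915641895,E:0.17633425)100:0.04836177939)100;"

res$rbs[, c("seq_id", "offset", "mismatches", "gene_family")]
#>   seq_id offset mismatches gene_family
#> 1      A      4          1          F3
#> 2      B      4          1          F3
#> 3      C      4          1          F3
#> 4      D      4          1          F3
#> 5      E      4          1          F3
```

The summary mirrors a per-plasmid length/GC table; the mean pairwise
identity of ~67% sits in the family's observed 61–79% band (plasmid C is
~1.1 kb longer because it carries the planted strain-specific gene); the
tree shows the A/B sister pair with full bootstrap support; and the RBS
table reports the planted `GGAGGCGA` exactly 4 nt upstream of every F3
start (one mismatch to the `GGAGGTGA` consensus), as in the real family.

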