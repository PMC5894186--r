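---
title: "Methods: tandem-repeat landscapes and multi-copy immune-gene censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tandem-repeat landscapes and multi-copy immune-gene censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gadarch` implements the comparative-genomics toolkit needed to
characterize two linked features of codfish-like genomes: an unusually
dense landscape of short tandem repeats (STRs, motifs of 1–10 bp
repeated in tandem), and innate-immune gene families (NOD-like
receptors, MHC class I) whose high copy number confounds assembly. The
package provides five analysis stages — STR detection and statistics,
gene-level overlap counting, GO-term enrichment testing, a six-frame
profile-based domain census, and read-depth collapse diagnostics —
plus a synthetic-genome generator that plants every statistical
structure those stages assume, so the whole pipeline is testable
without external data.

# STR detection

A locus is a *maximal perfect tandem array*: an interval that is
exactly periodic with unit size $u$, cannot be extended by one base in
either direction, and whose unit size is the minimal period of the
tract (an $(AC)_n$ array is never additionally reported with $u=4$).
Partial trailing units count, so `ACACA` is 2.5 copies of `AC`.
Arrays never span `N`.

Detection is run-length based: for each $u$, positions where
$s_i = s_{i+u}$ (both in `ACGT`) form runs; a run of length $r$ is a
candidate tract of length $r+u$, kept if $u$ is its minimal period and
it meets the thresholds. Defaults are `min_len[u] = max(12, 3u)` bp
with `min_copies[u] = min_len[u]/u`: a 12 bp floor keeps trivially
short tracts out of the statistics, and three full units keep larger
motifs honest. Only *perfect* repeats are detected; approximate-repeat
scoring (as mismatch-tolerant annotators perform) is out of scope, and
the thresholds are explicit arguments so other contracts can be
expressed.

Motifs are aggregated by canonical class: the lexicographically
smallest string among all rotations of the unit and of its reverse
complement, which makes the motif spectrum strand-symmetric (a tested
invariant).

Density is $10^6 \times \mathrm{array\ bp} / \mathrm{region\ bp}$
(bp/Mbp) and frequency $10^6 \times \mathrm{loci} / \mathrm{region\ bp}$
(loci/Mbp). When arrays of different unit size overlap, the bp totals
give shared bases to the smaller unit so the total row never
double-counts; locus counts stay unresolved so per-$u$ frequency keeps
its plain meaning. Coding-sequence statistics clip loci at merged CDS
boundaries and use the merged CDS length as the region size — whether
whole-locus attribution or clipping is used changes CDS densities, so
the clipping contract is stated rather than implicit.

# Coordinates and formats

All intervals live in R's native 1-based closed convention as
`GRanges`/`IRanges`; conversion happens only at file boundaries (GFF3
is already 1-based closed; VCF positions are 1-based). One internal
convention, enforced at the edges, is what prevents off-by-one drift —
the choice of which convention matters less than having exactly one.
FASTA goes through `Biostrings`, GFF3 through `rtracklayer`, VCF
through `vcfR`; placed/unplaced status is an explicit two-column
sidecar TSV rather than a naming heuristic, because assemblies differ
in how they name linkage-group sequences.

# Variants

Records are retained when `QUAL > 20` **and** `DP > 5`, read as strict
inequalities. Classification is by contract: equal length 1 → SNP;
equal length >1 → MNP; one allele a strict prefix of the other → INDEL
with signed size `len(alt) − len(ref)`; everything else (composite
insertion-plus-substitution events) → COMPLEX. Multi-allelic records
are split per ALT allele before filtering and classification — variant
callers differ here, so the per-allele choice is documented rather
than inherited.

The triple overlap counts a gene when a retained INDEL with
`|size| = 3` has its anchor (first affected base after the shared
REF/ALT prefix, i.e. `POS + 1` for left-aligned VCF indels) inside a
trinucleotide array that overlaps the gene. Both insertions and
deletions count. Gene scope defaults to the full gene span, with CDS
scope available; the two can differ, which is why both are exposed.

# Enrichment testing

Per GO term the unit of counting is the *gene*: with ≥1 STR versus
without. The 2×2 table is always with/without (the columns sum to the
term's gene count), which reconciles "with STRs vs total" and "with
vs without" phrasings.

`fisher_exact_2x2()` enumerates the hypergeometric support at the
observed margins and sums point probabilities not exceeding the
observed one, with a $1+10^{-7}$ relative tie tolerance; tests verify
exact agreement with `stats::fisher.test` on all small tables and
random tables to $n=40$. Direction (enrichment vs purification) is
read from the sample odds ratio, not from one-sided tests.

Multiple testing uses Benjamini–Yekutieli, valid under arbitrary
dependence: $\tilde p_{(i)} = \min_j \{ p_{(j)} \, m \, c(m)/j : j \ge
i \}$ with $c(m)=\sum_{i=1}^m 1/i$ (via `stats::p.adjust`). For
between-species tests the FDR family pools *all* term × species-pair
tests — the conservative reading when one corrected family is
reported. A term is "significant" when any of its pairwise tests
survives. Within-species tests compare each term against the species
background with the same machinery; a display threshold of
adjusted $p < 0.01$ is echoed alongside the rejection flag. GO-DAG
ancestor propagation is **off**: counting uses direct annotations
only, and a propagated analysis can be performed by pre-expanding the
gene→term map.

# Domain census

Assemblies are conceptually translated in all six frames (standard
code, stops rendered `*` with translation continuing, ambiguous codons
`X`, trailing partial codons dropped). Each frame is scanned with an
*ungapped* position-specific scoring matrix over the 20 amino acids
plus stop: the quantities of interest are hit counts above fractional
coverage thresholds, for which an ungapped PSSM is sufficient and
fully controllable; a full profile-HMM with insert/delete states is a
documented divergence from alignment-based domain search, not an
emulation of it. Stops score a large negative constant (−8
bits/column) rather than breaking the alignment, so pseudogenized
copies are *spanned and flagged* instead of fragmented — that is what
makes the "with stop codons" census row computable. Profile overhang
at sequence ends is allowed; coverage is aligned columns / profile
length.

Hits from different frames whose genomic back-projections overlap
reciprocally by ≥50% are deduplicated keeping the best score. Raw
per-frame counts are kept alongside, because published counts based
on raw per-frame hits are not always deduplicated and the two are
worth comparing. Census rows report all hits, >50% and >75% of the
domain length, >75% with internal stops, and the placed/unplaced
split from the sidecar map.

Completeness classification for BLAST-style gene-level searches uses
inclusive bounds: coverage ≥ 1.0 full length, ≥ 0.60 partial, else
below. MHC-class-I-style region classification anchors a ±10 kbp
window on the leftmost unused hit per sequence, labels the region with
the sorted set of alpha domains present (`a1+a2+a3` proxies a complete
gene), and proceeds greedily left to right.

# Collapse diagnostics

Per-sequence mean read depth divided by the assembly mean (total
depth over total length) gives normalized depth whose length-weighted
mean is 1 by construction. A sequence is flagged as a candidate
collapsed repeat when normalized depth exceeds 2.0 *and* it carries a
domain hit; 2.0 detects two-fold collapse, while the stricter 5×
preset corresponds to the gross collapse visible in published
length-versus-coverage diagnostics. The naive copy estimate is hits ×
round(normalized depth), with the fractional estimate emitted for
downstream judgment. Depth input is a TSV contract (per-base
samtools-depth-compatible, or per-sequence summaries) so the module is
testable without alignment tooling; gap positions are included in the
averages, matching `samtools depth -a -a` semantics.

# The synthetic-data generator

`simulate_genome()` is first-class, tested code. What it emulates:

* **STR spectrum.** Background sequence is made array-free by
  rejection (any detector-visible array is re-randomized), then arrays
  are planted per unit size to hit the configured density exactly;
  the default spectrum totals 96,364 bp/Mbp — the assembly-wide
  density reported for haddock — with dinucleotides dominant. Array
  lengths are geometric above the detection floor; motifs are drawn
  uniformly over canonical classes whose tandem repetition creates no
  side-band arrays; flanking bases are set to break extension, so the
  planted loci are *exactly* the detectable loci (verified by a
  closed-loop check at generation time).
* **Genes and enrichment.** Gene models (3 × 400 bp exons, 600 bp
  introns by default) receive CDS trinucleotide arrays with per-gene
  probability `base_str_p` times the product of their GO terms' effect
  multipliers — exactly the quantity Fisher's test compares. Effects
  >1 plant enrichment, <1 purification.
* **Variants.** Per-class per-bp rates follow the haddock-like
  defaults; 75% of records pass the quality/depth filter; size-3
  indels are planted inside genic trinucleotide arrays in exactly
  `n_tri_indel_genes` genes, and random size-3 indels are kept out of
  trinucleotide arrays so the planted count is the true count.
* **Domain families and collapse.** Copies are reverse-translated
  from a consensus with ~3% amino-acid divergence; pseudogenized
  copies carry one internal stop. Collapse is simulated mechanically:
  one emitted contig stands for $k$ copies and its read depth is
  multiplied by $k$ — the mechanism by which collapsed repeats show
  elevated coverage.

What it does **not** emulate: realistic base composition and repeat
families (background is uniform ACGT), imperfect/interrupted STRs,
read-level errors, alignment artifacts, GC-coverage bias, linked
paralog divergence structure, or a GO DAG (terms are flat labels).
Passing planted-truth tests therefore demonstrates the *counting and
testing machinery* is correct under the stated statistical structure,
not that any particular real genome will show these values.

A count-level companion, `simulate_go_counts()`, draws per-term
with/without counts directly for power and type-I-error studies of the
between-species tests at scale (510 terms × 200 genes in the shipped
design) without building sequence files.

# Numerical choices and degenerate inputs

* Fisher ties use a $1+10^{-7}$ relative tolerance; an all-zero table
  is an error (the test is undefined).
* The odds ratio `0/0` gives direction `none`; zero denominators give
  `Inf` (enriched).
* `str_statistics` rejects non-positive region sizes; empty locus sets
  give all-zero tables.
* Sequences shorter than 3 bp translate to empty frames with a
  warning; missing depth rows give mean 0 with a warning; hits on
  sequences absent from the placed map count as unplaced with a
  warning.
* Greedy non-overlap selection in the profile scan and greedy
  left-to-right window resolution in the MHC classifier break ties by
  score order and genomic order respectively, making outputs
  deterministic.

# Problem sizes used by the test and acceptance suites

The shipped suites exercise: the exhaustive detector-versus-oracle
comparison over all two-letter strings of length 12–13 plus 150–180
salted kilobase sequences; exact-test agreement on all 2×2 tables with
$n \le 14$ plus 500–900 random tables to $n = 40$; enrichment power
over 20 replicates of the 510-term two-species design; and the full
default simulation (6 × 300 kbp background plus domain contigs,
~1.82 Mbp). These sizes keep the whole pipeline reproducible in
minutes on a single core while leaving every contract exercised at its
boundary; all are parameters, and larger runs only change runtime.

# Known limitations

* Perfect-repeat detection understates densities relative to
  imperfect-repeat annotators; comparisons across tools must hold the
  detector fixed.
* The PSSM census does not produce E-values and is not calibrated
  against profile-HMM bit scores; thresholds are per-profile contracts.
* The collapse diagnostic assumes depth scales linearly with copy
  number and is blind to collapse on sequences without domain hits.
* Between-species enrichment assumes a shared GO vocabulary and
  comparable annotation depth; unequal annotation pipelines will show
  up as spurious differences.
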