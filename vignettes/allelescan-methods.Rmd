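---
title: "Methods: gene-disabling mutation scanning and diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-disabling mutation scanning and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelescan)
```

# Scope and model of the locus

`allelescan` analyzes allele sets of a single plus-strand nuclear gene
against one reference functional allele. Its built-in default architecture
is that of the Myr II myrosinase subfamily, typified by *AtTGG6* in
*Arabidopsis thaliana*: 13 exons and 12 introns, a 1539-nt CDS encoding a
512-residue preprotein plus stop, GT donors and AG acceptors everywhere
except intron 10, whose donor is the unusual GC. All coordinates
("reference coordinates") are 1-based on the unspliced reference, with +1
the first base of the start codon — the convention in which the mutation
catalogue of this locus is reported.

The pipeline has five stages: gene-model annotation, pairwise alignment
with indel normalization, mutation scanning and typing, partitioned
diversity statistics, and distance-based phylogeny. A sixth component, the
population simulator, generates data under known truth for validation.

# Gene-model annotation

`infer_model()` maps a spliced cDNA onto a genomic sequence by greedy exact
extension with k-mer re-anchoring across introns, followed by boundary
refinement. This exploits the fact that alleles of a single locus are
highly similar (≥ ~85% identity here), so full spliced dynamic programming
is unnecessary; anchors of `min_exon_len = 12` bases are essentially unique
at gene scale (expected chance hits per 2.6-kb gene: 2559 × 4⁻¹² ≈ 1.5 × 10⁻⁴).

Two numerical choices matter:

* **Substitution vs intron decision.** When extension hits a mismatch, the
  match is resumed one base later and the length of the resumed run decides
  the hypothesis: a genuine substitution (e.g. a SNP between allele and
  reference cDNA) resumes matching for a long run, while an intron start
  "resumes" only by chance with probability 4⁻ᵏ for a k-base run. The
  threshold is 8 bases (false-accept probability ≈ 1.5 × 10⁻⁵ per
  junction). If no downstream anchor can be found (a substitution within a
  few bases of an exon boundary corrupts the anchor k-mer), the
  substitution hypothesis is accepted as a fallback when the match resumes
  at all.
* **Boundary ambiguity.** When sequence repeats make several intron
  placements explain the same cDNA, the placement is slid within the
  ambiguity window to maximize splice-border dinucleotide match (donor
  GT — or GC for intron 10, identified positionally so expectations
  survive upstream indels — and acceptor AG), with ties going to the
  leftmost placement. The original analysis of this locus does not state a
  tie-break; the border-preferring leftmost rule is this package's
  convention and is deterministic.

Inference is verified internally: the spliced output must equal the cDNA's
length and may disagree with it at no more than 20% of positions (the slack
admits allele-vs-reference SNPs; exact inputs reproduce the model exactly,
which the test suite asserts over many simulated genes).

`translate_cds()` uses the standard nuclear code; alternative codes are out
of scope. An out-of-frame CDS is flagged, not rejected, because disabled
alleles routinely splice out of frame.

# Alignment and indel normalization

`global_align()` wraps affine-gap global (Needleman–Wunsch/Gotoh)
alignment; a gap run of length L costs `gap_open + gap_extend × L`. The
defaults (+1/−2, open 8, extend 1) were chosen so that isolated disabling
indels of 1–208 bases between ~85–97% identical sequences are recovered as
single gap runs rather than split gaps: a 208-base deletion costs 216,
far cheaper than any mismatch path, while splitting a gap in two costs an
extra `gap_open`. The test suite proves optimality against exhaustive
enumeration on short sequences.

`left_normalize()` shifts every gap run maximally leftward (the VCF-style
convention) without changing either sequence or the score; it is idempotent
and makes indel coordinates reproducible in homopolymer/repeat context.
Insertions are keyed to the reference base immediately left of the inserted
material, which matches the "insertion at +155" phrasing used for this
locus's catalogue.

# Mutation scanning, typing, functionality

`scan_allele()` reports every insertion and deletion, plus substitutions at
splice-border dinucleotides read through the coordinate map. Point
substitutions elsewhere are deliberately *not* events — they are diversity,
not lesions; nonsense point mutations are instead caught by the ORF check.
Flags follow from arithmetic, not labels:

* `frameshift` ⇔ exonic overlap > 0 and ≢ 0 (mod 3). A deletion's exonic
  overlap is computed against the model (e.g. the 17-base border deletion
  +2111..+2127 has 4 intronic + 13 exonic bases, hence frame-shifting);
  insertions inherit the region of their left flanking base.
* `splice_disrupting` ⇔ the event substitutes or removes an expected
  border dinucleotide (a deletion overlapping the intron-10 acceptor
  disables splicing in addition to any frame shift).

`call_functionality()` declares an allele functional iff it has no
frame-shifting and no splice-disrupting event *and* its own spliced CDS
(the reference model projected through the pairwise alignment) starts with
ATG, is a codon multiple, has no premature stop, and yields the reference
protein length (512 aa by default). The published analysis of this locus
does not state whether an ORF-level check beyond the mutation catalogue was
applied; the stricter check is this package's convention, and it is what
catches nonsense substitutions. A codon-preserving (3n) indel therefore
still disables an allele here if it changes the protein length — flagged as
`protein_length_<n>` so the reason is machine-readable.

`build_catalogue()` merges events with identical keys
(kind, start, end, length, detail) into types named Mu1, Mu2, … in
ascending coordinate order (ties: kind, length, detail). Exact-coordinate
identity is deliberate: nearby same-length events are distinct types, as in
the published catalogue where two 17-base deletions 20 nt apart are
separate types. `build_matrix()` marks a cell "N/A" when the allele carries
a larger deletion spanning the type's locus. One knowing deviation from the
published table: that table prints "N/A" only for the 208-base deletion
masking the exon-3 insertion locus, but prints "−" for carriers of the
border deletion at the three loci it spans; the package applies the
spanning rule uniformly, so those cells are "N/A" here.

# Diversity statistics

Site filtering follows the common "complete deletion" default of DnaSP-style
analyses: S, π, θw and haplotype identity use only columns with no gap and
no N in any row; indel sites are counted on all columns (a column with ≥ 1
gap is one indel site). Per-kb densities divide by the *total* aligned
length — the published per-kb numbers for this locus are integers of the
observed site counts only under that convention, which is how it was fixed
here. Variances: Nei (1987) eq. 8.12 for Hd, Nei (1987) eq. 10.7 for π,
Watterson (1975) for θw — the standard formulas behind those defaults.

`partition_alignment()` projects exon/intron labels through the reference
row's gaps; insertion columns inherit the region of the left flanking
reference base, so the exon and intron column sets always partition the
alignment. The five-partition report (genomic / exons / introns /
functional / disabled) mirrors the layout in which diversity of this locus
is reported. The one-way ANOVA comparing exon vs intron diversity is out of
scope; the report exposes the per-partition numbers such a test would
consume.

When no externally aligned MSA is supplied, `merge_alignments()` builds a
reference-anchored multiple alignment by merging left-normalized pairwise
alignments on reference coordinates (insertions at one anchor are
left-justified and padded). This is a deterministic coordinate merge, not a
progressive MSA: columns inside co-anchored insertions from different
alleles are not mutually aligned. For reference-centric site counting this
is adequate; reproducing alignment-dependent published statistics exactly
would additionally require the original progressive alignment and its
(unstated) parameters.

# Phylogeny

`tn93_distance()` implements the Tamura–Nei (1993) distance with empirical
base frequencies pooled over the pair and pairwise deletion of gap/N sites
(the common default for distance matrices); saturation (non-positive log
argument) returns `Inf` rather than an arbitrary cap. `nj_tree()` is
Saitou–Nei neighbor joining with two determinism guarantees: Q-criterion
ties join the lowest-index pair, and a negative branch length is clamped to
zero with the deficit moved to its sibling so the joined pair's path length
is preserved. The published phylogeny of this locus was a maximum-likelihood
search with bootstrap and a divergence-time axis; ML inference and clock
calibration are out of scope here — TN93 + NJ is the testable
distance-level counterpart (additive matrices are recovered exactly).

`min_independent_losses()` quantifies the observation that disabled alleles
are scattered across clades: it is the small-parsimony (Sankoff) minimum
number of functional → disabled transitions with the root fixed functional
(the ancestral allele is functional), ties resolved toward "functional".
No published count exists for this quantity, so it is property-tested
(0 when all leaves are functional; ≥ 1 when any is disabled; ≤ the number
of disabled leaves), not compared to a printed value.

# The simulator: what it emulates, and what it does not

`make_reference()` draws a random gene honoring the architecture above.
The default exon lengths (159, 130, 90, 110, 80, 60, 150, 120, 250, 115,
90, 120, 65; introns 85 nt) are not arbitrary: they are the unique-style
layout derived so that *every* published catalogue coordinate falls in its
stated region — +155 in exon 1, +437 in intron 2, +481 in exon 3, +644 in
exon 4, +1007 in exon 6, +1158 in exon 7, +1739..+1817 in exon 9, intron 10
ending at +2114, +2121/+2127 in exon 11, +2311..+2348 in exon 12 — with a
total genomic span of 2559 nt, close to the real ~2.7-kb gene.

`simulate_alleles()` applies, per allele: neutral SNPs at `snp_rate` per
site (default 0.0075, the order of the locus's reported per-site
diversity), then planted catalogue events right-to-left so coordinates stay
in reference space. Determinism is per-allele: each allele's stream is
seeded from the run seed and the allele index, so reordering alleles does
not change their sequences.

Three stability conventions keep planted truth recoverable *exactly*, which
is what the recovery tests assert:

* border dinucleotides, the start codon and the terminal stop never
  receive SNPs, and exonic SNPs never create an in-frame stop (a nonsense
  mutation is a separate, deliberate plan entry);
* inserted strings are drawn once per catalogue entry (alleles sharing a
  type share the event, as identity-by-descent would imply) with the final
  base forced to differ from the anchor base, so insertions cannot
  left-shift; reference bases flanking catalogue deletions are adjusted at
  generation time so those deletions cannot left-shift either;
* SNPs are kept ≥ 10 bases away from planted events: a substitution close
  to an indel can otherwise create a score-tied alternative alignment in
  which the gap "rotates" through repeat context and absorbs the
  substitution, moving the detected coordinate.

What the simulator does **not** emulate: genealogy. Alleles mutate
independently from the common reference, so expected pairwise π is ≈ 2 ×
`snp_rate`, every allele is almost surely a unique haplotype (Hd ≈ 1), and
there is no linkage or population structure. Recovery tests therefore
validate the *measurement machinery* — alignment, scanning, typing,
functionality, statistics — not the demographic realism of the data.
Reproducing the published diversity table from real accessions additionally
depends on the original (unstated) progressive-alignment parameters; that
comparison is an optional integration exercise for users with the GenBank
sequences (accessions KU301827–KU301855), not part of the desk-scale test
suite. The formula-level anchor is asserted instead: the published
29-allele haplotype partition {4, 3, 2, 2, 18 singletons} evaluates to
Hd = 0.973 under the estimator above.

# Problem sizes and determinism

The test suite runs entirely on synthetic data generated in-process: oracle
equalities use 200 random alignments (n ≤ 12, L ≤ 300) and exhaustive
alignment enumeration up to length 8; end-to-end recovery uses 20 seeded
simulations of 30 alleles (the 29-row published distribution plus one
nonsense-mutation carrier exercising the ORF path) over the full 2.6-kb
gene. Every stochastic step is seeded; the acceptance script derives all
randomness from its `--seed` argument.

# Known limitations

* Genomic-vs-genomic scanning assumes one reference and plus-strand
  sequences; reverse-complementing is a preprocessing step.
* `infer_model()` tolerates substitutions but not indels within exons;
  allele-specific models in the presence of indels are obtained by
  projecting the reference model through the pairwise alignment instead
  (this is what `call_functionality()` does).
* The merged MSA is reference-anchored (see above); supply an external MSA
  as gapped FASTA where column-exact multiple alignment matters.
* Distances are undefined (NA) for pairs with no comparable sites and
  infinite under saturation; `nj_tree()` expects a finite matrix.
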