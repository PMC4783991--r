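# allelescan

Pseudogenization analysis of a plant myrosinase locus: splice-aware gene
models, frame-shift and splice-border mutation scanning, functional/disabled
allele calls, partitioned diversity statistics, and distance-based phylogeny.

## The problem

*AtTGG6* is a pollen-expressed Myr II myrosinase gene of *Arabidopsis
thaliana* (13 exons, 12 introns, canonical GT/AG splice borders except a GC
donor at intron 10). Across natural ecotypes the locus segregates functional
alleles — a 1539-nt CDS encoding a 512-residue preprotein — alongside
disabled alleles carrying frame-shifting insertions/deletions and
substitutions of the intron-10 3′ splice border. Analyzing such an allele
set means answering, reproducibly:

* where are the exons and introns of each allele, and are the splice
  borders intact?
* which indel and splice-border lesions does each allele carry, typed
  against a reference-anchored catalogue (Mu1, Mu2, ...)?
* which alleles are functional (intact ORF: ATG start, in-frame, no
  premature stop, full-length protein) and which are disabled?
* how diverse is the locus — haplotype diversity, nucleotide diversity π,
  Watterson's θw, SNP and indel densities — overall and partitioned by
  exon/intron and by functionality?
* how often was the gene disabled independently on the allele phylogeny?

`allelescan` implements this pipeline end to end, plus a synthetic
allele-population simulator that plants the published 13-type mutation
catalogue and emits a machine-readable truth ledger, so every stage can be
validated by exact recovery.

## Core statistics and models

* **Mutation events.** Alleles are aligned to the reference functional
  allele with affine-gap global alignment (match +1, mismatch −2, gap open
  8, extend 1); gap runs are left-normalized so indel coordinates are
  reproducible in repeat context. An indel is frame-shifting when its
  exonic base count is ≢ 0 (mod 3); an event is splice-disrupting when it
  removes or substitutes an expected border dinucleotide. Coordinates are
  1-based from the first base of the start codon.
* **Diversity.** On gap-free, N-free columns: Hd = n(1 − Σxᵢ²)/(n − 1)
  with Nei's variance; π = mean pairwise difference per site with Nei's
  variance; θw = S/(aₙL) with Watterson's variance. Indel sites are counted
  on all columns; per-kb densities divide by total aligned length.
* **Phylogeny.** Tamura–Nei (TN93) distances (pairwise deletion, empirical
  base frequencies, separate purine/pyrimidine transition classes),
  Saitou–Nei neighbor joining with deterministic tie-breaking and
  non-negative branch lengths, and a small-parsimony count of independent
  functional → disabled transitions (root fixed functional).

## Worked example

Simulate a 29-allele population that replicates the published distribution
of the 13 catalogue mutations, then scan it:

```r
library(allelescan)
dir <- file.path(tempdir(), "demo")
cmd_simulate(dir, seed = 1, plan = "published")
res <- cmd_scan(file.path(dir, "alleles.fasta"),
                file.path(dir, "reference.fasta"),
                file.path(dir, "model.tsv"),
                file.path(dir, "scan"))
res$summary
```

prints (seed 1):

```
alleles: 29  functional: 10  disabled: 19  mutation types: 13
type frequencies: Mu1 8 Mu2 1 Mu3 3 Mu4 6 Mu5 2 Mu6 4 Mu7 1 Mu8 4 Mu9 2 Mu10 3 Mu11 1 Mu12 4 Mu13 2
events in intron-10 border region: 10
```

i.e. the scanner recovers, from raw sequence alone, the planted 10
functional / 19 disabled split, all 13 mutation types at their planted
coordinates (e.g. Mu8, the 17-base deletion crossing the intron-10
acceptor: 4 intronic + 13 exonic bases, frame-shifting and
splice-disrupting), the frequency spectrum, and the 10 events clustered at
the unusual GC/AG intron's 3′ border. Diversity and phylogeny run the same
way:

```r
cmd_diversity(file.path(dir, "alleles.fasta"), file.path(dir, "reference.fasta"),
              file.path(dir, "model.tsv"), file.path(dir, "div"))
#        label  n   S indel_sites hd     pi theta_w
#      genomic 29 436         268  1 0.0143  0.0483
#        exons 29 279         156  1 0.0151  0.0511
#      introns 29 157         112  1 0.0132  0.0440
#   functional 10 168           7  1 0.0137  0.0232
#     disabled 19 299         268  1 0.0146  0.0372
ph <- cmd_phylo(file.path(dir, "alleles.fasta"), file.path(dir, "reference.fasta"),
                file.path(dir, "model.tsv"), file.path(dir, "phy"))
ph$losses   # independent disabling events on the NJ tree: 5
```

(Under the simulator's independent-mutation model every allele is a unique
haplotype, hence Hd = 1 here; see the methods vignette for what the
simulator does and does not emulate.)

A thin shell wrapper over the same functions is installed at
`inst/cli/allelescan.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","allelescan.R",package="allelescan"))')" \
  scan --alleles alleles.fasta --reference reference.fasta --model model.tsv --out outdir
```

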