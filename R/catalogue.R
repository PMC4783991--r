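# The published frame-shift mutation catalogue of the AtTGG6 locus and the
# distribution of those mutations among 29 A. thaliana ecotypes, encoded as
# plain-text fixtures under inst/extdata. Coordinates are 1-based from the
# first nucleotide of the start codon of the functional (Tsu-1) allele.

#' The published 13-type mutation catalogue of the AtTGG6 locus
#'
#' Thirteen disabling mutation types (Mu1-Mu13): exonic insertions and
#' deletions of 1-208 bases and two substitutions of the intron-10 3'
#' splice border (AG to AT, AG to GG). Splice-border substitutions are
#' keyed at the acceptor dinucleotide; insertions at the reference base
#' left of the inserted material.
#'
#' @return data.frame: mu_id, kind, ref_start, ref_end, length,
#'   intron_index (NA for exonic events), detail, description.
#' @export
mutation_catalogue <- function() {
  path <- system.file("extdata", "attgg6_mutation_catalogue.tsv",
                      package = "allelescan", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$detail[is.na(tab$detail)] <- ""
  tab
}

#' The published distribution of mutation types among 29 ecotypes
#'
#' Presence/absence of each catalogue type in each of 29 ecotype alleles
#' ("+" present, "-" absent, "N/A" unassessable because a larger deletion
#' spans the locus), with the functional/disabled verdict per allele.
#'
#' @return data.frame shaped like [build_matrix()] output: allele_id,
#'   Mu1..Mu13, functionality.
#' @export
published_distribution <- function() {
  path <- system.file("extdata", "attgg6_mutation_matrix.tsv",
                      package = "allelescan", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Reference window of the intron-10 3' splice-border region
#'
#' The hot-spot window around the unusual GC/AG intron's acceptor: it spans
#' the loci of the four border-region mutation types (the 17-base deletion
#' into exon 11, the two acceptor substitutions, and the exon-11 single-base
#' insertion).
#'
#' @return integer vector `c(start, end)` in reference coordinates.
#' @export
intron10_border_region <- function() c(2111L, 2127L)
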