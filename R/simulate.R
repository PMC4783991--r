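# Synthetic allele-population generator. Produces a reference functional
# gene honoring the Myr II architecture (13 exons, GC donor for intron 10,
# AG acceptors, 1539-nt CDS encoding 512 aa + stop), then allele sets with
# neutral SNPs and planted disabling events from the published catalogue,
# together with a machine-readable truth ledger for recovery tests.

# Default exon lengths (sum 1539). Chosen so every published catalogue
# coordinate falls in its stated region: +155 in exon 1, +437 in intron 2,
# +481 in exon 3, +644 in exon 4, +1007 in exon 6, +1158 in exon 7,
# +1739..+1817 in exon 9, intron 10 ending at +2114, +2121/+2127 in
# exon 11, +2311..+2348 in exon 12.
.DEFAULT_EXON_LENGTHS <- c(159L, 130L, 90L, 110L, 80L, 60L, 150L, 120L,
                           250L, 115L, 90L, 120L, 65L)

#' Simulation configuration
#'
#' @param n_exons number of exons (default 13, the Myr II architecture).
#' @param cds_len CDS length in nt (default 1539 = 512 codons + stop);
#'   must be a multiple of 3.
#' @param intron_len intron length (default 85 nt; must be >= 4).
#' @param exon_lengths optional explicit exon lengths summing to `cds_len`;
#'   the default 13-exon layout places the published mutation catalogue's
#'   coordinates in their stated exons/introns.
#' @param gc_donor_introns introns allowed a GC donor (default 10).
#' @param snp_rate per-site neutral substitution probability per allele
#'   (default 0.0075, the order of the locus's per-site diversity).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 13L, cds_len = 1539L, intron_len = 85L,
                       exon_lengths = NULL, gc_donor_introns = 10L,
                       snp_rate = 0.0075, seed = 1L) {
  stopifnot(cds_len %% 3L == 0L, n_exons >= 2L,
            snp_rate >= 0, snp_rate < 1)
  if (intron_len < 4L) stop("introns must be at least 4 bases", call. = FALSE)
  if (is.null(exon_lengths)) {
    if (n_exons == 13L && cds_len == 1539L) {
      exon_lengths <- .DEFAULT_EXON_LENGTHS
    } else {
      base <- cds_len %/% n_exons
      exon_lengths <- rep(base, n_exons)
      exon_lengths[n_exons] <- cds_len - base * (n_exons - 1L)
    }
  }
  stopifnot(sum(exon_lengths) == cds_len, length(exon_lengths) == n_exons,
            all(exon_lengths >= 1L))
  structure(list(n_exons = as.integer(n_exons), cds_len = as.integer(cds_len),
                 intron_len = as.integer(intron_len),
                 exon_lengths = as.integer(exon_lengths),
                 gc_donor_introns = as.integer(gc_donor_introns),
                 snp_rate = snp_rate, seed = as.integer(seed)),
            class = "sim_config")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# deterministic sub-seed per allele index, kept under 2^31
.sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629)
}

#' Generate a random functional reference gene
#'
#' The CDS starts with ATG, ends with a stop codon, has no in-frame
#' internal stop, and is split across the configured exons; introns carry
#' the expected border dinucleotides (GC donor for intron 10, GT elsewhere,
#' AG acceptors). Bases flanking the published catalogue's deletion loci
#' are adjusted so those deletions cannot left-shift in homopolymer
#' context, keeping planted coordinates identical to detected ones.
#'
#' @param config a [sim_config()].
#' @return list: `reference` (genomic DNA string), `cdna` (spliced CDS),
#'   `model` (a `gene_model`).
#' @export
make_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  n_codons <- config$cds_len %/% 3L
  sense <- setdiff(apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                                     c("T","C","A","G")), 1, paste, collapse = ""),
                   .STOP_CODONS)
  codons <- c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  # exon/intron layout
  starts <- integer(config$n_exons); ends <- integer(config$n_exons)
  pos <- 1L
  cds_off <- 0L
  pieces <- character(0)
  for (k in seq_len(config$n_exons)) {
    len <- config$exon_lengths[k]
    starts[k] <- pos; ends[k] <- pos + len - 1L
    pieces <- c(pieces, substring(cds, cds_off + 1L, cds_off + len))
    cds_off <- cds_off + len
    pos <- pos + len
    if (k < config$n_exons) {
      donor <- if (k %in% config$gc_donor_introns) "GC" else "GT"
      interior <- paste(sample(c("A","C","G","T"), config$intron_len - 4L,
                               replace = TRUE), collapse = "")
      pieces <- c(pieces, paste0(donor, interior, "AG"))
      pos <- pos + config$intron_len
    }
  }
  model <- gene_model(starts, ends, gc_donor_introns = config$gc_donor_introns)
  genomic <- paste(pieces, collapse = "")
  genomic <- .pin_catalogue_loci(genomic, model)
  list(reference = genomic, cdna = splice(genomic, model), model = model)
}

# Prevent left-normalization drift of the built-in catalogue deletions:
# ensure ref[s-1] != ref[e] for each deletion [s, e] that fits the model.
.pin_catalogue_loci <- function(genomic, model) {
  g <- strsplit(genomic, "")[[1]]
  cat_path <- system.file("extdata", "attgg6_mutation_catalogue.tsv",
                          package = "allelescan")
  if (cat_path == "") return(genomic)  # during bootstrap
  cat_tab <- read.delim(cat_path, stringsAsFactors = FALSE)
  dels <- cat_tab[cat_tab$kind == "deletion", , drop = FALSE]
  forbidden <- .forbidden_positions(model, length(g))
  for (k in seq_len(nrow(dels))) {
    s <- dels$ref_start[k]; e <- dels$ref_end[k]
    if (s < 2L || e > length(g)) next
    if (g[s - 1L] != g[e]) next
    p <- s - 1L
    if (p %in% forbidden) next
    for (cand in setdiff(c("A", "C", "G", "T"), g[e])) {
      old <- g[p]; g[p] <- cand
      if (.creates_frame_stop(g, model, p)) { g[p] <- old; next }
      break
    }
  }
  paste(g, collapse = "")
}

# positions where neutral substitutions are not placed: splice-border
# dinucleotides, the start codon, and the terminal stop codon
.forbidden_positions <- function(model, L) {
  b <- .border_positions(model)
  pos <- c(b$p1, b$p2)
  first_exon <- model$exons$start[1]
  last_exon_end <- model$exons$end[nrow(model$exons)]
  c(pos, first_exon:(first_exon + 2L), (last_exon_end - 2L):last_exon_end)
}

# would the base at genomic position p (already substituted in g) put a
# stop codon in the reading frame of the spliced CDS?
.creates_frame_stop <- function(g, model, p) {
  reg <- region_of(model, p)
  if (!grepl("^exon", reg)) return(FALSE)
  k <- as.integer(sub("exon ", "", reg))
  cds_before <- if (k > 1) sum(model$exons$end[1:(k - 1L)] -
                               model$exons$start[1:(k - 1L)] + 1L) else 0L
  cds_pos <- cds_before + (p - model$exons$start[k]) + 1L
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  cds <- splice(paste(g, collapse = ""), model)
  codon <- substring(cds, 3L * codon_idx - 2L, 3L * codon_idx)
  codon %in% .STOP_CODONS
}

#' Simulate an allele population with planted mutations
#'
#' Per allele, neutral SNPs are placed first (uniformly at `snp_rate` per
#' site, skipping splice borders, the start codon and the terminal stop,
#' and never creating an in-frame stop), so that event coordinates stay in
#' reference space; planted events from the catalogue are then applied
#' right-to-left. Inserted bases are drawn randomly with the final base
#' forced to differ from the anchor base, so insertions cannot left-shift.
#' Deterministic: each allele uses a sub-seed derived from the run seed and
#' the allele index.
#'
#' @param reference genomic reference DNA string.
#' @param model the reference `gene_model`.
#' @param config a [sim_config()] (supplies snp_rate and seed).
#' @param plan data.frame with columns `allele_id`, `mu_id` assigning
#'   catalogue events to alleles; alleles absent from the plan receive no
#'   events. NULL means no planted events anywhere.
#' @param allele_ids ids of the alleles to simulate.
#' @param catalogue event catalogue (default [mutation_catalogue()]); may
#'   contain extra rows, including kind "nonsense_sub" (single-base
#'   substitution at ref_start creating an in-frame stop; detail = new
#'   base).
#' @return list of class `sim_result`: `alleles` (named character vector),
#'   `truth` (list: `events` data.frame with allele_id, mu_id, kind,
#'   ref_start, ref_end, length, detail, frameshift, splice_disrupting;
#'   `functionality` named character; `snps` named list of integer
#'   positions), `reference`, `model`, `config`.
#' @export
simulate_alleles <- function(reference, model, config = sim_config(),
                             plan = NULL,
                             allele_ids = sprintf("sim%02d", seq_len(10L)),
                             catalogue = mutation_catalogue()) {
  L <- nchar(reference)
  gref <- strsplit(reference, "")[[1]]
  forbidden <- .forbidden_positions(model, L)
  # one inserted string per catalogue insertion, shared by every carrier:
  # alleles sharing a type share the event, not independent re-draws
  set.seed(.sub_seed(config$seed, 0L))
  ins_seqs <- setNames(vector("list", nrow(catalogue)), catalogue$mu_id)
  for (k in which(catalogue$kind == "insertion")) {
    a <- catalogue$ref_start[k]
    ins <- sample(c("A", "C", "G", "T"), catalogue$length[k], replace = TRUE)
    if (ins[length(ins)] == gref[a]) {
      ins[length(ins)] <- sample(setdiff(c("A", "C", "G", "T"), gref[a]), 1L)
    }
    ins_seqs[[catalogue$mu_id[k]]] <- ins
  }
  truth_events <- list()
  truth_snps <- list()
  functionality <- setNames(rep("functional", length(allele_ids)), allele_ids)
  alleles <- setNames(character(length(allele_ids)), allele_ids)
  for (i in seq_along(allele_ids)) {
    id <- allele_ids[i]
    set.seed(.sub_seed(config$seed, i))
    g <- gref
    # events planned for this allele (needed to keep SNPs clear of them)
    plan_rows <- if (is.null(plan)) integer(0) else
      match(plan$mu_id[plan$allele_id == id], catalogue$mu_id)
    planned <- catalogue[plan_rows[!is.na(plan_rows)], , drop = FALSE]
    # --- neutral SNPs ---
    cand <- which(runif(L) < config$snp_rate)
    cand <- setdiff(cand, forbidden)
    if (nrow(planned) > 0L) {
      # a substitution near an indel can create a score-tied alternative
      # gap placement (the indel "rotates" through the repeat context and
      # absorbs the substitution); a 10-base exclusion buffer around each
      # planted event keeps planted coordinates stable
      near <- unlist(lapply(seq_len(nrow(planned)), function(k) {
        (planned$ref_start[k] - 10L):(planned$ref_end[k] + 10L)
      }))
      cand <- setdiff(cand, near)
    }
    placed <- integer(0)
    for (p in cand) {
      for (b in sample(setdiff(c("A", "C", "G", "T"), g[p]))) {
        old <- g[p]; g[p] <- b
        if (.creates_frame_stop(g, model, p)) { g[p] <- old; next }
        placed <- c(placed, p)
        break
      }
    }
    truth_snps[[id]] <- placed
    # --- planted events ---
    if (any(is.na(plan_rows))) {
      stop("plan references unknown mu_id(s) for allele ", id, call. = FALSE)
    }
    evs <- planned
    if (nrow(evs) > 1L) {
      ord <- order(evs$ref_start)
      so <- evs[ord, ]
      if (any(so$ref_start[-1] <= so$ref_end[-nrow(so)])) {
        stop("planted events overlap for allele ", id, call. = FALSE)
      }
    }
    if (nrow(evs) > 0L && (min(evs$ref_start) < 1L || max(evs$ref_end) > L)) {
      stop("planted event out of reference bounds for allele ", id, call. = FALSE)
    }
    evs <- evs[order(evs$ref_start, decreasing = TRUE), , drop = FALSE]
    for (k in seq_len(nrow(evs))) {
      e <- evs[k, ]
      rec <- .plant_event(g, gref, model, e, ins_seqs[[e$mu_id]])
      g <- rec$g
      truth_events[[length(truth_events) + 1L]] <- cbind(
        data.frame(allele_id = id, mu_id = e$mu_id, stringsAsFactors = FALSE),
        rec$truth)
      if (rec$truth$frameshift || rec$truth$splice_disrupting ||
          e$kind == "nonsense_sub") {
        functionality[id] <- "disabled"
      }
    }
    alleles[id] <- paste(g, collapse = "")
  }
  events <- if (length(truth_events)) do.call(rbind, truth_events) else
    data.frame(allele_id = character(0), mu_id = character(0),
               kind = character(0), ref_start = integer(0),
               ref_end = integer(0), length = integer(0),
               detail = character(0), frameshift = logical(0),
               splice_disrupting = logical(0))
  events <- events[order(events$allele_id, events$ref_start), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(alleles = alleles,
                 truth = list(events = events, functionality = functionality,
                              snps = truth_snps),
                 reference = reference, model = model, config = config),
            class = "sim_result")
}

# apply one planted event to character vector g (current allele state);
# gref is the unmutated reference (for truth normalization of deletions);
# ins is the run-wide inserted string for insertion catalogue entries
.plant_event <- function(g, gref, model, e, ins = NULL) {
  borders <- .border_positions(model)
  s <- e$ref_start; en <- e$ref_end
  if (e$kind == "deletion") {
    g <- g[-(s:en)]
    # left-normalize truth coordinates against the reference context
    while (s > 1L && gref[s - 1L] == gref[en]) { s <- s - 1L; en <- en - 1L }
    exonic <- .exonic_overlap(model, s, en)
    sd <- any(borders$p1 <= en & borders$p2 >= s)
    truth <- data.frame(kind = "deletion", ref_start = s, ref_end = en,
                        length = e$length, detail = "",
                        frameshift = exonic > 0L && exonic %% 3L != 0L,
                        splice_disrupting = sd, stringsAsFactors = FALSE)
  } else if (e$kind == "insertion") {
    stopifnot(!is.null(ins), length(ins) == e$length)
    g <- append(g, ins, after = s)
    reg <- region_of(model, s)
    exonic <- if (grepl("^exon", reg)) e$length else 0L
    truth <- data.frame(kind = "insertion", ref_start = s, ref_end = s,
                        length = e$length, detail = paste(ins, collapse = ""),
                        frameshift = exonic > 0L && exonic %% 3L != 0L,
                        splice_disrupting = any(borders$p1 == s),
                        stringsAsFactors = FALSE)
  } else if (e$kind %in% c("splice_donor_sub", "splice_acceptor_sub")) {
    new <- strsplit(e$detail, "")[[1]]
    stopifnot(length(new) == 2L, en == s + 1L)
    g[s] <- new[1]; g[s + 1L] <- new[2]
    truth <- data.frame(kind = e$kind, ref_start = s, ref_end = en,
                        length = 2L, detail = e$detail, frameshift = FALSE,
                        splice_disrupting = TRUE, stringsAsFactors = FALSE)
  } else if (e$kind == "nonsense_sub") {
    g[s] <- e$detail
    truth <- data.frame(kind = "nonsense_sub", ref_start = s, ref_end = s,
                        length = 1L, detail = e$detail, frameshift = FALSE,
                        splice_disrupting = FALSE, stringsAsFactors = FALSE)
  } else {
    stop("unknown planted event kind: ", e$kind, call. = FALSE)
  }
  list(g = g, truth = truth)
}

#' Build the plan replicating the published 29-ecotype distribution
#'
#' @param distribution data.frame from [published_distribution()].
#' @return data.frame (allele_id, mu_id) listing each "+" cell.
#' @export
distribution_plan <- function(distribution = published_distribution()) {
  mu_cols <- setdiff(names(distribution), c("allele_id", "functionality"))
  rows <- list()
  for (i in seq_len(nrow(distribution))) {
    present <- mu_cols[distribution[i, mu_cols] == "+"]
    if (length(present)) {
      rows[[length(rows) + 1L]] <- data.frame(
        allele_id = distribution$allele_id[i], mu_id = present,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(allele_id = character(0), mu_id = character(0))
}

#' Write a simulated dataset to a directory
#'
#' Writes alleles.fasta, reference.fasta, cdna.fasta, model.tsv,
#' truth_events.tsv and truth_alleles.tsv; re-reading these reproduces the
#' in-memory objects.
#'
#' @param sim a `sim_result`.
#' @param outdir output directory (created if needed).
#' @return invisibly, `outdir`.
#' @export
emit_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$alleles, file.path(outdir, "alleles.fasta"))
  write_fasta(setNames(sim$reference, "reference"),
              file.path(outdir, "reference.fasta"))
  write_fasta(setNames(splice(sim$reference, sim$model), "reference_cdna"),
              file.path(outdir, "cdna.fasta"))
  write_gene_model(sim$model, file.path(outdir, "model.tsv"))
  write.table(sim$truth$events, file.path(outdir, "truth_events.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  al <- data.frame(allele_id = names(sim$alleles),
                   intended_functionality = unname(
                     sim$truth$functionality[names(sim$alleles)]),
                   n_snps = vapply(sim$truth$snps[names(sim$alleles)],
                                   length, integer(1)))
  write.table(al, file.path(outdir, "truth_alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
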