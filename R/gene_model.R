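# Gene-model representation and splice-aware operations.
#
# Coordinates ("ref coordinates") are 1-based inclusive positions on the
# unspliced genomic reference, with +1 the first base of the start codon.
# The locus modeled here is a Myr II myrosinase gene: 13 exons, 12 introns,
# canonical GT/AG splice borders except a GC donor for intron 10.

#' Construct a gene model
#'
#' @param starts,ends integer vectors of 1-based inclusive exon intervals,
#'   in ascending order.
#' @param gc_donor_introns introns (1-based index) whose donor may be GC in
#'   addition to GT. Default `10L`, the unusual border of the Myr II family.
#' @param donor_expect,acceptor_expect optional full overrides: lists (one
#'   element per intron) of allowed donor / acceptor dinucleotides.
#' @return object of class `gene_model` with elements `exons` (data.frame
#'   start/end), `introns` (data.frame start/end, zero rows for a single
#'   exon), `donor_expect`, `acceptor_expect`.
#' @export
gene_model <- function(starts, ends, gc_donor_introns = 10L,
                       donor_expect = NULL, acceptor_expect = NULL) {
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) == 0L || length(starts) != length(ends)) {
    stop("need matching non-empty exon start/end vectors", call. = FALSE)
  }
  if (any(starts > ends)) stop("exon start > end", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("exons must be sorted by start", call. = FALSE)
  }
  n <- length(starts)
  if (n > 1 && any(starts[-1] <= ends[-n])) {
    stop("exons overlap or touch: introns would be empty", call. = FALSE)
  }
  exons <- data.frame(start = starts, end = ends)
  if (n > 1) {
    introns <- data.frame(start = ends[-n] + 1L, end = starts[-1] - 1L)
  } else {
    introns <- data.frame(start = integer(0), end = integer(0))
  }
  n_introns <- nrow(introns)
  if (is.null(donor_expect)) {
    donor_expect <- rep(list("GT"), n_introns)
    for (i in intersect(gc_donor_introns, seq_len(n_introns))) {
      donor_expect[[i]] <- c("GT", "GC")
    }
  }
  if (is.null(acceptor_expect)) acceptor_expect <- rep(list("AG"), n_introns)
  stopifnot(length(donor_expect) == n_introns,
            length(acceptor_expect) == n_introns)
  structure(list(exons = exons, introns = introns,
                 donor_expect = donor_expect, acceptor_expect = acceptor_expect),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model: %d exons, %d introns, span %d..%d\n",
              nrow(x$exons), nrow(x$introns),
              x$exons$start[1], x$exons$end[nrow(x$exons)]))
  invisible(x)
}

#' Total genomic span and exonic length of a model
#' @param model a `gene_model`.
#' @return named integer vector with `span` and `exonic`.
#' @export
model_lengths <- function(model) {
  c(span = model$exons$end[nrow(model$exons)] - model$exons$start[1] + 1L,
    exonic = sum(model$exons$end - model$exons$start + 1L))
}

#' Label reference positions as exon/intron
#'
#' @param model a `gene_model`.
#' @param pos integer vector of reference positions.
#' @return character vector like "exon 3" / "intron 10"; positions outside
#'   the model span are labeled "flank".
#' @export
region_of <- function(model, pos) {
  out <- rep("flank", length(pos))
  for (k in seq_len(nrow(model$exons))) {
    hit <- pos >= model$exons$start[k] & pos <= model$exons$end[k]
    out[hit] <- paste("exon", k)
  }
  for (k in seq_len(nrow(model$introns))) {
    hit <- pos >= model$introns$start[k] & pos <= model$introns$end[k]
    out[hit] <- paste("intron", k)
  }
  out
}

#' Splice a genomic sequence on a model
#'
#' Concatenates the exon substrings in order, yielding the cDNA/CDS.
#'
#' @param genomic DNA string.
#' @param model a `gene_model`.
#' @return DNA string of length sum of exon lengths.
#' @export
splice <- function(genomic, model) {
  L <- nchar(genomic)
  if (any(model$exons$start < 1L) || any(model$exons$end > L)) {
    stop("exon interval out of sequence bounds (sequence length ", L, ")",
         call. = FALSE)
  }
  paste(substring(genomic, model$exons$start, model$exons$end), collapse = "")
}

.CODON_TABLE <- NULL

codon_table <- function() {
  tab <- as.character(Biostrings::GENETIC_CODE)
  names(tab) <- names(Biostrings::GENETIC_CODE)
  tab
}

#' Translate a CDS with diagnostics
#'
#' Standard nuclear genetic code. Translation is reported up to (not
#' including) the first stop codon. A CDS whose length is not a multiple of
#' three is flagged, not rejected, since disabled alleles routinely splice
#' to out-of-frame CDSs; the trailing partial codon is ignored.
#'
#' @param cds DNA string.
#' @return list with `protein` (aa string up to first stop), `n_codons`
#'   (complete codons), `starts_with_atg`, `length_mod3` (nchar mod 3),
#'   `first_stop_codon` (1-based codon index of the first stop, NA if none),
#'   `premature_stop` (stop strictly before the final complete codon),
#'   `has_terminal_stop`.
#' @export
translate_cds <- function(cds) {
  tab <- codon_table()
  n <- nchar(cds)
  n_codons <- n %/% 3L
  aa <- character(0)
  if (n_codons > 0) {
    codons <- substring(cds, 3L * seq_len(n_codons) - 2L, 3L * seq_len(n_codons))
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"  # codons containing N
  }
  stops <- which(aa == "*")
  first_stop <- if (length(stops)) stops[1] else NA_integer_
  prot_end <- if (is.na(first_stop)) n_codons else first_stop - 1L
  list(protein = paste(aa[seq_len(prot_end)], collapse = ""),
       n_codons = n_codons,
       starts_with_atg = n >= 3L && substring(cds, 1L, 3L) == "ATG",
       length_mod3 = n %% 3L,
       first_stop_codon = first_stop,
       premature_stop = !is.na(first_stop) && first_stop < n_codons,
       has_terminal_stop = !is.na(first_stop) && first_stop == n_codons)
}

#' Check splice-border dinucleotides
#'
#' For each intron, the donor is the first two intron bases and the
#' acceptor the last two; each is tested for membership in the model's
#' expected set (GT donor everywhere, GC additionally allowed for intron 10,
#' AG acceptor everywhere, by default).
#'
#' @param genomic DNA string carrying the model.
#' @param model a `gene_model`.
#' @return data.frame with columns intron_index, donor_obs, acceptor_obs,
#'   donor_ok, acceptor_ok.
#' @export
check_borders <- function(genomic, model) {
  ni <- nrow(model$introns)
  if (ni == 0L) {
    return(data.frame(intron_index = integer(0), donor_obs = character(0),
                      acceptor_obs = character(0), donor_ok = logical(0),
                      acceptor_ok = logical(0)))
  }
  len <- model$introns$end - model$introns$start + 1L
  if (any(len < 4L)) {
    stop("intron shorter than 4 bases: intron ",
         paste(which(len < 4L), collapse = ", "), call. = FALSE)
  }
  if (max(model$introns$end) > nchar(genomic)) {
    stop("model extends past sequence end", call. = FALSE)
  }
  donor <- substring(genomic, model$introns$start, model$introns$start + 1L)
  acceptor <- substring(genomic, model$introns$end - 1L, model$introns$end)
  data.frame(
    intron_index = seq_len(ni),
    donor_obs = donor,
    acceptor_obs = acceptor,
    donor_ok = mapply(function(d, i) d %in% model$donor_expect[[i]],
                      donor, seq_len(ni), USE.NAMES = FALSE),
    acceptor_ok = mapply(function(a, i) a %in% model$acceptor_expect[[i]],
                         acceptor, seq_len(ni), USE.NAMES = FALSE)
  )
}

# longest common prefix length of x[xi..] and y[yi..] (character vectors)
.lcp <- function(x, xi, y, yi) {
  n <- min(length(x) - xi, length(y) - yi) + 1L
  if (n <= 0L) return(0L)
  cmp <- x[xi:(xi + n - 1L)] == y[yi:(yi + n - 1L)]
  w <- which(!cmp)
  if (length(w) == 0L) n else w[1] - 1L
}

#' Infer a gene model by mapping a cDNA onto a genomic sequence
#'
#' Anchors the cDNA on the genomic sequence by greedy exact extension and
#' k-mer re-anchoring across introns, then refines each intron placement
#' within its ambiguity window to (a) maximize splice-border dinucleotide
#' match against the expectation for that intron index, then (b) prefer the
#' leftmost placement. Tolerates isolated substitutions (e.g. SNPs between
#' an allele and the reference cDNA) but not indels within exons.
#'
#' @param genomic genomic DNA string; its first base is taken as cDNA start.
#' @param cdna spliced cDNA string.
#' @param min_exon_len minimum anchor length (default 12).
#' @param gc_donor_introns as in [gene_model()]; border preference during
#'   refinement uses these expectations by intron index.
#' @return a `gene_model` such that `splice(genomic, model) == cdna`.
#' @export
infer_model <- function(genomic, cdna, min_exon_len = 12L, gc_donor_introns = 10L) {
  g <- strsplit(genomic, "")[[1]]
  cd <- strsplit(cdna, "")[[1]]
  nG <- length(g); nC <- length(cd)
  if (nC > nG) stop("cDNA longer than genomic sequence", call. = FALSE)
  exon_starts <- integer(0); exon_ends <- integer(0)
  gpos <- 1L; cpos <- 1L
  cur_start <- 1L
  k <- max(min_exon_len, 12L)
  max_mm <- 0L  # substitutions tolerated in a row before declaring an intron
  while (cpos <= nC) {
    m <- .lcp(g, gpos, cd, cpos)
    if (cpos + m - 1L >= nC) {
      # cDNA exhausted: close final exon
      exon_starts <- c(exon_starts, cur_start)
      exon_ends <- c(exon_ends, gpos + (nC - cpos))
      cpos <- nC + 1L
      break
    }
    mm_c <- cpos + m  # first mismatching cDNA position if we keep extending
    mm_g <- gpos + m
    # try treating the mismatch as a substitution: does the match resume?
    resume <- 0L
    if (mm_g <= nG) {
      if (mm_c == nC) {
        # substitution at the very last cDNA base: close the final exon
        exon_starts <- c(exon_starts, cur_start)
        exon_ends <- c(exon_ends, mm_g)
        cpos <- nC + 1L
        break
      }
      resume <- .lcp(g, mm_g + 1L, cd, mm_c + 1L)
      # a real substitution resumes matching for a long run; an intron
      # masquerading as one resumes only by chance (P ~ 4^-resume)
      if (resume >= 8L) {
        gpos <- mm_g + 1L; cpos <- mm_c + 1L
        next
      }
    }
    # intron: re-anchor the next exon with a k-mer strictly beyond the
    # ambiguous boundary zone
    if (mm_c + k - 1L > nC) {
      # too little cDNA left for a full anchor; use the whole suffix
      anchor <- paste(cd[mm_c:nC], collapse = "")
    } else {
      anchor <- paste(cd[mm_c:(mm_c + k - 1L)], collapse = "")
    }
    q <- .find_first(g, anchor, from = mm_g + 4L)
    if (is.na(q)) {
      # no downstream anchor (e.g. a substitution within a few bases of an
      # exon boundary corrupts the k-mer): fall back to the substitution
      # hypothesis if the match resumes at all
      if (resume >= 1L && mm_g <= nG) {
        gpos <- mm_g + 1L; cpos <- mm_c + 1L
        next
      }
      stop(sprintf("cannot map cDNA span %d..%d onto genomic sequence",
                   mm_c, min(nC, mm_c + k - 1L)), call. = FALSE)
    }
    # boundary b in cDNA coords: exon ends at some b <= mm_c - 1; sliding
    # left by j requires cd[(mm_c-j)..(mm_c-1)] == g[(q-j)..(q-1)]
    j_max <- 0L
    while (j_max < m &&
           q - j_max - 1L >= 1L &&
           cd[mm_c - j_max - 1L] == g[q - j_max - 1L]) {
      j_max <- j_max + 1L
    }
    intron_idx <- length(exon_starts) + 1L
    donor_exp <- if (intron_idx %in% gc_donor_introns) c("GT", "GC") else "GT"
    best_j <- 0L; best_score <- -1L
    for (j in 0:j_max) {
      istart <- mm_g - j      # first intron base (genomic)
      iend <- q - j - 1L      # last intron base
      if (iend - istart + 1L < 4L) next
      donor <- paste(g[istart:(istart + 1L)], collapse = "")
      acceptor <- paste(g[(iend - 1L):iend], collapse = "")
      sc <- (donor %in% donor_exp) + (acceptor == "AG")
      # leftmost placement = largest j; iterate ascending, accept strictly
      # better, so ties resolve to the leftmost among max scores via >=
      if (sc >= best_score) { best_score <- sc; best_j <- j }
    }
    exon_starts <- c(exon_starts, cur_start)
    exon_ends <- c(exon_ends, mm_g - best_j - 1L)
    cur_start <- q - best_j
    gpos <- q - best_j
    cpos <- mm_c - best_j
  }
  model <- gene_model(exon_starts, exon_ends, gc_donor_introns = gc_donor_introns)
  spliced <- splice(genomic, model)
  if (nchar(spliced) != nchar(cdna)) {
    stop("model inference failed: spliced length != cDNA length", call. = FALSE)
  }
  mism <- mean(strsplit(spliced, "")[[1]] != cd)
  if (mism > 0.2) {
    stop(sprintf(paste("model inference failed: spliced sequence disagrees",
                       "with the cDNA at %.0f%% of positions"), 100 * mism),
         call. = FALSE)
  }
  model
}

# first occurrence (1-based) of pattern string in character vector g at or
# after position `from`; NA if absent
.find_first <- function(g, pattern, from) {
  if (from > length(g)) return(NA_integer_)
  hay <- paste(g[from:length(g)], collapse = "")
  hit <- regexpr(pattern, hay, fixed = TRUE)
  if (hit < 0) NA_integer_ else from + as.integer(hit) - 1L
}
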