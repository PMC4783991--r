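# Detection and typing of gene-disabling lesions: insertions/deletions of
# any length (frame-shifting when the exonic base count is not a multiple
# of three) and substitutions at splice-border dinucleotides. Point
# substitutions elsewhere are treated as diversity, not lesions; premature
# stops introduced by them are caught by the ORF check in
# call_functionality().

.empty_events <- function() {
  data.frame(allele_id = character(0), kind = character(0),
             ref_start = integer(0), ref_end = integer(0), length = integer(0),
             regions = character(0), exonic_bases = integer(0),
             frameshift = logical(0), splice_disrupting = logical(0),
             detail = character(0), stringsAsFactors = FALSE)
}

# border dinucleotide positions (ref coords) per intron: donor (first two
# intron bases) and acceptor (last two)
.border_positions <- function(model) {
  ni <- nrow(model$introns)
  if (ni == 0L) return(data.frame(intron = integer(0), role = character(0),
                                  p1 = integer(0), p2 = integer(0)))
  rbind(
    data.frame(intron = seq_len(ni), role = "donor",
               p1 = model$introns$start, p2 = model$introns$start + 1L),
    data.frame(intron = seq_len(ni), role = "acceptor",
               p1 = model$introns$end - 1L, p2 = model$introns$end)
  )
}

# count of exonic reference positions in [s, e]
.exonic_overlap <- function(model, s, e) {
  sum(pmax(0L, pmin(e, model$exons$end) - pmax(s, model$exons$start) + 1L))
}

# region labels spanned by [s, e], in genomic order
.regions_spanned <- function(model, s, e) {
  labs <- character(0)
  add <- function(tab, what) {
    hit <- which(tab$end >= s & tab$start <= e)
    if (length(hit)) data.frame(start = tab$start[hit],
                                lab = paste(what, hit)) else NULL
  }
  parts <- rbind(add(model$exons, "exon"), add(model$introns, "intron"))
  if (is.null(parts) || nrow(parts) == 0L) return("flank")
  parts <- parts[order(parts$start), , drop = FALSE]
  parts$lab
}

#' Scan one allele against the reference for disabling mutations
#'
#' Aligns the allele to the reference (affine global alignment,
#' left-normalized), then reports every insertion and deletion plus any
#' substitution at a splice-border dinucleotide. An indel's `frameshift`
#' flag is set when its exonic base count is positive and not a multiple of
#' three; `splice_disrupting` is set when the event removes or substitutes
#' an expected border dinucleotide. Insertions are keyed to the reference
#' base immediately left of the inserted bases and inherit its region.
#'
#' @param allele,reference DNA strings (the reference carries `model`).
#' @param model a `gene_model` in reference coordinates.
#' @param allele_id id used in the report.
#' @param params an [align_params()].
#' @param aln optional precomputed left-normalized `pairwise_alignment` of
#'   reference vs allele (avoids re-aligning).
#' @return data.frame of events sorted by ref_start (possibly zero rows):
#'   allele_id, kind (insertion / deletion / splice_donor_sub /
#'   splice_acceptor_sub), ref_start, ref_end, length, regions
#'   (comma-separated), exonic_bases, frameshift, splice_disrupting, detail.
#' @export
scan_allele <- function(allele, reference, model, allele_id = "allele",
                        params = align_params(), aln = NULL) {
  if (is.null(aln)) aln <- left_normalize(global_align(reference, allele, params))
  map <- build_map(aln)
  borders <- .border_positions(model)
  events <- .empty_events()
  add_event <- function(kind, s, e, len, regions, exonic, detail) {
    fs <- exonic > 0L && (exonic %% 3L) != 0L
    sd <- FALSE
    if (kind == "deletion" && nrow(borders) > 0L) {
      sd <- any(borders$p1 <= e & borders$p2 >= s)
    } else if (kind == "insertion" && nrow(borders) > 0L) {
      # inserted between the two bases of a border dinucleotide
      sd <- any(borders$p1 == s)
    } else if (kind %in% c("splice_donor_sub", "splice_acceptor_sub")) {
      sd <- TRUE
    }
    rbind(events, data.frame(
      allele_id = allele_id, kind = kind, ref_start = s, ref_end = e,
      length = len, regions = paste(regions, collapse = ","),
      exonic_bases = exonic, frameshift = fs, splice_disrupting = sd,
      detail = detail, stringsAsFactors = FALSE))
  }
  # deletions: runs of NA in ref_to_alt
  del_runs <- .gap_runs(is.na(map$ref_to_alt))
  if (nrow(del_runs) > 0L) {
    for (k in seq_len(nrow(del_runs))) {
      s <- del_runs$start[k]; e <- del_runs$end[k]
      events <- add_event("deletion", s, e, e - s + 1L,
                          .regions_spanned(model, s, e),
                          .exonic_overlap(model, s, e), "")
    }
  }
  # insertions
  if (nrow(map$insertions) > 0L) {
    for (k in seq_len(nrow(map$insertions))) {
      a <- map$insertions$ref_anchor[k]
      len <- map$insertions$length[k]
      reg <- if (a == 0L) region_of(model, 1L) else region_of(model, a)
      exonic <- if (grepl("^exon", reg)) len else 0L
      anchor <- max(a, 1L)
      events <- add_event("insertion", anchor, anchor, len, reg, exonic,
                          map$insertions$seq[k])
    }
  }
  # splice-border substitutions, read through the coordinate map
  if (nrow(borders) > 0L) {
    achars <- strsplit(allele, "")[[1]]
    for (k in seq_len(nrow(borders))) {
      p1 <- borders$p1[k]; p2 <- borders$p2[k]
      a1 <- map$ref_to_alt[p1]; a2 <- map$ref_to_alt[p2]
      if (is.na(a1) || is.na(a2)) next  # deleted border: covered by the indel
      obs <- paste0(achars[a1], achars[a2])
      i <- borders$intron[k]
      expected <- if (borders$role[k] == "donor") model$donor_expect[[i]] else
        model$acceptor_expect[[i]]
      if (!(obs %in% expected)) {
        kind <- if (borders$role[k] == "donor") "splice_donor_sub" else
          "splice_acceptor_sub"
        events <- add_event(kind, p1, p2, 2L, paste("intron", i), 0L, obs)
      }
    }
  }
  events[order(events$ref_start, events$kind, events$length, events$detail), ,
         drop = FALSE]
}

#' Call an allele functional or disabled
#'
#' An allele is functional iff it has no frame-shifting and no
#' splice-disrupting event, and its own spliced CDS (the reference model
#' projected through the alignment) starts with ATG, has length divisible
#' by three, translates without a premature stop, and yields the reference
#' protein length. Substitutions are tolerated; a nonsense point mutation
#' is caught here even though it is not an indel/splice event.
#'
#' @param allele DNA string.
#' @param events event data.frame from [scan_allele()].
#' @param reference reference DNA string.
#' @param model a `gene_model`.
#' @param reference_protein_len expected protein length (aa).
#' @param params an [align_params()].
#' @param aln optional precomputed left-normalized alignment.
#' @return list of class `functionality_call`: allele_id, status
#'   ("functional"/"disabled"), reasons (character vector, empty iff
#'   functional).
#' @export
call_functionality <- function(allele, events, reference, model,
                               reference_protein_len = 512L,
                               params = align_params(), aln = NULL) {
  reasons <- character(0)
  disabling <- events$frameshift | events$splice_disrupting
  if (any(disabling)) {
    reasons <- c(reasons, sprintf("%s at +%d", events$kind[disabling],
                                  events$ref_start[disabling]))
  }
  # ORF check on the allele's own spliced CDS (model projected through the
  # pairwise alignment; insertions anchored inside exons are included)
  cds <- project_and_splice(allele, reference, model, params, aln = aln)
  tr <- translate_cds(cds)
  if (!tr$starts_with_atg) reasons <- c(reasons, "no_atg_start")
  if (tr$length_mod3 != 0L) reasons <- c(reasons, "length_not_multiple_of_3")
  if (tr$premature_stop) reasons <- c(reasons, "premature_stop")
  if (!tr$premature_stop && tr$length_mod3 == 0L &&
      nchar(tr$protein) != reference_protein_len) {
    reasons <- c(reasons, sprintf("protein_length_%d", nchar(tr$protein)))
  }
  status <- if (length(reasons) == 0L) "functional" else "disabled"
  structure(list(allele_id = events$allele_id[1] %||% "allele",
                 status = status, reasons = unique(reasons)),
            class = "functionality_call")
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a

#' Project the reference gene model onto an allele and splice it
#'
#' Exon intervals are carried through the (left-normalized) pairwise
#' alignment: each exon becomes the allele bases aligned to its reference
#' positions, plus any insertion anchored strictly inside the exon.
#'
#' @inheritParams call_functionality
#' @return the allele's spliced CDS as a DNA string.
#' @export
project_and_splice <- function(allele, reference, model, params = align_params(),
                               aln = NULL) {
  if (is.null(aln)) aln <- left_normalize(global_align(reference, allele, params))
  map <- build_map(aln)
  achars <- strsplit(allele, "")[[1]]
  pieces <- character(nrow(model$exons))
  for (k in seq_len(nrow(model$exons))) {
    s <- model$exons$start[k]; e <- model$exons$end[k]
    alt_idx <- map$ref_to_alt[s:e]
    alt_idx <- alt_idx[!is.na(alt_idx)]
    seg <- achars[alt_idx]
    ins <- map$insertions[map$insertions$ref_anchor >= s &
                          map$insertions$ref_anchor < e, , drop = FALSE]
    if (nrow(ins) > 0L && length(alt_idx) > 0L) {
      # contiguous allele span from first to last exon-aligned base picks
      # up insertions anchored strictly inside the exon
      pieces[k] <- paste(achars[alt_idx[1]:alt_idx[length(alt_idx)]],
                         collapse = "")
    } else {
      pieces[k] <- paste(seg, collapse = "")
    }
  }
  paste(pieces, collapse = "")
}

#' Build the mutation-type catalogue across alleles
#'
#' Events with identical keys (kind, ref_start, ref_end, length, detail)
#' across alleles are one type. Type ids ("Mu1", "Mu2", ...) are assigned in
#' ascending ref_start order, ties broken by kind, then length, then detail.
#'
#' @param events data.frame of events pooled across alleles (all scanned
#'   against the same reference).
#' @return data.frame: mu_id, kind, ref_start, ref_end, length, regions,
#'   exonic_bases, frameshift, splice_disrupting, detail, frequency.
#' @export
build_catalogue <- function(events) {
  if (nrow(events) == 0L) {
    out <- .empty_events()
    out$allele_id <- NULL
    out$mu_id <- character(0); out$frequency <- integer(0)
    return(out)
  }
  key <- paste(events$kind, events$ref_start, events$ref_end, events$length,
               events$detail, sep = "|")
  first <- !duplicated(key)
  types <- events[first, setdiff(names(events), "allele_id"), drop = FALSE]
  types$frequency <- as.integer(table(key)[key[first]])
  ord <- order(types$ref_start, types$kind, types$length, types$detail)
  types <- types[ord, , drop = FALSE]
  types$mu_id <- paste0("Mu", seq_len(nrow(types)))
  rownames(types) <- NULL
  types[, c("mu_id", "kind", "ref_start", "ref_end", "length", "regions",
            "exonic_bases", "frameshift", "splice_disrupting", "detail",
            "frequency")]
}

# key of an event / catalogue row for identity tests
.event_key <- function(d) {
  paste(d$kind, d$ref_start, d$ref_end, d$length, d$detail, sep = "|")
}

#' Build the allele x mutation-type matrix
#'
#' Cells are "+" (type present), "-" (absent) or "N/A" when the allele
#' carries a larger deletion spanning the type's locus, so presence of that
#' type cannot be assessed. A functionality column is appended.
#'
#' @param events pooled event data.frame (with allele_id).
#' @param catalogue from [build_catalogue()].
#' @param calls named list of `functionality_call`s (or a named character
#'   vector of statuses), one per allele.
#' @param allele_ids row order; defaults to names of `calls`.
#' @return data.frame, one row per allele: allele_id, one column per mu_id,
#'   functionality.
#' @export
build_matrix <- function(events, catalogue, calls, allele_ids = NULL) {
  statuses <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$status, character(1))
  if (is.null(allele_ids)) allele_ids <- names(statuses)
  ckey <- .event_key(catalogue)
  m <- matrix("-", nrow = length(allele_ids), ncol = nrow(catalogue),
              dimnames = list(allele_ids, catalogue$mu_id))
  for (id in allele_ids) {
    ev <- events[events$allele_id == id, , drop = FALSE]
    if (nrow(ev) == 0L) next
    ekey <- .event_key(ev)
    m[id, ckey %in% ekey] <- "+"
    # spanning deletions mask other types' loci
    dels <- ev[ev$kind == "deletion", , drop = FALSE]
    for (j in seq_len(nrow(catalogue))) {
      if (m[id, j] == "+") next
      spanned <- nrow(dels) > 0L &&
        any(dels$ref_start <= catalogue$ref_start[j] &
            dels$ref_end >= catalogue$ref_end[j])
      if (spanned) m[id, j] <- "N/A"
    }
  }
  out <- data.frame(allele_id = allele_ids, m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$functionality <- unname(statuses[allele_ids])
  rownames(out) <- NULL
  out
}

#' Summarize a mutation matrix
#'
#' @param matrix data.frame from [build_matrix()] (or an equivalently shaped
#'   published table: allele_id, Mu columns with +/-/N/A, functionality).
#' @param catalogue catalogue giving each type's locus (mu_id, ref_start,
#'   ref_end); required for `region` counting.
#' @param region optional `c(start, end)` reference window; type
#'   occurrences whose locus intersects it are counted (e.g. the 3' border
#'   region of intron 10, a frame-shift hot spot).
#' @return list: n_alleles, n_functional, n_disabled, n_types, frequency
#'   (named integer per type), events_in_region (NA if no region given).
#' @export
summarize_matrix <- function(matrix, catalogue = NULL, region = NULL) {
  mu_cols <- setdiff(names(matrix), c("allele_id", "functionality"))
  pres <- as.matrix(matrix[, mu_cols, drop = FALSE]) == "+"
  freq <- colSums(pres)
  events_in_region <- NA_integer_
  if (!is.null(region)) {
    if (is.null(catalogue)) stop("region counting needs a catalogue", call. = FALSE)
    loc <- catalogue[match(mu_cols, catalogue$mu_id), , drop = FALSE]
    in_region <- !is.na(loc$ref_start) &
      loc$ref_start <= region[2] & loc$ref_end >= region[1]
    events_in_region <- sum(pres[, in_region, drop = FALSE])
  }
  list(n_alleles = nrow(matrix),
       n_functional = sum(matrix$functionality == "functional"),
       n_disabled = sum(matrix$functionality == "disabled"),
       n_types = length(mu_cols),
       frequency = setNames(as.integer(freq), mu_cols),
       events_in_region = as.integer(events_in_region))
}

#' Scan a whole allele set
#'
#' Convenience pipeline: scan every allele, call functionality, build the
#' catalogue (ids reassigned across the pooled events) and the matrix.
#'
#' @param alleles named character vector of allele sequences.
#' @param reference reference DNA string.
#' @param model a `gene_model`.
#' @param reference_protein_len expected protein length.
#' @param params an [align_params()].
#' @return list: events, catalogue, calls (named list), matrix.
#' @export
scan_alleles <- function(alleles, reference, model,
                         reference_protein_len = 512L,
                         params = align_params()) {
  all_events <- .empty_events()
  calls <- list()
  for (id in names(alleles)) {
    aln <- left_normalize(global_align(reference, alleles[[id]], params))
    ev <- scan_allele(alleles[[id]], reference, model, allele_id = id,
                      params = params, aln = aln)
    all_events <- rbind(all_events, ev)
    calls[[id]] <- call_functionality(alleles[[id]], ev, reference, model,
                                      reference_protein_len, params, aln = aln)
    calls[[id]]$allele_id <- id
  }
  catalogue <- build_catalogue(all_events)
  mat <- build_matrix(all_events, catalogue, calls, allele_ids = names(alleles))
  list(events = all_events, catalogue = catalogue, calls = calls, matrix = mat)
}
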