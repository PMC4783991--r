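#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.delim write.table
NULL

# Sequences are represented throughout as named character strings over
# {A,C,G,T,N} (uppercase); names are record ids. Gapped alignment rows
# additionally use "-".

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Normalize a DNA string
#'
#' Uppercases, maps U to T, and validates that only A/C/G/T/N remain.
#'
#' @param seq character scalar.
#' @param id record id used in error messages.
#' @return normalized character scalar.
#' @keywords internal
normalize_dna <- function(seq, id = "<seq>") {
  s <- chartr("u", "U", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), .DNA_ALPHABET)
  if (length(bad) > 0) {
    stop(sprintf("sequence '%s' contains invalid characters: %s",
                 id, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nchar(s) == 0L) stop(sprintf("sequence '%s' is empty", id), call. = FALSE)
  s
}

#' Read a multi-record FASTA file
#'
#' Records are returned in file order as a named character vector of
#' uppercase DNA strings (U mapped to T). The full description line is kept
#' in the \code{"descriptions"} attribute; names are the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file.
#' @return named character vector of DNA sequences.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "acgt"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  if (length(set) == 0L) stop("FASTA file has no records: ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[`, character(1), 1L)
  if (any(is.na(ids)) || any(ids == "")) {
    stop("FASTA record with empty id in ", path, call. = FALSE)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i) normalize_dna(seqs[[i]], ids[[i]]),
                character(1))
  names(out) <- ids
  attr(out, "descriptions") <- setNames(headers, ids)
  out
}

#' Write sequences to FASTA
#'
#' @param records named character vector of DNA (or gapped DNA) strings.
#' @param path output path.
#' @param width line-wrap width (bases per line).
#' @return invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (length(records) > 0 && (is.null(names(records)) || any(names(records) == ""))) {
    stop("all records must be named", call. = FALSE)
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a gene-model TSV
#'
#' Expects a header line `exon_index<TAB>start<TAB>end` with 1-based
#' inclusive exon intervals in reference coordinates, and returns a
#' [gene_model()] with introns derived as the gaps between consecutive
#' exons (donor GT everywhere except intron 10 which also allows GC;
#' acceptor AG everywhere, unless overridden via ...).
#'
#' @param path path to the TSV.
#' @param ... passed to [gene_model()] (e.g. `gc_donor_introns`).
#' @return a `gene_model` object.
#' @export
read_gene_model <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("exon_index", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene-model TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[order(tab$exon_index), , drop = FALSE]
  gene_model(starts = as.integer(tab$start), ends = as.integer(tab$end), ...)
}

#' Write a gene model as TSV
#'
#' @param model a `gene_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gene_model <- function(model, path) {
  stopifnot(inherits(model, "gene_model"))
  tab <- data.frame(exon_index = seq_len(nrow(model$exons)),
                    start = model$exons$start, end = model$exons$end)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
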