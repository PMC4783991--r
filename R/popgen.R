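# Population-diversity statistics on a gapped multiple alignment, with
# partitioning by exon/intron and by allele functionality.
#
# Site-filtering convention ("complete deletion", the common DnaSP
# default): segregating sites, pi, theta_w and haplotype identity are
# computed on columns free of gaps and of N in every row; indel sites are
# counted on all columns (a column with >= 1 gap is one indel site).
# Per-kb densities divide by the TOTAL aligned length.

.aln_matrix <- function(aln) {
  if (length(aln) < 2L) stop("alignment needs >= 2 rows", call. = FALSE)
  if (length(unique(nchar(aln))) != 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(aln, ""))
  rownames(m) <- names(aln)
  m
}

.clean_columns <- function(m) {
  ok <- colSums(m == "-" | m == "N") == 0L
  ok
}

#' Segregating sites, indel sites and comparable length
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return list: S (segregating sites among gap-free, N-free columns),
#'   indel_sites (columns containing >= 1 gap), L_ungapped (gap-free,
#'   N-free columns), L_total.
#' @export
segregating_and_indel_sites <- function(aln) {
  m <- .aln_matrix(aln)
  clean <- .clean_columns(m)
  n_var <- sum(apply(m[, clean, drop = FALSE], 2,
                     function(col) length(unique(col)) > 1L))
  list(S = as.integer(n_var),
       indel_sites = as.integer(sum(colSums(m == "-") > 0L)),
       L_ungapped = as.integer(sum(clean)),
       L_total = ncol(m))
}

#' Haplotype diversity
#'
#' Hd = n(1 - sum x_i^2)/(n - 1) over haplotype frequencies x_i, with
#' haplotypes defined on gap-free, N-free columns. The sampling variance is
#' Nei's (1987, eq. 8.12):
#' V = 2/(n(n-1)) * (2(n-2)(sum x^3 - (sum x^2)^2) + sum x^2 - (sum x^2)^2).
#'
#' @param aln gapped alignment (named character vector).
#' @return list: hd, sd. Both NA if no comparable columns remain.
#' @export
haplotype_diversity <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  clean <- .clean_columns(m)
  if (sum(clean) == 0L) return(list(hd = NA_real_, sd = NA_real_))
  hap <- apply(m[, clean, drop = FALSE], 1, paste, collapse = "")
  x <- as.numeric(table(hap)) / n
  s2 <- sum(x^2); s3 <- sum(x^3)
  hd <- n * (1 - s2) / (n - 1)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  list(hd = hd, sd = sqrt(max(v, 0)))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all sequence pairs of the proportion of differing gap-free,
#' N-free columns. The sampling variance is Nei's (1987, eq. 10.7):
#' V = (n+1) pi / (3(n-1) L) + 2 (n^2 + n + 3) pi^2 / (9 n (n-1)).
#'
#' @param aln gapped alignment.
#' @return list: pi, sd.
#' @export
nucleotide_diversity <- function(aln) {
  m <- .aln_matrix(aln)
  n <- nrow(m)
  clean <- .clean_columns(m)
  L <- sum(clean)
  if (L == 0L) return(list(pi = NA_real_, sd = NA_real_))
  mc <- m[, clean, drop = FALSE]
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(mc[i, ] != mc[j, ])
    }
  }
  pi <- tot / choose(n, 2) / L
  v <- (n + 1) * pi / (3 * (n - 1) * L) +
    2 * (n^2 + n + 3) * pi^2 / (9 * n * (n - 1))
  list(pi = pi, sd = sqrt(max(v, 0)))
}

#' Watterson's theta per site
#'
#' theta_w = S / (a_n * L) with a_n = sum_{i=1}^{n-1} 1/i, on gap-free,
#' N-free columns. SD from Watterson's (1975) variance of S:
#' Var(S) = a_n * theta * L + b_n * (theta * L)^2 with
#' b_n = sum_{i=1}^{n-1} 1/i^2, so Var(theta_hat) = Var(S)/(a_n L)^2.
#'
#' @param aln gapped alignment.
#' @return list: theta_w, sd, S, L.
#' @export
watterson_theta <- function(aln) {
  s <- segregating_and_indel_sites(aln)
  n <- length(aln)
  L <- s$L_ungapped
  if (L == 0L) return(list(theta_w = NA_real_, sd = NA_real_, S = s$S, L = L))
  a_n <- sum(1 / seq_len(n - 1L))
  b_n <- sum(1 / seq_len(n - 1L)^2)
  theta <- s$S / (a_n * L)
  theta_abs <- theta * L
  v_s <- a_n * theta_abs + b_n * theta_abs^2
  list(theta_w = theta, sd = sqrt(v_s) / (a_n * L), S = s$S, L = L)
}

#' Partition an alignment into exonic and intronic sub-alignments
#'
#' The gene model (in reference coordinates) is projected through the
#' reference row's gaps. Insertion columns (gap in the reference row)
#' inherit the region of the left flanking reference base; insertion
#' columns before the first reference base go with its region. The two
#' column sets partition the alignment columns.
#'
#' @param aln gapped alignment containing the reference row.
#' @param model a `gene_model`.
#' @param ref_id name of the reference row.
#' @return list of two gapped alignments: `exons`, `introns` (either may
#'   have zero columns, returned as empty strings).
#' @export
partition_alignment <- function(aln, model, ref_id) {
  if (!(ref_id %in% names(aln))) {
    stop("reference row '", ref_id, "' not in alignment", call. = FALSE)
  }
  m <- .aln_matrix(aln)
  refrow <- m[ref_id, ]
  ref_pos <- cumsum(refrow != "-")
  ref_pos[ref_pos == 0L] <- 1L  # leading insertion columns
  labels <- region_of(model, ref_pos)
  is_exon <- grepl("^exon", labels)
  sub <- function(keep) {
    vapply(seq_len(nrow(m)), function(i) paste(m[i, keep], collapse = ""),
           character(1)) |> setNames(rownames(m))
  }
  list(exons = sub(is_exon), introns = sub(!is_exon))
}

#' Subset alignment rows by functionality
#'
#' @param aln gapped alignment.
#' @param calls named list of `functionality_call`s or named character
#'   vector of statuses.
#' @param status "functional" or "disabled".
#' @return gapped alignment with matching rows; warns and returns NULL if
#'   fewer than 2 rows match.
#' @export
subset_rows <- function(aln, calls, status) {
  statuses <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$status, character(1))
  keep <- names(aln)[names(aln) %in% names(statuses)[statuses == status]]
  if (length(keep) < 2L) {
    warning("fewer than 2 rows with status '", status, "'; no report")
    return(NULL)
  }
  aln[keep]
}

#' Assemble a diversity report for one partition
#'
#' @param aln gapped alignment.
#' @param label partition label for the report row.
#' @return one-row data.frame: label, n, L_total, L_ungapped, S,
#'   indel_sites, hd, hd_sd, pi, pi_sd, theta_w, theta_sd, snp_per_kb,
#'   indel_per_kb, pct_identity. Densities are per kb of total aligned
#'   length; pct_identity is the mean pairwise percent identity over
#'   gap-free, N-free columns.
#' @export
diversity_report <- function(aln, label = "alignment") {
  s <- segregating_and_indel_sites(aln)
  hd <- haplotype_diversity(aln)
  pi <- nucleotide_diversity(aln)
  th <- watterson_theta(aln)
  pct <- if (is.na(pi$pi)) NA_real_ else 100 * (1 - pi$pi)
  data.frame(label = label, n = length(aln),
             L_total = s$L_total, L_ungapped = s$L_ungapped,
             S = s$S, indel_sites = s$indel_sites,
             hd = hd$hd, hd_sd = hd$sd, pi = pi$pi, pi_sd = pi$sd,
             theta_w = th$theta_w, theta_sd = th$sd,
             snp_per_kb = 1000 * s$S / s$L_total,
             indel_per_kb = 1000 * s$indel_sites / s$L_total,
             pct_identity = pct,
             stringsAsFactors = FALSE)
}

#' Five-partition diversity report
#'
#' The standard layout for this analysis: whole genomic alignment, exons,
#' introns, functional alleles, disabled alleles. The reference row is used
#' for partitioning only and is excluded from all statistics.
#'
#' @param aln gapped alignment including the reference row.
#' @param model a `gene_model`.
#' @param ref_id reference row name.
#' @param calls functionality calls for the non-reference rows.
#' @return data.frame with up to five rows (a functionality partition with
#'   fewer than two alleles is dropped with a warning).
#' @export
diversity_report_partitions <- function(aln, model, ref_id, calls) {
  parts <- partition_alignment(aln, model, ref_id)
  drop_ref <- function(a) a[setdiff(names(a), ref_id)]
  reports <- list(diversity_report(drop_ref(aln), "genomic"))
  if (nchar(parts$exons[1]) > 0) {
    reports <- c(reports, list(diversity_report(drop_ref(parts$exons), "exons")))
  }
  if (nchar(parts$introns[1]) > 0) {
    reports <- c(reports, list(diversity_report(drop_ref(parts$introns), "introns")))
  }
  for (st in c("functional", "disabled")) {
    sub <- subset_rows(drop_ref(aln), calls, st)
    if (!is.null(sub)) {
      reports <- c(reports, list(diversity_report(sub, st)))
    }
  }
  do.call(rbind, reports)
}
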