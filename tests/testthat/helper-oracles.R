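# Independent oracles and small generators used across the suite.
# These deliberately re-derive quantities by the most direct route
# (enumeration, all-pairs loops, closed forms) rather than calling the
# package's optimized paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# random gapped alignment: start from a core sequence, mutate and poke gaps
rand_alignment <- function(n_rows, L, gap_prob = 0.05, sub_prob = 0.1,
                           n_prob = 0) {
  core <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- vapply(seq_len(n_rows), function(i) {
    r <- core
    sub <- runif(L) < sub_prob
    r[sub] <- sample(c("A", "C", "G", "T"), sum(sub), replace = TRUE)
    gap <- runif(L) < gap_prob
    r[gap] <- "-"
    if (n_prob > 0) {
      nn <- runif(L) < n_prob
      r[nn & r != "-"] <- "N"
    }
    paste(r, collapse = "")
  }, character(1))
  setNames(rows, paste0("r", seq_len(n_rows)))
}

# ---- popgen oracles (all-pairs / direct formula) ----

oracle_clean_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unname(aln), ""))
  keep <- apply(m, 2, function(col) all(col != "-" & col != "N"))
  m[, keep, drop = FALSE]
}

oracle_pi <- function(aln) {
  m <- oracle_clean_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  if (L == 0) return(NA_real_)
  tot <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(m[i, ] != m[j, ]); np <- np + 1
  }
  tot / np
}

oracle_hd <- function(aln) {
  m <- oracle_clean_matrix(aln)
  n <- nrow(m)
  if (ncol(m) == 0) return(NA_real_)
  hap <- apply(m, 1, paste, collapse = "")
  x <- as.numeric(table(hap)) / n
  n * (1 - sum(x^2)) / (n - 1)
}

oracle_theta_w <- function(aln) {
  m <- oracle_clean_matrix(aln)
  n <- nrow(m); L <- ncol(m)
  if (L == 0) return(NA_real_)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * L)
}

# ---- exhaustive affine-gap global alignment (enumeration, not DP) ----
# Enumerates every monotone alignment path and scores it with
# gap cost = open + extend * run_length. Exponential; lengths <= 8 only.

oracle_align_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  nx <- length(x); ny <- length(y)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > nx && j > ny) { best <<- max(best, sc); return(invisible()) }
    if (i <= nx && j <= ny) {
      rec(i + 1, j + 1, "M",
          sc + if (x[i] == y[j]) match else mismatch)
    }
    if (i <= nx) {  # consume x against a gap in y
      rec(i + 1, j, "X",
          sc - gap_extend - if (prev == "X") 0 else gap_open)
    }
    if (j <= ny) {
      rec(i, j + 1, "Y",
          sc - gap_extend - if (prev == "Y") 0 else gap_open)
    }
  }
  rec(1L, 1L, "S", 0)
  best
}

# ---- additive distances from a random binary tree (for NJ recovery) ----

rand_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) runif(k, 0.05, 0.6))
  tr <- ape::unroot(tr)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}

# ---- shared simulated dataset (built once per test run) ----

sim_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 20260922L)
      ref <- make_reference(cfg)
      dist <- published_distribution()
      sim <- simulate_alleles(ref$reference, ref$model, cfg,
                              plan = distribution_plan(dist),
                              allele_ids = dist$allele_id)
      scan <- scan_alleles(sim$alleles, ref$reference, ref$model)
      cache <<- list(cfg = cfg, ref = ref, sim = sim, scan = scan)
    }
    cache
  }
})

# catalogue entry for a nonsense point mutation: the first single-base
# change in codons 30..150 that creates an in-frame stop at least 3 bases
# inside its exon
nonsense_entry <- function(ref) {
  m <- ref$model
  cds <- ref$cdna
  cum <- cumsum(m$exons$end - m$exons$start + 1L)
  for (ci in 30:150) {
    codon <- substring(cds, 3 * ci - 2L, 3 * ci)
    for (pos_in in 1:3) {
      for (b in c("A", "G", "T")) {
        if (substr(codon, pos_in, pos_in) == b) next
        new <- codon
        substr(new, pos_in, pos_in) <- b
        if (!(new %in% c("TAA", "TAG", "TGA"))) next
        cds_pos <- 3L * ci - 3L + pos_in
        k <- which(cds_pos <= cum)[1]
        off <- cds_pos - c(0L, cum)[k]
        gpos <- m$exons$start[k] + off - 1L
        if (gpos >= m$exons$start[k] + 3L && gpos <= m$exons$end[k] - 3L) {
          return(data.frame(mu_id = "MuX", kind = "nonsense_sub",
                            ref_start = gpos, ref_end = gpos, length = 1L,
                            detail = b, stringsAsFactors = FALSE))
        }
      }
    }
  }
  stop("no nonsense site found in the reference")
}
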