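test_that("site counting distinguishes SNP columns from indel columns", {
  two <- c(a = "ACGT", b = "ACGT")
  s0 <- segregating_and_indel_sites(two)
  expect_identical(c(s0$S, s0$indel_sites, s0$L_ungapped), c(0L, 0L, 4L))

  s1 <- segregating_and_indel_sites(c(a = "ACGT", b = "ACCT"))
  expect_identical(s1$S, 1L)

  s2 <- segregating_and_indel_sites(c(a = "AC-T", b = "ACGT", c = "ACGA"))
  expect_identical(s2$indel_sites, 1L)
  expect_identical(s2$S, 1L)          # column 4 varies; column 3 is masked
  expect_identical(s2$L_ungapped, 3L)

  expect_error(segregating_and_indel_sites(c(a = "ACGT")), ">= 2 rows")
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(c(a = "AAAA", b = "AAAA", c = "AAAA"))$hd, 0)
  expect_equal(haplotype_diversity(c(a = "AAAA", b = "AAAT"))$hd, 1)
  # the published 29-allele haplotype partition {4,3,2,2, 18 singletons}
  sizes <- c(4, 3, 2, 2, rep(1, 18))
  n <- sum(sizes)
  x <- sizes / n
  hd <- n * (1 - sum(x^2)) / (n - 1)
  expect_equal(round(hd, 3), 0.973)
})

test_that("diversity statistics match brute-force oracles to 1e-12", {
  set.seed(501)
  for (case in 1:60) {
    n <- sample(2:12, 1)
    L <- sample(20:300, 1)
    aln <- rand_alignment(n, L, gap_prob = runif(1, 0, 0.1),
                          sub_prob = runif(1, 0, 0.3),
                          n_prob = sample(c(0, 0.02), 1))
    if (segregating_and_indel_sites(aln)$L_ungapped == 0) next
    expect_equal(nucleotide_diversity(aln)$pi, oracle_pi(aln),
                 tolerance = 1e-12)
    expect_equal(haplotype_diversity(aln)$hd, oracle_hd(aln),
                 tolerance = 1e-12)
    expect_equal(watterson_theta(aln)$theta_w, oracle_theta_w(aln),
                 tolerance = 1e-12)
  }
})

test_that("Watterson estimator handles the closed-form small cases", {
  # n = 2, S = 1, L = 100: a_1 = 1 so theta = 0.01
  aln2 <- c(a = paste0("A", strrep("C", 99)), b = strrep("C", 100))
  th <- watterson_theta(aln2)
  expect_equal(th$theta_w, 0.01)
  # n = 4 with S = 5 over L = 100: theta = 5 / ((1 + 1/2 + 1/3) * 100)
  base <- strrep("A", 100)
  rows <- c(base, base, base, base)
  for (p in 1:5) substr(rows[2], p, p) <- "G"
  aln4 <- setNames(rows, paste0("r", 1:4))
  expect_equal(watterson_theta(aln4)$theta_w, 5 / ((1 + 1/2 + 1/3) * 100))
  # S = 0 -> zero estimate, zero SD
  th0 <- watterson_theta(c(a = "ACGT", b = "ACGT"))
  expect_identical(c(th0$theta_w, th0$sd), c(0, 0))
})

test_that("pi and Hd are invariant to permutations; Hd never grows with a duplicate", {
  set.seed(502)
  aln <- rand_alignment(8, 120, gap_prob = 0.03, sub_prob = 0.2)
  perm <- sample(seq_along(aln))
  expect_equal(haplotype_diversity(aln[perm])$hd, haplotype_diversity(aln)$hd)
  # column permutation leaves pi and theta unchanged
  m <- do.call(rbind, strsplit(unname(aln), ""))
  cp <- sample(ncol(m))
  aln_cp <- setNames(apply(m[, cp], 1, paste, collapse = ""), names(aln))
  expect_equal(nucleotide_diversity(aln_cp)$pi, nucleotide_diversity(aln)$pi)
  expect_equal(watterson_theta(aln_cp)$theta_w, watterson_theta(aln)$theta_w)
  # duplicating an existing row cannot increase Hd
  for (k in 1:5) {
    dup <- c(aln, setNames(aln[sample(length(aln), 1)], "dup"))
    expect_lte(haplotype_diversity(dup)$hd, haplotype_diversity(aln)$hd + 1e-12)
  }
})

test_that("alignment partitioning projects the model through reference gaps", {
  # single-exon model: everything is exonic
  aln1 <- c(ref = "ACGTACGT", s1 = "ACGTACGA")
  p1 <- partition_alignment(aln1, gene_model(1, 8), "ref")
  expect_identical(p1$exons, aln1)
  expect_identical(nchar(p1$introns[[1]]), 0L)

  # simulated gene with insertions: column counts partition L_total
  cfg <- sim_config(seed = 41)
  ref <- make_reference(cfg)
  sim <- simulate_alleles(ref$reference, ref$model, cfg,
                          plan = data.frame(allele_id = c("a", "b"),
                                            mu_id = c("Mu1", "Mu6")),
                          allele_ids = c("a", "b", "c"))
  aln <- merge_alignments(sim$alleles, ref$reference, ref_id = "REF")
  parts <- partition_alignment(aln, ref$model, "REF")
  expect_identical(nchar(parts$exons[[1]]) + nchar(parts$introns[[1]]),
                   nchar(aln[[1]]))
  # with no insertions the exon part is exactly the exonic length
  aln0 <- merge_alignments(sim$alleles["c"], ref$reference, ref_id = "REF")
  parts0 <- partition_alignment(aln0, ref$model, "REF")
  expect_identical(nchar(parts0$exons[[1]]),
                   unname(model_lengths(ref$model)["exonic"]))
  expect_error(partition_alignment(aln, ref$model, "nope"), "not in alignment")
})

test_that("row subsetting by functionality enforces the n >= 2 rule", {
  aln <- c(a = "ACGT", b = "ACGA", c = "ACGG", d = "ACGC")
  calls <- c(a = "functional", b = "functional", c = "disabled", d = "disabled")
  expect_identical(names(subset_rows(aln, calls, "functional")), c("a", "b"))
  calls2 <- c(a = "functional", b = "disabled", c = "disabled", d = "disabled")
  expect_warning(out <- subset_rows(aln, calls2, "functional"), "fewer than 2")
  expect_null(out)
})

test_that("diversity reports assemble coherent statistics", {
  ident <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  rep0 <- diversity_report(ident, "identical")
  expect_equal(rep0$hd, 0)
  expect_equal(rep0$pi, 0)
  expect_equal(rep0$theta_w, 0)
  expect_equal(rep0$pct_identity, 100)
  expect_equal(rep0$snp_per_kb, 0)

  # five-partition layout over a simulated population
  fx <- sim_fixture()
  aln <- merge_alignments(fx$sim$alleles, fx$ref$reference, ref_id = "REF")
  reps <- diversity_report_partitions(aln, fx$ref$model, "REF", fx$scan$calls)
  expect_identical(reps$label,
                   c("genomic", "exons", "introns", "functional", "disabled"))
  expect_identical(reps$n, c(29L, 29L, 29L, 10L, 19L))
  expect_true(all(reps$hd >= 0 & reps$hd <= 1))
  expect_true(all(reps$S <= reps$L_ungapped))
})

test_that("simulated neutral diversity matches the mutation-model expectation", {
  # two alleles differ at a site when exactly one mutated (2r(1-r)) or both
  # mutated to different bases (r^2 * 2/3)
  r <- 0.0075
  # 54 of the 2559 sites (12 x 4 border bases, start codon, terminal stop)
  # never receive neutral substitutions
  expected <- (2 * r * (1 - r) + r^2 * 2 / 3) * (2559 - 54) / 2559
  pis <- vapply(1:20, function(seed) {
    cfg <- sim_config(seed = 6000 + seed, snp_rate = r)
    ref <- make_reference(cfg)
    sim <- simulate_alleles(ref$reference, ref$model, cfg, plan = NULL,
                            allele_ids = paste0("s", 1:6))
    nucleotide_diversity(sim$alleles)$pi
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - expected), 3 * se)
})
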