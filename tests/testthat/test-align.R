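test_that("global alignment handles identity and single indels", {
  p <- align_params()
  a <- global_align("ACGT", "ACGT", p)
  expect_identical(a$ref, "ACGT")
  expect_identical(a$alt, "ACGT")
  expect_equal(a$score, 4 * p$match)

  d <- global_align("ACGT", "AGT", p)
  expect_equal(d$score, 3 * p$match - p$gap_open - p$gap_extend)
  expect_identical(nchar(d$ref), 4L)
  expect_identical(gsub("-", "", d$alt), "AGT")
  expect_error(global_align("", "A"), "non-empty")
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  set.seed(401)
  grids <- list(align_params(),
                align_params(match = 2, mismatch = -3, gap_open = 4,
                             gap_extend = 2))
  cases <- c(list(c("ACGTACGT", "AGTTACG")),  # fixed 8x7 case
             lapply(1:10, function(i) {
               c(rand_dna(sample(2:8, 1)), rand_dna(sample(2:8, 1)))
             }))
  for (p in grids) {
    for (cs in cases) {
      got <- global_align(cs[1], cs[2], p)$score
      want <- oracle_align_score(cs[1], cs[2], p$match, p$mismatch,
                                 p$gap_open, p$gap_extend)
      expect_equal(got, want, info = paste(cs, collapse = " vs "))
    }
  }
})

test_that("left normalization shifts gaps maximally left and is idempotent", {
  p <- align_params()
  # homopolymer deletion: all placements equivalent; must settle leftmost
  aln <- structure(list(ref = "GAAAAC", alt = "GAA-AC", score = 0, params = p),
                   class = "pairwise_alignment")
  n1 <- left_normalize(aln)
  expect_identical(n1$alt, "G-AAAC")
  expect_identical(left_normalize(n1)$alt, n1$alt)  # idempotent

  # insertion in a repeat: every phase-aligned placement yields the same
  # sequence and must normalize to the same (leftmost) columns
  ref <- "TTACACACGG"
  for (cut in c(2, 4, 6, 8)) {
    alt <- paste0(substr(ref, 1, cut), "AC", substr(ref, cut + 1, 10))
    nn <- left_normalize(global_align(ref, alt, p))
    m <- build_map(nn)
    expect_identical(nrow(m$insertions), 1L)
    expect_identical(m$insertions$ref_anchor, 2L)  # leftmost: after TT
  }
})

test_that("left normalization preserves score and sequences", {
  set.seed(402)
  p <- align_params()
  rescore <- function(aln) {
    r <- strsplit(aln$ref, "")[[1]]; a <- strsplit(aln$alt, "")[[1]]
    sc <- 0; prev <- "S"
    for (k in seq_along(r)) {
      if (r[k] != "-" && a[k] != "-") {
        sc <- sc + if (r[k] == a[k]) p$match else p$mismatch
        prev <- "M"
      } else {
        cur <- if (r[k] == "-") "I" else "D"
        sc <- sc - p$gap_extend - if (prev == cur) 0 else p$gap_open
        prev <- cur
      }
    }
    sc
  }
  for (i in 1:20) {
    ref <- rand_dna(120)
    # derive alt by random indels + substitutions
    a <- strsplit(ref, "")[[1]]
    cut <- sort(sample(20:100, 2))
    a <- a[-(cut[1]:(cut[1] + sample(1:6, 1)))]
    alt <- paste(a, collapse = "")
    aln <- global_align(ref, alt, p)
    nn <- left_normalize(aln)
    expect_identical(gsub("-", "", nn$ref), ref)
    expect_identical(gsub("-", "", nn$alt), alt)
    expect_equal(rescore(nn), aln$score)
  }
})

test_that("coordinate maps are total, monotone and key indels correctly", {
  p <- align_params()
  # identity
  m <- build_map(global_align("ACGTT", "ACGTT", p))
  expect_identical(m$ref_to_alt, 1:5)
  expect_identical(nrow(m$insertions), 0L)

  # a deletion marks exactly the removed reference span
  ref <- rand_dna(3000)
  alt <- paste0(substr(ref, 1, 2110), substr(ref, 2128, 3000))
  mm <- build_map(left_normalize(global_align(ref, alt, p)))
  deleted <- which(is.na(mm$ref_to_alt))
  expect_identical(range(deleted), c(2111L, 2127L))

  # insertion keyed to the reference base left of the inserted material
  set.seed(7)
  ref2 <- rand_dna(400)
  ins <- "CA"
  # guard against homopolymer drift in this random context
  while (substr(ref2, 155, 155) == substr(ins, 2, 2)) ref2 <- rand_dna(400)
  alt2 <- paste0(substr(ref2, 1, 155), ins, substr(ref2, 156, 400))
  m2 <- build_map(left_normalize(global_align(ref2, alt2, p)))
  expect_identical(nrow(m2$insertions), 1L)
  expect_lte(m2$insertions$ref_anchor, 155L)  # leftmost-equivalent anchor
  expect_identical(m2$insertions$length, 2L)

  # monotone over random pairs
  for (i in 1:10) {
    r <- rand_dna(150); a <- rand_dna(sample(120:180, 1))
    mp <- build_map(left_normalize(global_align(r, a, p)))
    expect_identical(length(mp$ref_to_alt), 150L)
    expect_false(is.unsorted(mp$ref_to_alt, na.rm = TRUE))
  }
})

test_that("reference-anchored merge yields a consistent multiple alignment", {
  set.seed(403)
  cfg <- sim_config(seed = 31)
  ref <- make_reference(cfg)
  sim <- simulate_alleles(ref$reference, ref$model, cfg, plan = NULL,
                          allele_ids = paste0("s", 1:5))
  aln <- merge_alignments(sim$alleles, ref$reference, ref_id = "ref")
  expect_identical(length(aln), 6L)
  expect_identical(length(unique(nchar(aln))), 1L)
  expect_identical(gsub("-", "", aln[["ref"]]), ref$reference)
  for (id in names(sim$alleles)) {
    expect_identical(gsub("-", "", aln[[id]]), unname(sim$alleles[[id]]))
  }
})
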