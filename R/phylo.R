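# Distance-based phylogeny: Tamura-Nei (1993) pairwise distances with
# pairwise deletion of gap/N sites, Saitou-Nei neighbor joining with
# deterministic tie-breaking and non-negative branch lengths, and a
# small-parsimony count of independent functional -> disabled transitions.

#' Tamura-Nei (TN93) distance between two aligned sequences
#'
#' Uses empirical base frequencies pooled over the comparable sites of the
#' pair and distinguishes the two transition classes (A<->G, C<->T) from
#' transversions. Sites with a gap or N in either sequence are skipped
#' (pairwise deletion).
#'
#' @param a,b equal-length (gapped) DNA strings.
#' @return non-negative distance; `Inf` when a logarithm argument is
#'   non-positive (saturation); `NA` when no comparable sites remain.
#' @export
tn93_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  if (length(x) != length(y)) stop("sequences must have equal length", call. = FALSE)
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  freq <- (table(factor(x, levels = c("A", "C", "G", "T"))) +
           table(factor(y, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- x != y
  P1 <- sum(diff & ((x == "A" & y == "G") | (x == "G" & y == "A"))) / n
  P2 <- sum(diff & ((x == "C" & y == "T") | (x == "T" & y == "C"))) / n
  Q <- sum(diff) / n - P1 - P2
  if (P1 + P2 + Q == 0) return(0)
  if (gA * gG == 0 || gT * gC == 0 || gR * gY == 0) return(Inf)
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gT * gC / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
  w1 <- 1 - P1 / k1 - Q / (2 * gR)
  w2 <- 1 - P2 / k2 - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  if (w1 <= 0 || w2 <= 0 || w3 <= 0) return(Inf)
  -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
}

#' TN93 distance matrix over an alignment
#'
#' @param aln named character vector of equal-length (gapped) rows.
#' @return symmetric matrix with zero diagonal, labeled by row names.
#' @export
tn93_matrix <- function(aln) {
  n <- length(aln)
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- tn93_distance(aln[[i]], aln[[j]])
    }
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining. Ties in the Q-criterion are broken toward
#' the lowest index pair. A negative branch length is clamped to zero with
#' the deficit moved to its sibling branch, keeping the path length between
#' the joined pair.
#'
#' @param D symmetric distance matrix with labels (n >= 3).
#' @return an [ape::read.tree()] `phylo` object (unrooted, trifurcating at
#'   the final join).
#' @export
nj_tree <- function(D) {
  n <- nrow(D)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (n < 3L) stop("neighbor joining needs at least 3 taxa", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-9)) stop("distance matrix must be symmetric", call. = FALSE)
  labels <- rownames(D)
  # each active node holds a newick fragment (without trailing length)
  frags <- as.list(labels)
  d <- D
  clamp <- function(bi, bj) {
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    c(max(bi, 0), max(bj, 0))
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    rs <- rowSums(d)
    Q <- (m - 2) * d - outer(rs, rs, `+`)
    diag(Q) <- Inf
    # lowest-index pair among minima (column-major scan of upper triangle)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        if (Q[i, j] < bestq - 1e-12) { bestq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    b <- clamp(bi, bj)
    newfrag <- sprintf("(%s:%s,%s:%s)", frags[[i]], fmt(b[1]),
                       frags[[j]], fmt(b[2]))
    others <- setdiff(seq_len(m), c(i, j))
    newd <- (d[i, others] + d[j, others] - d[i, j]) / 2
    d2 <- d[others, others, drop = FALSE]
    d2 <- rbind(cbind(d2, newd), c(newd, 0))
    frags <- c(frags[others], list(newfrag))
    d <- d2
  }
  # final trifurcation from the three remaining pairwise distances
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  bl <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frags[[1]], fmt(bl[1]),
                 frags[[2]], fmt(bl[2]), frags[[3]], fmt(bl[3]))
  ape::read.tree(text = nwk)
}

#' Minimum number of independent gene-disabling events on a tree
#'
#' Small-parsimony (Sankoff) count of functional -> disabled transitions of
#' the binary functionality character, with the root state fixed to
#' functional (the ancestral allele is functional; disabled alleles derive
#' from it). Internal states are reconstructed by dynamic programming with
#' unit change cost and ties resolved toward "functional", and transitions
#' are counted on the resulting labeling.
#'
#' @param tree a `phylo` object whose tip labels have statuses.
#' @param calls named list of `functionality_call`s or named character
#'   vector of statuses covering every tip label.
#' @return integer count of functional -> disabled transitions.
#' @export
min_independent_losses <- function(tree, calls) {
  statuses <- if (is.character(calls)) calls else
    vapply(calls, function(x) x$status, character(1))
  miss <- setdiff(tree$tip.label, names(statuses))
  if (length(miss) > 0) {
    stop("missing functionality for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # cost[node, state]: min changes in subtree given node has state
  # (state 1 = functional, 2 = disabled)
  cost <- matrix(Inf, ntip + nnode, 2)
  tipstate <- ifelse(statuses[tree$tip.label] == "functional", 1L, 2L)
  for (i in seq_len(ntip)) cost[i, tipstate[i]] <- 0
  children <- split(tree$edge[, 2], tree$edge[, 1])
  # process internal nodes deepest-first: order by node depth
  depth <- rep(0L, ntip + nnode)
  for (k in seq_len(nrow(tree$edge))) {
    depth[tree$edge[k, 2]] <- depth[tree$edge[k, 1]] + 1L
  }
  internals <- (ntip + 1L):(ntip + nnode)
  internals <- internals[order(depth[internals], decreasing = TRUE)]
  for (v in internals) {
    ch <- children[[as.character(v)]]
    for (s in 1:2) {
      tot <- 0
      for (c_ in ch) {
        tot <- tot + min(cost[c_, 1] + (s != 1L), cost[c_, 2] + (s != 2L))
      }
      cost[v, s] <- tot
    }
  }
  # root fixed functional; backtrace preferring "functional" on ties
  state <- rep(NA_integer_, ntip + nnode)
  state[root] <- 1L
  preorder <- internals[order(depth[internals])]
  losses <- 0L
  for (v in preorder) {
    s <- state[v]
    for (c_ in children[[as.character(v)]]) {
      if (c_ <= ntip) {
        cs <- tipstate[c_]
      } else {
        c1 <- cost[c_, 1] + (s != 1L)
        c2 <- cost[c_, 2] + (s != 2L)
        cs <- if (c1 <= c2) 1L else 2L
        state[c_] <- cs
      }
      if (s == 1L && cs == 2L) losses <- losses + 1L
    }
  }
  losses
}

#' Write a distance matrix as a labeled square TSV
#' @param D matrix; @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(D, path) {
  tab <- data.frame(id = rownames(D), D, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
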