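# shared fixtures built in code

# long count table for a planted multi-sample binomial mixture
make_mixture_tbl <- function(theta, n_per, depth = 300, seed = 1) {
  withr::with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(theta))) {
      for (i in seq_len(n_per[k])) {
        d <- stats::rpois(ncol(theta), depth)
        rows[[length(rows) + 1]] <- tibble::tibble(
          variant_id = sprintf("k%d_i%d", k, i),
          sample = paste0("S", seq_len(ncol(theta))),
          alt_count = stats::rbinom(ncol(theta), d, theta[k, ]),
          depth = d,
          truth = k
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

# adjusted Rand index (independent implementation from the contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# per-sample segment table covering one chromosome with given breaks/states
seg_tbl <- function(sample, chrom, breaks, major, minor) {
  tibble::tibble(
    sample = sample, chrom = chrom,
    start0 = breaks[-length(breaks)], end0 = breaks[-1],
    cn_major = major, cn_minor = minor
  )
}

# SNP BAF table for one segment with binomial draws at a fixed BAF
snp_baf_tbl <- function(sample, chrom, positions, baf, depth = 100,
                        seed = 1) {
  withr::with_seed(seed, {
    d <- stats::rpois(length(positions), depth)
    tibble::tibble(chrom = chrom, pos = positions, sample = sample,
                   b_count = stats::rbinom(length(positions), d, baf),
                   depth = d)
  })
}

# independent BFS oracle for the minimum-event distance: breadth-first
# search over contiguous +/-1 events; a run must be strictly positive in
# every segment before an operation; states capped one above the tested
# maximum copy number (overshoot beyond that cannot shorten a path)
bfs_event_distances <- function(a, cap = 5L) {
  L <- length(a)
  base <- cap + 1L
  encode <- function(v) as.integer(sum(v * base^(0:(L - 1))) + 1)
  dist <- rep(NA_integer_, base^L)
  dist[encode(a)] <- 0L
  frontier <- matrix(as.integer(a), nrow = 1)
  runs <- list()
  for (i in 1:L) for (j in i:L) runs[[length(runs) + 1]] <- i:j
  d <- 0L
  while (nrow(frontier) > 0) {
    nxt <- list()
    for (r in runs) {
      for (s in c(1L, -1L)) {
        ok <- rowSums(frontier[, r, drop = FALSE] >= 1) == length(r)
        if (s > 0) {
          ok <- ok & rowSums(frontier[, r, drop = FALSE] + 1 > cap) == 0
        }
        if (!any(ok)) next
        nb <- frontier[ok, , drop = FALSE]
        nb[, r] <- nb[, r] + s
        nxt[[length(nxt) + 1]] <- nb
      }
    }
    if (!length(nxt)) break
    nb <- unique(do.call(rbind, nxt))
    codes <- as.integer(nb %*% base^(0:(L - 1)) + 1)
    keep <- is.na(dist[codes]) & !duplicated(codes)
    dist[codes[keep]] <- d + 1L
    frontier <- nb[keep, , drop = FALSE]
    d <- d + 1L
  }
  list(dist = dist, encode = encode)
}

# planted clone tree restricted to its leaves as an ape phylogeny with the
# diploid outgroup attached at the founding clone
planted_leaf_phylo <- function(tree) {
  ch <- split(tree$clone, tree$parent)
  rec <- function(id) {
    kids <- ch[[as.character(id)]]
    if (is.null(kids)) return(sprintf("S%d", id))
    sprintf("(%s)", paste(vapply(kids, rec, ""), collapse = ","))
  }
  ape::collapse.singles(
    ape::read.tree(text = sprintf("(%s,diploid);", rec(1)))
  )
}
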