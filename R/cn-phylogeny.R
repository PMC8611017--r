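#' Minimum-event distance between haplotype-specific copy-number profiles
#'
#' The directed minimum number of contiguous segmental +/-1 operations
#' transforming profile `a` into profile `b`, computed per chromosome by a
#' scanline: gains and losses are counted as the sums of positive
#' increments of the positive and negative parts of the difference signal.
#' The distance is infeasible (`Inf`) when `b` demands copies on a segment
#' where `a` has zero: lost genetic material cannot be regained.
#'
#' @param a,b equal-length non-negative integer vectors (one haplotype), or
#'   matrices/data frames with one column per haplotype.
#' @param chrom optional chromosome factor per segment; events never span
#'   chromosome boundaries.
#' @return numeric event count (possibly `Inf`).
#' @export
event_distance <- function(a, b, chrom = NULL) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "profiles must have equal dimensions")
  assert_that(all(a >= 0) && all(b >= 0), "copy numbers must be >= 0")
  if (is.null(chrom)) chrom <- rep(1L, nrow(a))
  assert_that(length(chrom) == nrow(a), "`chrom` must match profile length")
  if (any(a == 0 & b > 0)) return(Inf)
  total <- 0
  for (h in seq_len(ncol(a))) {
    for (cc in unique(chrom)) {
      d <- b[chrom == cc, h] - a[chrom == cc, h]
      up <- pmax(d, 0)
      dn <- pmax(-d, 0)
      total <- total +
        sum(pmax(up - c(0, head(up, -1)), 0)) +
        sum(pmax(dn - c(0, head(dn, -1)), 0))
    }
  }
  total
}

# symmetrised distance for tree building; both directions infeasible gets a
# large finite penalty
symmetric_event_distance <- function(a, b, chrom = NULL, penalty = NULL) {
  d_ab <- event_distance(a, b, chrom)
  d_ba <- event_distance(b, a, chrom)
  d <- min(d_ab, d_ba)
  if (!is.finite(d)) {
    penalty <- penalty %||% (2 * (sum(abs(as.matrix(a) - as.matrix(b))) + 1))
    return(structure(penalty, infeasible = TRUE))
  }
  d
}

# profiles argument: tibble sample, segment_id, chrom, cnA, cnB
profile_matrices <- function(profiles) {
  profiles <- as_tibble(profiles)
  need <- c("sample", "segment_id", "chrom", "cnA", "cnB")
  assert_that(all(need %in% names(profiles)),
              "profiles need sample, segment_id, chrom, cnA, cnB")
  segs <- profiles %>%
    distinct(.data$segment_id, .data$chrom) %>%
    arrange(.data$segment_id)
  samples <- sort(unique(profiles$sample))
  get <- function(col) {
    w <- profiles %>%
      select("sample", "segment_id", dplyr::all_of(col)) %>%
      tidyr::pivot_wider(names_from = "segment_id",
                         values_from = dplyr::all_of(col)) %>%
      arrange(.data$sample)
    m <- as.matrix(w[, as.character(segs$segment_id), drop = FALSE])
    rownames(m) <- w$sample
    m
  }
  list(cnA = get("cnA"), cnB = get("cnB"),
       chrom = segs$chrom, segment_id = segs$segment_id, samples = samples)
}

# stack the two haplotypes of one sample into a 2-column matrix
sample_profile <- function(m, s) cbind(m$cnA[s, ], m$cnB[s, ])

#' Pairwise minimum-event distance matrix
#'
#' @param profiles tibble `sample`, `segment_id`, `chrom`, `cnA`, `cnB`.
#' @param add_diploid add a diploid pseudo-sample (all copy numbers 1)
#'   named `"diploid"` for rooting.
#' @return list: `dist` (symmetric matrix), `directed` (matrix of directed
#'   distances, `Inf` where infeasible), `infeasible_pairs`.
#' @export
cn_distance_matrix <- function(profiles, add_diploid = TRUE) {
  m <- profile_matrices(profiles)
  samples <- m$samples
  profs <- purrr::map(samples, ~ sample_profile(m, .x))
  names(profs) <- samples
  if (add_diploid) {
    profs$diploid <- matrix(1L, length(m$chrom), 2)
    samples <- c(samples, "diploid")
  }
  k <- length(samples)
  directed <- matrix(0, k, k, dimnames = list(samples, samples))
  sym <- matrix(0, k, k, dimnames = list(samples, samples))
  infeas <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        directed[i, j] <- event_distance(profs[[i]], profs[[j]], m$chrom)
      }
    }
  }
  # evolution between two extant profiles runs through a common ancestor;
  # the segment-wise minimum (floored at one copy wherever either profile
  # still has the segment) is a feasible ancestor candidate, and the summed
  # distance through it bounds the path even when both direct directions
  # are infeasible because of differently lost segments
  through_ancestor <- function(a, b) {
    z <- pmin(a, b)
    z[z == 0 & (a > 0 | b > 0)] <- 1L
    event_distance(z, a, m$chrom) + event_distance(z, b, m$chrom)
  }
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) {
        d_direct <- min(directed[i, j], directed[j, i])
        d_anc <- through_ancestor(profs[[i]], profs[[j]])
        if (!is.finite(d_direct)) {
          infeas[[length(infeas) + 1]] <- c(samples[i], samples[j])
        }
        sym[i, j] <- sym[j, i] <- min(d_direct, d_anc)
      }
    }
  }
  list(dist = sym, directed = directed,
       infeasible_pairs = infeas, matrices = m)
}

#' Build a copy-number phylogeny by neighbour joining
#'
#' Neighbour joining on symmetrised minimum-event distances, rooted at an
#' added diploid pseudo-sample; negative branch lengths are clamped to 0.
#'
#' @param profiles tibble `sample`, `segment_id`, `chrom`, `cnA`, `cnB`
#'   with at least 2 samples.
#' @return object of class `cn_tree`: `phylo` (rooted ape tree including
#'   the `diploid` tip), `dist`, `directed`, `profiles` matrices.
#' @export
build_cn_tree <- function(profiles) {
  dm <- cn_distance_matrix(profiles, add_diploid = TRUE)
  n_real <- length(dm$matrices$samples)
  assert_that(n_real >= 2, "need >= 2 samples to build a tree")
  if (n_real == 2) {
    # NJ needs >= 3 tips; with the diploid root it is exactly 3
    phylo <- ape::nj(stats::as.dist(dm$dist))
  } else {
    phylo <- ape::nj(stats::as.dist(dm$dist))
  }
  phylo$edge.length <- pmax(phylo$edge.length, 0)
  phylo <- ape::root(phylo, outgroup = "diploid", resolve.root = TRUE)
  structure(list(phylo = phylo, dist = dm$dist, directed = dm$directed,
                 matrices = dm$matrices,
                 infeasible_pairs = dm$infeasible_pairs),
            class = "cn_tree")
}

#' @export
print.cn_tree <- function(x, ...) {
  cat(sprintf("<cn_tree> %d samples + diploid root, %d segments\n",
              length(x$matrices$samples), length(x$matrices$chrom)))
  invisible(x)
}

#' Parsimony reconstruction of ancestral copy-number profiles
#'
#' Per-segment, per-haplotype Sankoff dynamic programme on the rooted tree:
#' unit cost per copy-number step, transitions from 0 to a positive copy
#' number barred (lost alleles are never regained), root fixed at the
#' diploid state, ties broken toward the smaller copy number. Branch event
#' counts are recomputed as minimum-event distances between the
#' reconstructed parent and child profiles.
#'
#' @param tree a [build_cn_tree()] result.
#' @return list: `ancestors` (tibble node, segment_id, chrom, cnA, cnB),
#'   `branch_events` (tibble parent, child, events), `total_events`.
#' @export
reconstruct_ancestors <- function(tree) {
  assert_that(inherits(tree, "cn_tree"), "`tree` must be a cn_tree")
  phylo <- tree$phylo
  m <- tree$matrices
  n_tip <- length(phylo$tip.label)
  n_node <- phylo$Nnode
  n_seg <- length(m$chrom)
  max_cn <- max(m$cnA, m$cnB, 1)
  states <- 0:max_cn
  ns <- length(states)

  # transition cost: |i - j| steps; 0 -> positive barred
  trans <- outer(states, states, function(i, j) abs(i - j))
  trans[states == 0, states > 0] <- Inf

  edge <- phylo$edge
  root <- n_tip + 1
  # postorder traversal
  post <- ape::reorder.phylo(phylo, "postorder")$edge

  tip_value <- function(label, h, seg) {
    if (label == "diploid") return(1L)
    if (h == 1) m$cnA[label, seg] else m$cnB[label, seg]
  }

  anc <- array(NA_integer_, dim = c(n_node, n_seg, 2))
  for (h in 1:2) {
    for (seg in seq_len(n_seg)) {
      cost <- matrix(Inf, n_tip + n_node, ns)
      for (t in seq_len(n_tip)) {
        v <- tip_value(phylo$tip.label[t], h, seg)
        cost[t, ] <- Inf
        cost[t, v + 1] <- 0
      }
      inner <- unique(post[, 1])
      for (nd in inner) cost[nd, ] <- 0
      for (k in seq_len(nrow(post))) {
        par <- post[k, 1]
        ch <- post[k, 2]
        # min over child states of (trans cost + child cost)
        add <- apply(trans + rep(cost[ch, ], each = ns), 1, min)
        cost[par, ] <- cost[par, ] + add
      }
      # choose states top-down; root fixed diploid
      choice <- integer(n_tip + n_node)
      choice[root] <- 1L  # state "1" (index 2) is diploid per haplotype
      pre <- post[rev(seq_len(nrow(post))), , drop = FALSE]
      for (k in seq_len(nrow(pre))) {
        par <- pre[k, 1]
        ch <- pre[k, 2]
        if (ch <= n_tip) next
        tot <- trans[choice[par] + 1, ] + cost[ch, ]
        best <- min(tot)
        choice[ch] <- states[which(tot == best)[1]]  # ties -> smaller state
      }
      anc[, seg, h] <- choice[(n_tip + 1):(n_tip + n_node)]
    }
  }

  ancestors <- purrr::map_dfr(seq_len(n_node), function(i) {
    tibble(node = n_tip + i, segment_id = m$segment_id, chrom = m$chrom,
           cnA = anc[i, , 1], cnB = anc[i, , 2])
  })

  node_profile <- function(nd) {
    if (nd <= n_tip) {
      lab <- phylo$tip.label[nd]
      if (lab == "diploid") matrix(1L, n_seg, 2) else sample_profile(m, lab)
    } else {
      cbind(anc[nd - n_tip, , 1], anc[nd - n_tip, , 2])
    }
  }
  branch_events <- purrr::map_dfr(seq_len(nrow(edge)), function(k) {
    pp <- node_profile(edge[k, 1])
    cp <- node_profile(edge[k, 2])
    ev <- event_distance(pp, cp, m$chrom)
    tibble(parent = edge[k, 1], child = edge[k, 2], events = ev)
  })
  if (any(!is.finite(branch_events$events))) {
    bad <- branch_events %>% filter(!is.finite(.data$events))
    abort(paste("infeasible labelling: child demands regain on branches",
                paste(bad$parent, "->", bad$child, collapse = "; ")),
          class = "mrclone_error")
  }
  list(ancestors = ancestors, branch_events = branch_events,
       total_events = sum(branch_events$events))
}

# unrooted bipartitions of the tip set (as sorted label strings), excluding
# trivial ones
tree_bipartitions <- function(phylo) {
  tips <- sort(phylo$tip.label)
  parts <- ape::prop.part(phylo)
  labs <- attr(parts, "labels")
  out <- character(0)
  for (p in parts) {
    side <- sort(labs[p])
    other <- setdiff(tips, side)
    if (length(side) >= 2 && length(other) >= 2) {
      key <- if (side[1] < other[1]) paste(side, collapse = ",") else
        paste(other, collapse = ",")
      out <- c(out, key)
    }
  }
  unique(out)
}

#' Jackknife branch support for a copy-number phylogeny
#'
#' Each replicate drops `drop_fraction` of the joint segments uniformly
#' without replacement, rebuilds the neighbour-joining tree, and each
#' bipartition of the original tree is scored by the percentage of
#' replicates containing it.
#'
#' @param profiles tibble `sample`, `segment_id`, `chrom`, `cnA`, `cnB`.
#' @param n_replicates number of jackknife replicates (default 100).
#' @param drop_fraction fraction of segments dropped per replicate.
#' @param seed RNG seed.
#' @return list: `support` (tibble bipartition, support in \[0, 100\]),
#'   `tree` (the full-data `cn_tree`).
#' @export
jackknife_support <- function(profiles, n_replicates = 100,
                              drop_fraction = 0.5, seed = 1) {
  profiles <- as_tibble(profiles)
  assert_that(length(unique(profiles$sample)) >= 3,
              "need >= 3 samples for branch support")
  full <- build_cn_tree(profiles)
  target <- tree_bipartitions(full$phylo)
  seg_ids <- sort(unique(profiles$segment_id))
  n_keep <- max(2, round(length(seg_ids) * (1 - drop_fraction)))
  hits <- setNames(numeric(length(target)), target)
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      keep <- sort(sample(seg_ids, n_keep))
      rep_tree <- build_cn_tree(filter(profiles, .data$segment_id %in% keep))
      bp <- tree_bipartitions(rep_tree$phylo)
      hits[target %in% bp] <- hits[target %in% bp] + 1
    }
  })
  list(
    support = tibble(bipartition = target,
                     support = 100 * unname(hits) / n_replicates),
    tree = full
  )
}
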