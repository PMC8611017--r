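#' Rule-based clone-tree reconstruction from VAF clusters
#'
#' Clusters of somatic SNVs with per-sample cellular fractions (CF) are
#' assembled into a rooted clone tree: clusters with CF above the founding
#' threshold (default 90%) in all samples merge into the founding clone
#' (trunk); the remaining clusters are grouped by their sample presence
#' pattern (CF at or above the presence cutoff, default 5%); each clone's
#' parent is the clone with the smallest presence superset (ties broken by
#' larger mean CF, then by id); clusters sharing a presence pattern are
#' chained in order of decreasing mean CF. Branch lengths are SNV counts.
#'
#' @param cluster_cf tibble `cluster`, `sample`, `cf`, `n_snvs` (as from
#'   [cluster_cellular_fractions()]).
#' @param founding_cf founding-clone threshold (default 0.90).
#' @param presence_cf presence cutoff (default 0.05).
#' @param merge_cf clusters sharing a presence pattern whose cellular
#'   fractions differ by less than this in every sample are grouped into a
#'   single clone (default 0.05); set to 0 to keep every cluster distinct.
#' @param min_snvs minimum SNVs with signal required to build a tree; below
#'   this an `insufficient signal` result is returned (default 5).
#' @return object of class `clone_tree`: tibble `clones` (clone, parent,
#'   n_snvs, mean_cf, member_clusters, presence pattern), matrix `cf`
#'   (clone x sample), `samples`, flags `unplaced`, `insufficient_signal`.
#' @export
build_clone_tree <- function(cluster_cf, founding_cf = 0.90,
                             presence_cf = 0.05, merge_cf = 0.05,
                             min_snvs = 5) {
  cluster_cf <- as_tibble(cluster_cf)
  assert_that(all(c("cluster", "sample", "cf", "n_snvs") %in% names(cluster_cf)),
              "`cluster_cf` needs cluster, sample, cf, n_snvs")
  samples <- sort(unique(cluster_cf$sample))
  wide <- cluster_cf %>%
    select("cluster", "sample", "cf") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "cf") %>%
    arrange(.data$cluster)
  cf <- as.matrix(wide[, samples, drop = FALSE])
  rownames(cf) <- wide$cluster
  n_snvs <- cluster_cf %>%
    distinct(.data$cluster, .data$n_snvs) %>%
    arrange(.data$cluster) %>%
    pull(.data$n_snvs)

  total_snvs <- sum(n_snvs)
  if (total_snvs < min_snvs) {
    return(structure(list(
      clones = tibble(), cf = NULL, samples = samples,
      insufficient_signal = TRUE, total_snvs = total_snvs
    ), class = "clone_tree"))
  }

  founding <- apply(cf, 1, function(x) all(x > founding_cf))
  assert_that(any(founding),
              paste("no cluster qualifies as founding clone (CF >",
                    founding_cf, "in all samples); review purity estimates",
                    "or thresholds"))

  present <- cf >= presence_cf
  pattern_key <- apply(present, 1, function(x) paste(which(x), collapse = ","))

  # founding clone = clone 1
  rest <- which(!founding)
  clone_rows <- list(tibble(
    clone = 1L,
    parent = NA_integer_,
    n_snvs = sum(n_snvs[founding]),
    mean_cf = mean(cf[founding, , drop = FALSE]),
    member_clusters = list(as.integer(rownames(cf)[founding])),
    pattern = paste(seq_along(samples), collapse = ","),
    unplaced = FALSE
  ))
  clone_cf <- matrix(colMeans(cf[founding, , drop = FALSE]), 1,
                     dimnames = list(NULL, samples))

  if (length(rest) > 0) {
    rest_tbl <- tibble(
      cluster = as.integer(rownames(cf)[rest]),
      idx = rest,
      pattern = pattern_key[rest],
      mean_cf = rowMeans(cf[rest, , drop = FALSE]),
      n_present = rowSums(present[rest, , drop = FALSE])
    ) %>%
      filter(.data$n_present > 0) %>%  # clusters absent everywhere are dropped
      arrange(dplyr::desc(.data$n_present), dplyr::desc(.data$mean_cf),
              .data$cluster)

    # group same-pattern clusters whose CF vectors are indistinguishable
    # (within merge_cf in every sample) into one clone; remaining clusters
    # become distinct clones, chained within equal patterns
    groups <- list()
    for (pat in unique(rest_tbl$pattern)) {
      members <- rest_tbl %>% filter(.data$pattern == pat)
      open <- NULL
      for (i in seq_len(nrow(members))) {
        idx <- members$idx[i]
        if (!is.null(open)) {
          ref_cf <- colSums(cf[open, , drop = FALSE] * n_snvs[open]) /
            sum(n_snvs[open])
          if (max(abs(cf[idx, ] - ref_cf)) < merge_cf) {
            open <- c(open, idx)
            next
          }
          groups[[length(groups) + 1]] <- open
        }
        open <- idx
      }
      if (!is.null(open)) groups[[length(groups) + 1]] <- open
    }

    clone_meta <- purrr::map(groups, function(g) {
      w <- n_snvs[g] / sum(n_snvs[g])
      cf_vec <- colSums(cf[g, , drop = FALSE] * w)
      list(
        clusters = as.integer(rownames(cf)[g]),
        cf_vec = cf_vec,
        n_snvs = sum(n_snvs[g]),
        pattern = pattern_key[g[1]],
        mean_cf = mean(cf_vec),
        set = which(present[g[1], ])
      )
    })
    # deterministic clone ids: patterns with more samples first, then CF
    ord <- order(-lengths(purrr::map(clone_meta, "set")),
                 -purrr::map_dbl(clone_meta, "mean_cf"),
                 purrr::map_int(clone_meta, ~ min(.x$clusters)))
    clone_meta <- clone_meta[ord]
    for (i in seq_along(clone_meta)) clone_meta[[i]]$clone <- i + 1L
    full_set <- seq_along(samples)
    sets <- c(list(full_set), purrr::map(clone_meta, "set"))
    mean_cfs <- c(clone_rows[[1]]$mean_cf, purrr::map_dbl(clone_meta, "mean_cf"))
    ids <- c(1L, purrr::map_int(clone_meta, "clone"))
    patterns <- c(clone_rows[[1]]$pattern, purrr::map_chr(clone_meta, "pattern"))

    for (i in seq_along(clone_meta)) {
      me <- clone_meta[[i]]
      j <- i + 1  # index into sets/ids for this clone
      # candidate parents: clones whose presence set is a superset
      is_sup <- purrr::map_lgl(seq_along(sets), function(k) {
        k != j && all(me$set %in% sets[[k]])
      })
      # same-pattern chaining: restrict same-pattern candidates to those with
      # larger mean CF (earlier in the sorted chain)
      same <- patterns == me$pattern
      ok <- is_sup & (!same | mean_cfs > me$mean_cf |
                        (mean_cfs == me$mean_cf & ids < me$clone))
      unplaced <- FALSE
      if (!any(ok)) {
        parent <- 1L
        unplaced <- TRUE
      } else {
        cand <- which(ok)
        sizes <- purrr::map_int(sets[cand], length)
        cand <- cand[sizes == min(sizes)]
        if (any(patterns[cand] == me$pattern)) {
          # same-pattern clusters form a chain in decreasing mean CF: attach
          # to the same-pattern clone immediately above this one
          cand <- cand[patterns[cand] == me$pattern]
          cand <- cand[which.min(mean_cfs[cand])]
        } else if (length(cand) > 1) {
          mc <- mean_cfs[cand]
          cand <- cand[mc == max(mc)]
          if (length(cand) > 1) cand <- cand[which.min(ids[cand])]
        }
        parent <- ids[cand]
      }
      clone_rows[[length(clone_rows) + 1]] <- tibble(
        clone = me$clone,
        parent = parent,
        n_snvs = me$n_snvs,
        mean_cf = me$mean_cf,
        member_clusters = list(me$clusters),
        pattern = me$pattern,
        unplaced = unplaced
      )
      clone_cf <- rbind(clone_cf, me$cf_vec)
    }
  }

  clones <- bind_rows(clone_rows)
  rownames(clone_cf) <- clones$clone
  res <- structure(list(
    clones = clones, cf = clone_cf, samples = samples,
    insufficient_signal = FALSE, total_snvs = total_snvs,
    presence_cf = presence_cf
  ), class = "clone_tree")
  check_nested_presence(res)
  res
}

# warn (not fail) when a child's presence set escapes its parent's, or when
# sibling CF sums cross the parent CF by more than the tolerance
check_nested_presence <- function(tree, tol = 0.05) {
  clones <- tree$clones
  for (i in seq_len(nrow(clones))) {
    p <- clones$parent[i]
    if (is.na(p)) next
    child_set <- which(tree$cf[i, ] >= tree$presence_cf)
    parent_set <- which(tree$cf[match(p, clones$clone), ] >= tree$presence_cf)
    if (!all(child_set %in% parent_set) && !clones$unplaced[i]) {
      warn(sprintf("clone %d presence is not nested within parent %d",
                   clones$clone[i], p))
    }
  }
  sib <- split(seq_len(nrow(clones)), clones$parent)
  for (p in names(sib)) {
    pi <- match(as.integer(p), clones$clone)
    if (is.na(pi)) next
    sib_sum <- colSums(tree$cf[sib[[p]], , drop = FALSE])
    over <- sib_sum > tree$cf[pi, ] + tol
    if (any(over)) {
      warn(sprintf("sibling CF sum exceeds parent clone %s CF in sample(s) %s",
                   p, paste(tree$samples[over], collapse = ", ")))
    }
  }
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  if (isTRUE(x$insufficient_signal)) {
    cat(sprintf("<clone_tree> insufficient signal (%d SNVs)\n", x$total_snvs))
  } else {
    cat(sprintf("<clone_tree> %d clones, %d SNVs, %d samples\n",
                nrow(x$clones), x$total_snvs, length(x$samples)))
  }
  invisible(x)
}

#' Annotate samples at their deepest contained clone
#'
#' Each sample is annotated at the clone furthest from the tree stem among
#' clones with CF at or above the presence cutoff. A sample carrying clones
#' from more than one branch at the deepest level is flagged as clonal
#' intermixing.
#'
#' @param tree a [build_clone_tree()] result.
#' @return tibble: `sample`, `annotation_clone`, `depth`, `intermixing`.
#' @export
annotate_samples <- function(tree) {
  assert_that(inherits(tree, "clone_tree"), "`tree` must be a clone_tree")
  assert_that(!isTRUE(tree$insufficient_signal), "tree has insufficient signal")
  clones <- tree$clones
  depth_of <- function(id) {
    d <- 0
    while (!is.na(id)) {
      id <- clones$parent[match(id, clones$clone)]
      d <- d + 1
    }
    d
  }
  depths <- purrr::map_int(clones$clone, ~ as.integer(depth_of(.x)))
  purrr::map_dfr(seq_along(tree$samples), function(s) {
    present <- which(tree$cf[, s] >= tree$presence_cf)
    dmax <- max(depths[present])
    deepest <- present[depths[present] == dmax]
    pick <- deepest[which.max(tree$cf[deepest, s])]
    # intermixing: >1 present clone at max depth on different branches, or
    # any present clone not an ancestor/descendant of the pick
    anc <- function(id) {
      out <- integer(0)
      while (!is.na(id)) {
        out <- c(out, id)
        id <- clones$parent[match(id, clones$clone)]
      }
      out
    }
    lineage <- anc(clones$clone[pick])
    intermix <- any(!clones$clone[present] %in% lineage)
    tibble(sample = tree$samples[s],
           annotation_clone = clones$clone[pick],
           depth = dmax,
           intermixing = intermix)
  })
}

#' Export a clone tree as a Newick string and edge list
#'
#' Branch lengths are the SNV counts of each clone. The Newick string
#' round-trips through [parse_newick()].
#'
#' @param tree a `clone_tree`.
#' @return list with `newick` (string) and `edges` (tibble parent, child,
#'   length).
#' @export
tree_to_newick <- function(tree) {
  assert_that(inherits(tree, "clone_tree"), "`tree` must be a clone_tree")
  clones <- tree$clones
  # cycle guard
  for (i in seq_len(nrow(clones))) {
    seen <- integer(0)
    id <- clones$clone[i]
    while (!is.na(id)) {
      assert_that(!id %in% seen, "cyclic parent mapping: invalid tree")
      seen <- c(seen, id)
      id <- clones$parent[match(id, clones$clone)]
    }
  }
  children <- split(clones$clone, clones$parent)
  rec <- function(id) {
    kids <- children[[as.character(id)]]
    lab <- sprintf("c%d:%d", id, clones$n_snvs[match(id, clones$clone)])
    if (is.null(kids)) return(lab)
    sprintf("(%s)%s", paste(purrr::map_chr(sort(kids), rec), collapse = ","), lab)
  }
  root <- clones$clone[is.na(clones$parent)]
  newick <- paste0("(", rec(root), ");")
  edges <- clones %>%
    filter(!is.na(.data$parent)) %>%
    transmute(parent = .data$parent, child = .data$clone,
              length = .data$n_snvs)
  list(newick = newick, edges = edges)
}

#' Parse a Newick string written by [tree_to_newick()]
#'
#' Minimal recursive-descent parser for rooted Newick with `label:length`
#' node annotations.
#'
#' @param newick a Newick string.
#' @return tibble `label`, `parent_label`, `length`.
#' @export
parse_newick <- function(newick) {
  s <- gsub(";\\s*$", "", trimws(newick))
  pos <- 1
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  out <- list()
  parse_node <- function(parent) {
    kids <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1
      repeat {
        parse_node_label <- parse_node(NA_character_)
        kids <- c(kids, parse_node_label)
        if (peek() == ",") { pos <<- pos + 1 } else break
      }
      assert_that(peek() == ")", "malformed newick: expected )")
      pos <<- pos + 1
    }
    m <- regmatches(substr(s, pos, n),
                    regexpr("^[^(),:;]*", substr(s, pos, n)))
    label <- m
    pos <<- pos + nchar(m)
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1
      m <- regmatches(substr(s, pos, n),
                      regexpr("^[0-9eE.+-]+", substr(s, pos, n)))
      len <- as.numeric(m)
      pos <<- pos + nchar(m)
    }
    out[[length(out) + 1]] <<- tibble(label = label, length = len)
    for (k in kids) {
      out[[length(out) + 1]] <<- tibble(label = k, parent_label = label)
    }
    label
  }
  root <- parse_node(NA_character_)
  nodes <- bind_rows(out)
  lens <- nodes %>% filter(!is.na(.data$length)) %>%
    distinct(.data$label, .keep_all = TRUE) %>% select("label", "length")
  parents <- nodes %>% filter(!is.na(.data$parent_label)) %>%
    distinct(.data$label, .keep_all = TRUE) %>% select("label", "parent_label")
  lens %>%
    left_join(parents, by = "label") %>%
    select("label", "parent_label", "length")
}
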