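#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted VAF mixture model
#'
#' One row per cluster x sample with weight and the binomial success
#' probability.
#'
#' @param x a `vaf_mixture`.
#' @param ... unused.
#' @return tibble: `cluster`, `sample`, `weight`, `theta`.
#' @method tidy vaf_mixture
#' @export
tidy.vaf_mixture <- function(x, ...) {
  tidyr::expand_grid(cluster = seq_len(x$K), sample = x$samples) %>%
    mutate(weight = x$pi[.data$cluster],
           theta = x$theta[cbind(.data$cluster,
                                 match(.data$sample, x$samples))])
}

#' Glance at a fitted VAF mixture model
#'
#' @param x a `vaf_mixture`.
#' @param ... unused.
#' @return one-row tibble: `k`, `loglik`, `bic`, `converged`, `n_variants`.
#' @method glance vaf_mixture
#' @export
glance.vaf_mixture <- function(x, ...) {
  tibble(k = x$K, loglik = x$loglik, bic = x$bic,
         converged = x$converged, n_variants = nrow(x$assignment))
}

#' Tidy a clone tree
#'
#' @param x a `clone_tree`.
#' @param ... unused.
#' @return edge-list tibble: `clone`, `parent`, `n_snvs`, `mean_cf`,
#'   `unplaced`.
#' @method tidy clone_tree
#' @export
tidy.clone_tree <- function(x, ...) {
  if (isTRUE(x$insufficient_signal)) return(tibble())
  x$clones %>% select("clone", "parent", "n_snvs", "mean_cf", "unplaced")
}

#' Glance at a clone tree
#'
#' @param x a `clone_tree`.
#' @param ... unused.
#' @return one-row tibble: `n_clones`, `n_snvs`, `n_samples`,
#'   `insufficient_signal`.
#' @method glance clone_tree
#' @export
glance.clone_tree <- function(x, ...) {
  tibble(
    n_clones = if (isTRUE(x$insufficient_signal)) 0L else nrow(x$clones),
    n_snvs = x$total_snvs,
    n_samples = length(x$samples),
    insufficient_signal = isTRUE(x$insufficient_signal)
  )
}

#' Tidy a copy-number phylogeny
#'
#' @param x a `cn_tree`.
#' @param ... unused.
#' @return tibble of tree edges with branch lengths (event counts from
#'   neighbour joining, clamped at 0).
#' @method tidy cn_tree
#' @export
tidy.cn_tree <- function(x, ...) {
  phylo <- x$phylo
  labels <- c(phylo$tip.label,
              paste0("node", seq_len(phylo$Nnode)))
  tibble(
    parent = labels[phylo$edge[, 1]],
    child = labels[phylo$edge[, 2]],
    length = phylo$edge.length
  )
}

#' Glance at a copy-number phylogeny
#'
#' @param x a `cn_tree`.
#' @param ... unused.
#' @return one-row tibble: `n_samples`, `n_segments`,
#'   `n_infeasible_pairs`.
#' @method glance cn_tree
#' @export
glance.cn_tree <- function(x, ...) {
  tibble(
    n_samples = length(x$matrices$samples),
    n_segments = length(x$matrices$chrom),
    n_infeasible_pairs = length(x$infeasible_pairs)
  )
}
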