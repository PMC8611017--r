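#' Binomial mixture clustering of multi-sample VAFs
#'
#' Variants are clustered on their joint alt/depth counts across all samples
#' of a patient with a binomial mixture fitted by EM. Clustering is intended
#' for copy-number-neutral diploid variants; cluster centres are converted to
#' cellular fractions as `2 * theta / purity`, truncated to \[0, 1\].
#'
#' @name vaf_clustering
NULL

VAF_FLOOR <- 1e-10

# build an n_variants x n_samples list of matrices from a long table
vaf_matrices <- function(vaf_tbl) {
  vaf_tbl <- as_tibble(vaf_tbl)
  assert_that(all(c("variant_id", "sample", "alt_count", "depth") %in%
                    names(vaf_tbl)),
              "need columns variant_id, sample, alt_count, depth")
  assert_that(all(vaf_tbl$alt_count <= vaf_tbl$depth),
              "alt_count must not exceed depth")
  alt <- tidyr::pivot_wider(vaf_tbl[, c("variant_id", "sample", "alt_count")],
                            names_from = "sample", values_from = "alt_count")
  dep <- tidyr::pivot_wider(vaf_tbl[, c("variant_id", "sample", "depth")],
                            names_from = "sample", values_from = "depth")
  ids <- alt$variant_id
  alt <- as.matrix(alt[, -1, drop = FALSE])
  dep <- as.matrix(dep[, -1, drop = FALSE])
  assert_that(!anyNA(alt) && !anyNA(dep),
              "every variant needs counts in every sample")
  list(ids = ids, alt = alt, depth = dep, samples = colnames(alt))
}

# log-likelihood matrix (variants x K) under per-cluster per-sample binomials
mixture_loglik_matrix <- function(alt, dep, theta) {
  K <- nrow(theta)
  n <- nrow(alt)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    th <- pmin(pmax(theta[k, ], VAF_FLOOR), 1 - VAF_FLOOR)
    ll[, k] <- rowSums(dbinom(alt, dep, rep(th, each = n), log = TRUE))
  }
  ll
}

em_binomial_mixture <- function(alt, dep, K, init_theta, max_iter = 500,
                                tol = 1e-6) {
  n <- nrow(alt)
  S <- ncol(alt)
  theta <- init_theta
  pi_k <- rep(1 / K, K)
  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    lmat <- mixture_loglik_matrix(alt, dep, theta) +
      matrix(log(pi_k), n, K, byrow = TRUE)
    lmax <- apply(lmat, 1, max)
    w <- exp(lmat - lmax)
    rowsum_w <- rowSums(w)
    resp <- w / rowsum_w
    ll <- sum(lmax + log(rowsum_w))
    ll_trace <- c(ll_trace, ll)
    nk <- colSums(resp)
    pi_k <- nk / n
    for (k in seq_len(K)) {
      num <- colSums(resp[, k] * alt)
      den <- colSums(resp[, k] * dep)
      theta[k, ] <- ifelse(den > 0, num / den, VAF_FLOOR)
    }
    theta <- pmin(pmax(theta, VAF_FLOOR), 1 - VAF_FLOOR)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  # final E-step quantities at the converged parameters
  lmat <- mixture_loglik_matrix(alt, dep, theta) +
    matrix(log(pi_k), n, K, byrow = TRUE)
  lmax <- apply(lmat, 1, max)
  w <- exp(lmat - lmax)
  resp <- w / rowSums(w)
  ll <- sum(lmax + log(rowSums(w)))
  list(theta = theta, pi = pi_k, resp = resp, loglik = ll,
       ll_trace = ll_trace, converged = converged)
}

#' Fit a binomial mixture to multi-sample variant counts
#'
#' EM with multiple seeded restarts; clusters with weight below `1e-3` are
#' pruned after fitting. VAFs of exactly zero are floored at `1e-10`
#' internally so that the likelihood stays finite.
#'
#' @param vaf_tbl long table: `variant_id`, `sample`, `alt_count`, `depth`.
#' @param K number of mixture components (>= 1).
#' @param n_restarts EM restarts with distinct seeded initialisations.
#' @param seed master seed for the restarts.
#' @param max_iter,tol EM convergence controls (relative log-likelihood).
#' @return object of class `vaf_mixture`: fields `K`, `pi`, `theta`
#'   (K x samples), `assignment` (tibble variant_id/cluster), `resp`,
#'   `loglik`, `bic`, `converged`, `samples`, `ll_trace`.
#' @export
fit_binomial_mixture <- function(vaf_tbl, K, n_restarts = 10, seed = 1,
                                 max_iter = 500, tol = 1e-6) {
  assert_count(K, "K")
  m <- vaf_matrices(vaf_tbl)
  alt <- m$alt
  dep <- m$depth
  n <- nrow(alt)
  assert_that(n >= 1, "empty VAF matrix")
  vaf <- alt / pmax(dep, 1)
  vaf[vaf == 0] <- VAF_FLOOR

  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_seed(child_seed(seed, r), {
      if (K == 1) {
        matrix(colSums(alt) / pmax(colSums(dep), 1), 1, ncol(alt))
      } else if (r == 1 && n >= K) {
        km <- tryCatch(
          suppressWarnings(kmeans(vaf, centers = K, nstart = 3))$centers,
          error = function(e) NULL)  # fewer distinct points than centres
        if (!is.null(km)) km else
          vaf[sample(n, K, replace = n < K), , drop = FALSE] +
            matrix(runif(K * ncol(alt), 0, 0.02), K)
      } else {
        vaf[sample(n, K, replace = n < K), , drop = FALSE] +
          matrix(runif(K * ncol(alt), 0, 0.02), K)
      }
    })
    init <- pmin(pmax(init, VAF_FLOOR), 1 - VAF_FLOOR)
    fit <- em_binomial_mixture(alt, dep, K, init, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  # prune empty components and re-normalise
  keep <- best$pi >= 1e-3
  if (!all(keep)) {
    best$theta <- best$theta[keep, , drop = FALSE]
    best$pi <- best$pi[keep] / sum(best$pi[keep])
    lmat <- mixture_loglik_matrix(alt, dep, best$theta) +
      matrix(log(best$pi), n, sum(keep), byrow = TRUE)
    lmax <- apply(lmat, 1, max)
    w <- exp(lmat - lmax)
    best$resp <- w / rowSums(w)
    best$loglik <- sum(lmax + log(rowSums(w)))
  }
  K_eff <- nrow(best$theta)
  n_par <- (K_eff - 1) + K_eff * ncol(alt)
  bic <- -2 * best$loglik + n_par * log(n)
  cluster <- max.col(best$resp, ties.method = "first")
  if (!best$converged) {
    warn("EM did not converge within max_iter; returning best model")
  }
  structure(list(
    K = K_eff, pi = best$pi, theta = best$theta,
    assignment = tibble(variant_id = m$ids, cluster = cluster),
    resp = best$resp, loglik = best$loglik, bic = bic,
    converged = best$converged, samples = m$samples,
    ll_trace = best$ll_trace
  ), class = "vaf_mixture")
}

#' @export
print.vaf_mixture <- function(x, ...) {
  cat(sprintf("<vaf_mixture> K=%d, loglik=%.2f, BIC=%.2f, %d variants\n",
              x$K, x$loglik, x$bic, nrow(x$assignment)))
  invisible(x)
}

#' Select the number of VAF clusters by BIC
#'
#' Fits binomial mixtures for K = 1..K_max and returns the BIC-minimal
#' model. The upper limit defaults to 20 clusters. Clusters retaining
#' fewer than `min_cluster_size` variants after selection are treated as
#' outlier groups: they are dissolved and their variants re-attached to the
#' nearest remaining cluster by refitting the mixture at the reduced K
#' (initialised from the surviving cluster centres).
#'
#' @inheritParams fit_binomial_mixture
#' @param K_max largest number of clusters to consider.
#' @param min_cluster_size smallest variant count a cluster may keep
#'   (default 3; set to 1 to disable consolidation).
#' @return the selected `vaf_mixture`, with a `bic_path` attribute
#'   (tibble of K and BIC).
#' @export
select_mixture_model <- function(vaf_tbl, K_max = 20, n_restarts = 10,
                                 seed = 1, max_iter = 500, tol = 1e-6,
                                 min_cluster_size = 3) {
  assert_count(K_max, "K_max")
  n <- length(unique(as_tibble(vaf_tbl)$variant_id))
  K_hi <- min(K_max, n)
  fits <- purrr::map(seq_len(K_hi), function(K) {
    fit_binomial_mixture(vaf_tbl, K, n_restarts = n_restarts,
                         seed = child_seed(seed, K),
                         max_iter = max_iter, tol = tol)
  })
  bics <- purrr::map_dbl(fits, "bic")
  best <- fits[[which.min(bics)]]
  m <- vaf_matrices(vaf_tbl)

  refit_k <- function(init) {
    fit <- em_binomial_mixture(m$alt, m$depth, nrow(init), init,
                               max_iter = max_iter, tol = tol)
    n_par <- (nrow(init) - 1) + nrow(init) * ncol(m$alt)
    structure(list(
      K = nrow(init), pi = fit$pi, theta = fit$theta,
      assignment = tibble(variant_id = m$ids,
                          cluster = max.col(fit$resp, ties.method = "first")),
      resp = fit$resp, loglik = fit$loglik,
      bic = -2 * fit$loglik + n_par * log(nrow(m$alt)),
      converged = fit$converged, samples = m$samples,
      ll_trace = fit$ll_trace
    ), class = "vaf_mixture")
  }

  # backward-merge refinement: the K-wise search can miss a better model
  # one cluster down; refitting from pairwise-merged centres recovers it
  repeat {
    if (best$K <= 1) break
    improved <- FALSE
    pairs <- utils::combn(best$K, 2)
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1, p]; j <- pairs[2, p]
      w <- best$pi[c(i, j)] / sum(best$pi[c(i, j)])
      merged <- w[1] * best$theta[i, ] + w[2] * best$theta[j, ]
      init <- rbind(best$theta[-c(i, j), , drop = FALSE], merged)
      cand <- refit_k(init)
      if (cand$bic < best$bic) {
        best <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }

  # dissolve undersized outlier clusters and re-attach their members
  repeat {
    sizes <- tabulate(best$assignment$cluster, nbins = best$K)
    if (best$K <= 1 || min(sizes) >= min_cluster_size) break
    drop_k <- which.min(sizes)
    best <- refit_k(best$theta[-drop_k, , drop = FALSE])
  }
  attr(best, "bic_path") <- tibble(K = seq_len(K_hi), bic = bics)
  best
}

#' Estimate tumour purity from copy-number-neutral VAFs
#'
#' Clusters each sample's VAFs (restricted to copy-number-neutral diploid
#' variants) one-dimensionally and returns twice the median VAF of the
#' highest-mean cluster, clipped to (0, 1\].
#'
#' @param vaf_tbl long table `variant_id`, `sample`, `alt_count`, `depth`,
#'   already restricted to copy-number-neutral variants.
#' @param fallback named per-sample purity used (with a warning) when a
#'   sample has fewer than `min_variants` variants.
#' @param min_variants minimum variants required per sample (default 5).
#' @param K_max clusters considered in the 1-D pre-clustering.
#' @param min_weight smallest mixture weight a cluster may have and still
#'   anchor the purity estimate; the clonal cluster is expected to hold a
#'   sizeable share of the copy-number-neutral variants, so tiny
#'   high-mean noise clusters are skipped.
#' @param seed RNG seed.
#' @return named numeric vector of purities per sample.
#' @export
estimate_purity <- function(vaf_tbl, fallback = NULL, min_variants = 5,
                            K_max = 6, min_weight = 0.1, seed = 1) {
  vaf_tbl <- as_tibble(vaf_tbl)
  samples <- unique(vaf_tbl$sample)
  out <- setNames(numeric(length(samples)), samples)
  for (s in samples) {
    sub <- filter(vaf_tbl, .data$sample == s)
    if (nrow(sub) < min_variants) {
      assert_that(!is.null(fallback) && s %in% names(fallback),
                  sprintf("sample %s: too few neutral variants and no fallback purity", s))
      warn(sprintf("sample %s: too few neutral variants (%d); using fallback purity",
                   s, nrow(sub)))
      out[s] <- fallback[[s]]
      next
    }
    fit <- select_mixture_model(sub, K_max = min(K_max, nrow(sub)),
                                n_restarts = 5, seed = child_seed(seed, match(s, samples)))
    members <- fit$assignment$cluster
    eligible <- which(fit$pi >= min_weight)
    if (!length(eligible)) eligible <- seq_len(fit$K)
    top <- eligible[which.max(fit$theta[eligible, 1])]
    ids <- fit$assignment$variant_id[members == top]
    med <- median(sub$alt_count[sub$variant_id %in% ids] /
                    sub$depth[sub$variant_id %in% ids])
    out[s] <- min(1, max(2 * med, 1e-3))
  }
  out
}

#' Cellular fractions of mixture clusters
#'
#' Converts per-cluster per-sample binomial success probabilities to
#' cellular fractions `2 * theta / purity`, truncated to \[0, 1\].
#'
#' @param model a `vaf_mixture`.
#' @param purities named per-sample purity vector.
#' @return tibble: `cluster`, `sample`, `theta`, `cf`, `n_snvs`.
#' @export
cluster_cellular_fractions <- function(model, purities) {
  assert_that(inherits(model, "vaf_mixture"), "`model` must be a vaf_mixture")
  assert_that(all(model$samples %in% names(purities)),
              "every sample needs a purity")
  counts <- model$assignment %>% count(.data$cluster, name = "n_snvs")
  tidyr::expand_grid(cluster = seq_len(model$K),
                     sample = model$samples) %>%
    mutate(
      theta = model$theta[cbind(.data$cluster, match(.data$sample, model$samples))],
      cf = pmin(1, pmax(0, 2 * .data$theta / unname(purities[.data$sample])))
    ) %>%
    left_join(counts, by = "cluster") %>%
    mutate(n_snvs = tidyr::replace_na(.data$n_snvs, 0L))
}
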