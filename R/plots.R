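#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_text labs theme_minimal scale_fill_manual facet_wrap
#' @export
ggplot2::autoplot

#' Plot multi-sample VAF clusters
#'
#' Scatter of per-variant VAFs for a pair of samples, coloured by cluster.
#'
#' @param object a `vaf_mixture`.
#' @param vaf_tbl the long count table the model was fitted to.
#' @param samples length-2 character: samples for the x and y axes
#'   (defaults to the first two).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot vaf_mixture
#' @export
autoplot.vaf_mixture <- function(object, vaf_tbl, samples = NULL, ...) {
  vaf_tbl <- as_tibble(vaf_tbl)
  samples <- samples %||% head(object$samples, 2)
  assert_that(length(samples) == 2, "need two samples to plot")
  wide <- vaf_tbl %>%
    mutate(vaf = .data$alt_count / .data$depth) %>%
    select("variant_id", "sample", "vaf") %>%
    filter(.data$sample %in% samples) %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "vaf") %>%
    inner_join(object$assignment, by = "variant_id")
  ggplot(wide, aes(x = .data[[samples[1]]], y = .data[[samples[2]]],
                   colour = factor(.data$cluster))) +
    geom_point(alpha = 0.7) +
    labs(x = paste("VAF", samples[1]), y = paste("VAF", samples[2]),
         colour = "cluster") +
    theme_minimal()
}

#' Plot a clone tree
#'
#' Simple node-link layout; node size is the clone's SNV count, labels are
#' clone ids.
#'
#' @param object a `clone_tree`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot clone_tree
#' @export
autoplot.clone_tree <- function(object, ...) {
  assert_that(!isTRUE(object$insufficient_signal),
              "tree has insufficient signal")
  clones <- object$clones
  depth <- function(id) {
    d <- 0
    while (!is.na(id)) {
      id <- clones$parent[match(id, clones$clone)]
      d <- d + 1
    }
    d
  }
  lay <- clones %>%
    mutate(y = -purrr::map_dbl(.data$clone, depth)) %>%
    arrange(.data$y, .data$clone) %>%
    group_by(.data$y) %>%
    mutate(x = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2) %>%
    ungroup()
  edges <- lay %>%
    filter(!is.na(.data$parent)) %>%
    inner_join(select(lay, parent_clone = "clone", px = "x", py = "y"),
               by = c(parent = "parent_clone"))
  ggplot() +
    geom_segment(data = edges,
                 aes(x = .data$px, y = .data$py,
                     xend = .data$x, yend = .data$y)) +
    geom_point(data = lay, aes(x = .data$x, y = .data$y,
                               size = .data$n_snvs), colour = "steelblue") +
    geom_text(data = lay, aes(x = .data$x, y = .data$y,
                              label = .data$clone), vjust = -1.2) +
    labs(size = "SNVs", x = NULL, y = "depth in tree") +
    theme_minimal()
}

#' Plot phased haplotype-specific copy number along the genome
#'
#' @param phased tibble from [phase_haplotypes()].
#' @return a ggplot, one facet per sample.
#' @export
plot_phased_segments <- function(phased) {
  long <- phased %>%
    filter(!.data$unphased) %>%
    tidyr::pivot_longer(c("cnA", "cnB"), names_to = "haplotype",
                        values_to = "cn") %>%
    mutate(mid = (.data$start0 + .data$end0) / 2)
  ggplot(long, aes(x = .data$mid, y = .data$cn, colour = .data$haplotype)) +
    geom_segment(aes(x = .data$start0, xend = .data$end0,
                     yend = .data$cn)) +
    facet_wrap(~sample, ncol = 1) +
    labs(x = "genome position", y = "haplotype copy number") +
    theme_minimal()
}

#' Plot per-biopsy UHR classification as a tile matrix
#'
#' @param uhr_calls tibble from [classify_biopsy_uhr()].
#' @return a ggplot.
#' @export
plot_uhr_matrix <- function(uhr_calls) {
  long <- uhr_calls %>%
    tidyr::pivot_longer(c("tmm_positive", "uhr_mutation_present"),
                        names_to = "indicator", values_to = "value")
  ggplot(long, aes(x = .data$sample, y = .data$indicator,
                   fill = .data$value)) +
    geom_tile(colour = "white") +
    geom_text(data = uhr_calls,
              aes(x = .data$sample, y = 2.7, label = .data$classification),
              inherit.aes = FALSE, size = 3) +
    labs(x = NULL, y = NULL, fill = NULL) +
    theme_minimal()
}
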