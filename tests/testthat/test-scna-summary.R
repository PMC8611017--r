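mk_events <- function(rows) {
  # rows: list of c(segment_id, start0, end0, sample, cnA, cnB)
  purrr::map_dfr(rows, function(r) {
    tibble::tibble(segment_id = as.integer(r[[1]]), chrom = r[[7]],
                   start0 = as.numeric(r[[2]]), end0 = as.numeric(r[[3]]),
                   sample = r[[4]], cnA = as.integer(r[[5]]),
                   cnB = as.integer(r[[6]]), ploidy = 2)
  })
}

test_that("segment event classes follow the baseline rules", {
  seg <- tibble::tibble(
    segment_id = 1:6, sample = "S1",
    cnA = c(1L, 2L, 0L, 16L, 2L, 1L), cnB = c(1L, 0L, 0L, 1L, 1L, 0L),
    ploidy = 2
  )
  out <- classify_segment_events(seg)
  expect_equal(out$event,
               c("neutral",        # (1,1)
                 "loh",            # (2,0): copy-neutral LOH
                 "deep_loss",      # (0,0)
                 "amplification",  # (16,1)
                 "gain",           # (2,1)
                 "loh"))           # (1,0)
  # tetraploid baseline moves the thresholds
  seg4 <- tibble::tibble(segment_id = 1:2, sample = "S1",
                         cnA = c(3L, 5L), cnB = c(2L, 4L), ploidy = 4)
  expect_equal(classify_segment_events(seg4)$event,
               c("gain", "amplification"))
  # missing ploidy assumes diploid with a warning
  expect_warning(
    out2 <- classify_segment_events(
      tibble::tibble(segment_id = 1, sample = "S1", cnA = 2L, cnB = 1L)),
    "ploidy")
  expect_equal(out2$event, "gain")
})

test_that("cytoband aggregation applies the 50% coverage rule", {
  bands <- tibble::tibble(chrom = "chr1", start0 = c(0, 100), end0 = c(100, 200),
                          band = c("1p1", "1q1"))
  ev <- tibble::tibble(segment_id = 1:2, chrom = "chr1",
                       start0 = c(0, 100), end0 = c(100, 110),
                       sample = "S1", event = c("gain", "loh"))
  out <- aggregate_cytobands(ev, bands)
  expect_equal(nrow(out), 1)  # the 10%-covered band is not flagged
  expect_equal(out$band, "1p1")
  expect_equal(out$event, "gain")
  expect_error(
    aggregate_cytobands(dplyr::mutate(ev, chrom = "chrX"), bands),
    "do not match")
})

test_that("clonality stratification counts segments and genome fractions", {
  chr <- "chr1"
  # 4 segments x 2 samples; seg1 clonal gain, seg2 subclonal loh,
  # seg3 neutral, seg4 discordant classes -> subclonal
  rows <- list(
    list(1, 0, 100, "S1", 2, 1, chr), list(1, 0, 100, "S2", 2, 1, chr),
    list(2, 100, 200, "S1", 1, 0, chr), list(2, 100, 200, "S2", 1, 1, chr),
    list(3, 200, 300, "S1", 1, 1, chr), list(3, 200, 300, "S2", 1, 1, chr),
    list(4, 300, 400, "S1", 2, 1, chr), list(4, 300, 400, "S2", 1, 0, chr)
  )
  ev <- classify_segment_events(mk_events(rows))
  out <- stratify_scna_clonality(ev)
  expect_equal(out$n_clonal, 1)
  expect_equal(out$n_subclonal, 2)
  expect_equal(out$pct_clonal, 25)
  expect_equal(out$pct_subclonal, 50)
  expect_equal(out$pct_affected, 75)

  # all samples identical and altered -> no subclonal segments
  rows2 <- list(
    list(1, 0, 100, "S1", 2, 1, chr), list(1, 0, 100, "S2", 2, 1, chr),
    list(2, 100, 200, "S1", 1, 0, chr), list(2, 100, 200, "S2", 1, 0, chr)
  )
  out2 <- stratify_scna_clonality(classify_segment_events(mk_events(rows2)))
  expect_equal(out2$n_subclonal, 0)
  expect_equal(out2$pct_affected, 100)

  # length conservation: clonal% + subclonal% + unaffected% = 100
  expect_equal(out$pct_clonal + out$pct_subclonal +
                 (100 - out$pct_affected), 100, tolerance = 0.1)
})

test_that("stratification is invariant to sample order", {
  chr <- "chr2"
  rows <- list(
    list(1, 0, 100, "S1", 2, 1, chr), list(1, 0, 100, "S2", 1, 1, chr),
    list(2, 100, 200, "S1", 1, 0, chr), list(2, 100, 200, "S2", 1, 0, chr)
  )
  ev <- classify_segment_events(mk_events(rows))
  out_a <- stratify_scna_clonality(ev)
  out_b <- stratify_scna_clonality(dplyr::arrange(ev, dplyr::desc(.data$sample)))
  expect_equal(out_a, out_b)
})

test_that("chromosome classes separate whole-chromosome from segmental", {
  # chr1: full-length gain; chr2: focal gain; chr3: untouched
  rows <- list(
    list(1, 0, 1000, "S1", 2, 1, "chr1"),
    list(2, 0, 900, "S1", 1, 1, "chr2"), list(3, 900, 1000, "S1", 2, 1, "chr2"),
    list(4, 0, 1000, "S1", 1, 1, "chr3")
  )
  ev <- classify_segment_events(mk_events(rows))
  out <- classify_chromosomes(ev)
  cls <- stats::setNames(out$chromosomes$class, out$chromosomes$chrom)
  expect_equal(unname(cls["chr1"]), "whole_chromosome")
  expect_equal(unname(cls["chr2"]), "segmental")
  expect_equal(unname(cls["chr3"]), "unchanged")
  expect_equal(sum(unlist(out$fractions)), 1)
})

test_that("whole-chromosome-only cohorts have no segmental chromosomes", {
  tree <- simulate_clone_tree(4, seed = 31)
  cfg <- sim_config(n_clones = 4, whole_chromosome_event_fraction = 1,
                    cn_event_rate = 2, msai_probability = 0, seed = 31)
  cn <- simulate_cn_evolution(tree, cfg, seed = 31)
  prof <- cn$profiles %>%
    dplyr::inner_join(cn$genome, by = c("segment_id", "chrom")) %>%
    dplyr::mutate(sample = paste0("S", .data$clone), ploidy = 2)
  ev <- classify_segment_events(prof)
  out <- classify_chromosomes(ev)
  expect_equal(out$fractions$segmental, 0)
})

test_that("planted trunk events are clonal and branch events subclonal", {
  tree <- tibble::tibble(clone = 1:3, parent = c(NA, 1L, 1L))
  cfg <- sim_config(n_clones = 3, cn_event_rate = 2, msai_probability = 0,
                    seed = 37)
  cn <- simulate_cn_evolution(tree, cfg, seed = 37)
  # noise-free per-sample profiles: one sample per clone
  prof <- cn$profiles %>%
    dplyr::inner_join(cn$genome, by = c("segment_id", "chrom")) %>%
    dplyr::mutate(sample = paste0("S", .data$clone), ploidy = 2)
  ev <- classify_segment_events(prof)
  seg_cl <- ev %>%
    dplyr::group_by(.data$segment_id) %>%
    dplyr::summarise(
      clonal = dplyr::n_distinct(.data$event) == 1 &&
        .data$event[1] != "neutral",
      any_event = any(.data$event != "neutral"))
  trunk_ev <- dplyr::filter(cn$events, .data$clone == 1)
  for (i in seq_len(nrow(trunk_ev))) {
    segs <- trunk_ev$seg_start[i]:trunk_ev$seg_end[i]
    # trunk events are inherited by every clone: identical class everywhere
    expect_true(all(seg_cl$clonal[seg_cl$segment_id %in% segs] |
                      !seg_cl$any_event[seg_cl$segment_id %in% segs]))
  }
})

test_that("cohort medians reproduce the published per-patient summaries", {
  tbl <- readr::read_tsv(
    system.file("extdata", "scna_clonality_cohort.tsv", package = "mrclone"),
    show_col_types = FALSE)
  med <- clonality_table_medians(tbl)
  expect_equal(med$median_pct_affected, 34, tolerance = 0.5)
  expect_equal(med$median_n_subclonal, 57)
  expect_equal(med$median_n_clonal, 132)
})
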