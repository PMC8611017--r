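#' Classify copy-number events per segment and sample
#'
#' With baseline `b = round(ploidy)`: `deep_loss` when total copy number is
#' 0; `loh` when one haplotype is lost and the total stays at or below the
#' baseline (this includes copy-number-neutral LOH); `amplification` when
#' the total reaches `2b + 1`; `gain` for totals between baseline and
#' amplification; `neutral` otherwise.
#'
#' @param segments tibble with one row per segment x sample: `segment_id`,
#'   `sample`, `cnA`, `cnB` (or `cn_major`/`cn_minor` when unphased) and
#'   optionally `ploidy` per sample (assumed 2 with a warning if missing).
#' @return the tibble with an added `event` column.
#' @export
classify_segment_events <- function(segments) {
  segments <- as_tibble(segments)
  if (!all(c("cnA", "cnB") %in% names(segments))) {
    assert_that(all(c("cn_major", "cn_minor") %in% names(segments)),
                "need cnA/cnB or cn_major/cn_minor columns")
    segments$cnA <- segments$cn_major
    segments$cnB <- segments$cn_minor
  }
  if (!"ploidy" %in% names(segments) || anyNA(segments$ploidy)) {
    warn("missing ploidy; assuming diploid baseline")
    segments$ploidy <- dplyr::coalesce(segments[["ploidy"]] %||% NA_real_, 2)
  }
  # unphased segments fall back to major/minor (event class is orientation-free)
  if (all(c("cn_major", "cn_minor") %in% names(segments))) {
    segments <- segments %>%
      mutate(cnA = dplyr::coalesce(.data$cnA, .data$cn_major),
             cnB = dplyr::coalesce(.data$cnB, .data$cn_minor))
  }
  segments %>%
    mutate(
      b = round(.data$ploidy),
      total = .data$cnA + .data$cnB,
      event = dplyr::case_when(
        .data$total == 0 ~ "deep_loss",
        pmin(.data$cnA, .data$cnB) == 0 & .data$total >= 1 &
          .data$total <= .data$b ~ "loh",
        .data$total >= 2 * .data$b + 1 ~ "amplification",
        .data$total > .data$b ~ "gain",
        TRUE ~ "neutral"
      )
    ) %>%
    select(-"b", -"total")
}

#' Aggregate segment events onto cytobands
#'
#' A band carries an event class in a sample when events of that class
#' cover at least `min_coverage` (default 50%) of the band's length in that
#' sample. Multiple classes may coexist on a band and are reported as
#' separate rows.
#'
#' @param events classified segments (from [classify_segment_events()])
#'   with `chrom`, `start0`, `end0`, `sample`, `event`.
#' @param cytobands tibble `chrom`, `start0`, `end0`, `band`.
#' @param min_coverage fraction of the band that must be covered.
#' @return tibble: `band`, `chrom`, `sample`, `event`, `covered_fraction`.
#' @export
aggregate_cytobands <- function(events, cytobands, min_coverage = 0.5) {
  events <- as_tibble(events)
  cytobands <- as_tibble(cytobands)
  assert_that(all(c("chrom", "start0", "end0", "band") %in% names(cytobands)),
              "`cytobands` needs chrom, start0, end0, band")
  shared <- intersect(unique(events$chrom), unique(cytobands$chrom))
  assert_that(length(shared) > 0,
              "cytoband and segment chromosomes do not match")
  ev <- filter(events, .data$event != "neutral")
  if (nrow(ev) == 0) {
    return(tibble(band = character(), chrom = character(),
                  sample = character(), event = character(),
                  covered_fraction = numeric()))
  }
  ev %>%
    inner_join(cytobands, by = "chrom", suffix = c("", "_band"),
               relationship = "many-to-many") %>%
    mutate(ov = pmax(0, pmin(.data$end0, .data$end0_band) -
                       pmax(.data$start0, .data$start0_band))) %>%
    filter(.data$ov > 0) %>%
    group_by(.data$band, .data$chrom, .data$sample, .data$event,
             band_len = .data$end0_band - .data$start0_band) %>%
    summarise(covered = sum(.data$ov), .groups = "drop") %>%
    mutate(covered_fraction = .data$covered / .data$band_len) %>%
    filter(.data$covered_fraction >= min_coverage) %>%
    select("band", "chrom", "sample", "event", "covered_fraction")
}

#' Stratify copy-number events into clonal and subclonal
#'
#' A joint segment is *clonal* when the same non-neutral event class is
#' present in every sample of the patient, *subclonal* when a non-neutral
#' event appears in at least one but not with the same class in all
#' samples. Counts and the corresponding percentages of the tiled autosomal
#' genome are reported, plus the union-affected fraction.
#'
#' @param events classified joint segments: `segment_id`, `chrom`,
#'   `start0`, `end0`, `sample`, `event` (one row per segment x sample).
#' @return one-row tibble: `n_clonal`, `n_subclonal`, `pct_clonal`,
#'   `pct_subclonal`, `pct_affected`, `genome_length`.
#' @export
stratify_scna_clonality <- function(events) {
  events <- as_tibble(events)
  n_samples <- length(unique(events$sample))
  seg <- events %>%
    group_by(.data$segment_id, .data$chrom, .data$start0, .data$end0) %>%
    summarise(
      n_nonneutral = sum(.data$event != "neutral"),
      same_class = dplyr::n_distinct(.data$event) == 1 &&
        .data$event[1] != "neutral",
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    mutate(
      clonality = dplyr::case_when(
        .data$same_class & .data$n == n_samples ~ "clonal",
        .data$n_nonneutral > 0 ~ "subclonal",
        TRUE ~ "unaffected"
      ),
      len = .data$end0 - .data$start0
    )
  genome_length <- sum(seg$len)
  tibble(
    n_clonal = sum(seg$clonality == "clonal"),
    n_subclonal = sum(seg$clonality == "subclonal"),
    pct_clonal = 100 * sum(seg$len[seg$clonality == "clonal"]) / genome_length,
    pct_subclonal = 100 * sum(seg$len[seg$clonality == "subclonal"]) / genome_length,
    pct_affected = .data$pct_clonal + .data$pct_subclonal,
    genome_length = genome_length
  )
}

#' Per-patient medians of a clonality summary table
#'
#' Computes cohort medians of clonal segment counts, subclonal segment
#' counts and the union genome fraction (clonal % + subclonal %) from a
#' per-patient summary table.
#'
#' @param summary_tbl tibble with one row per patient: `n_clonal`,
#'   `n_subclonal`, `pct_clonal`, `pct_subclonal`.
#' @return one-row tibble: `median_pct_affected`, `median_n_subclonal`,
#'   `median_n_clonal`.
#' @export
clonality_table_medians <- function(summary_tbl) {
  summary_tbl <- as_tibble(summary_tbl)
  need <- c("n_clonal", "n_subclonal", "pct_clonal", "pct_subclonal")
  assert_that(all(need %in% names(summary_tbl)),
              "need n_clonal, n_subclonal, pct_clonal, pct_subclonal")
  tibble(
    median_pct_affected = median(summary_tbl$pct_clonal +
                                   summary_tbl$pct_subclonal),
    median_n_subclonal = median(summary_tbl$n_subclonal),
    median_n_clonal = median(summary_tbl$n_clonal)
  )
}

#' Classify chromosomes as unchanged, whole-chromosome or segmentally altered
#'
#' A chromosome is `unchanged` when no sample carries a non-neutral event on
#' it, `whole_chromosome` when every non-neutral event spans at least
#' `whole_fraction` (default 95%) of the chromosome length, and `segmental`
#' otherwise.
#'
#' @param events classified joint segments (as in
#'   [stratify_scna_clonality()]).
#' @param whole_fraction span threshold for whole-chromosome events.
#' @return list: `chromosomes` (tibble `chrom`, `class`) and `fractions`
#'   (one-row tibble of the three class fractions).
#' @export
classify_chromosomes <- function(events, whole_fraction = 0.95) {
  events <- as_tibble(events)
  chrom_len <- events %>%
    distinct(.data$chrom, .data$segment_id, .data$start0, .data$end0) %>%
    group_by(.data$chrom) %>%
    summarise(clen = sum(.data$end0 - .data$start0), .groups = "drop")

  # contiguous runs of the same non-neutral event within sample x chromosome
  runs <- events %>%
    filter(.data$event != "neutral") %>%
    group_by(.data$sample, .data$chrom) %>%
    arrange(.data$start0, .by_group = TRUE) %>%
    mutate(block = cumsum(dplyr::row_number() == 1 |
                            .data$event != dplyr::lag(.data$event, default = "") |
                            .data$start0 != dplyr::lag(.data$end0, default = -1))) %>%
    group_by(.data$sample, .data$chrom, .data$event, .data$block) %>%
    summarise(span = sum(.data$end0 - .data$start0), .groups = "drop")

  run_summary <- runs %>%
    inner_join(chrom_len, by = "chrom") %>%
    group_by(.data$chrom) %>%
    summarise(any_event = dplyr::n() > 0,
              all_whole = all(.data$span >= whole_fraction * .data$clen),
              .groups = "drop")
  chroms <- chrom_len %>%
    left_join(run_summary, by = "chrom") %>%
    mutate(class = dplyr::case_when(
      is.na(.data$any_event) ~ "unchanged",
      .data$all_whole ~ "whole_chromosome",
      TRUE ~ "segmental"
    )) %>%
    select("chrom", "class")

  fractions <- tibble(
    unchanged = mean(chroms$class == "unchanged"),
    whole_chromosome = mean(chroms$class == "whole_chromosome"),
    segmental = mean(chroms$class == "segmental")
  )
  list(chromosomes = chroms, fractions = fractions)
}

#' Uniform synthetic cytoband table for the synthetic genome
#'
#' @param genome tibble `chrom`, `start0`, `end0` (segments or chromosome
#'   extents); bands are built as `n_bands` equal divisions per chromosome.
#' @param n_bands bands per chromosome.
#' @return tibble `chrom`, `start0`, `end0`, `band`.
#' @export
synthetic_cytobands <- function(genome, n_bands = 4) {
  genome %>%
    group_by(.data$chrom) %>%
    summarise(cstart = min(.data$start0), cend = max(.data$end0),
              .groups = "drop") %>%
    purrr::pmap_dfr(function(chrom, cstart, cend) {
      bounds <- round(seq(cstart, cend, length.out = n_bands + 1))
      arm <- c(rep("p", ceiling(n_bands / 2)), rep("q", floor(n_bands / 2)))
      tibble(chrom = chrom,
             start0 = bounds[-(n_bands + 1)], end0 = bounds[-1],
             band = paste0(sub("chr", "", chrom), arm,
                           c(seq_len(ceiling(n_bands / 2)),
                             seq_len(floor(n_bands / 2)))))
    })
}
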