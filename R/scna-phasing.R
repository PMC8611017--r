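#' Joint consistent segmentation across a patient's samples
#'
#' Takes per-sample allele-specific segment tables, forms the union of
#' breakpoints per chromosome, carries each sample's copy-number states onto
#' the refined intervals, and merges back adjacent intervals whose states
#' agree in every sample.
#'
#' @param segments long tibble: `sample`, `chrom`, `start0`, `end0`
#'   (0-based half-open), `cn_major`, `cn_minor` (integer states; per-sample
#'   segments must tile each chromosome without overlap).
#' @return tibble of joint segments: `segment_id`, `chrom`, `start0`,
#'   `end0`, plus per-sample states in long form columns `sample`,
#'   `cn_major`, `cn_minor` (one row per segment x sample).
#' @export
joint_segment <- function(segments) {
  segments <- as_tibble(segments)
  need <- c("sample", "chrom", "start0", "end0", "cn_major", "cn_minor")
  assert_that(all(need %in% names(segments)),
              "`segments` needs sample, chrom, start0, end0, cn_major, cn_minor")
  assert_that(nrow(segments) > 0, "empty segment table")
  # overlap check within each sample/chromosome
  segments %>%
    group_by(.data$sample, .data$chrom) %>%
    arrange(.data$start0, .by_group = TRUE) %>%
    group_walk(function(g, key) {
      if (nrow(g) > 1) {
        assert_that(all(g$start0[-1] >= g$end0[-nrow(g)]),
                    sprintf("overlapping segments in sample %s, %s",
                            key$sample, key$chrom))
      }
    })

  samples <- unique(segments$sample)
  out <- segments %>%
    group_by(.data$chrom) %>%
    group_modify(function(g, key) {
      bp <- sort(unique(c(g$start0, g$end0)))
      refined <- tibble(start0 = bp[-length(bp)], end0 = bp[-1])
      per <- purrr::map_dfr(samples, function(s) {
        gs <- filter(g, .data$sample == s)
        idx <- purrr::map_int(refined$start0, function(x) {
          w <- which(gs$start0 <= x & gs$end0 > x)
          if (length(w)) w[1] else NA_integer_
        })
        tibble(sample = s, start0 = refined$start0, end0 = refined$end0,
               cn_major = gs$cn_major[idx], cn_minor = gs$cn_minor[idx])
      })
      # drop refined intervals not covered by every sample
      keep <- per %>%
        group_by(.data$start0) %>%
        summarise(ok = !anyNA(.data$cn_major), .groups = "drop")
      per <- semi_join(per, filter(keep, .data$ok), by = "start0")
      # merge back adjacent intervals identical in all samples
      state <- per %>%
        arrange(.data$sample, .data$start0) %>%
        group_by(.data$start0, .data$end0) %>%
        summarise(key = paste(.data$sample, .data$cn_major, .data$cn_minor,
                              collapse = ";"), .groups = "drop") %>%
        arrange(.data$start0) %>%
        mutate(block = cumsum(dplyr::row_number() == 1 |
                                .data$key != dplyr::lag(.data$key, default = "") |
                                .data$start0 != dplyr::lag(.data$end0, default = -1)))
      blocks <- state %>%
        group_by(.data$block) %>%
        summarise(start0 = min(.data$start0), end0 = max(.data$end0),
                  .groups = "drop")
      per %>%
        inner_join(select(state, "start0", "block"), by = "start0") %>%
        group_by(.data$sample, .data$block) %>%
        summarise(start0 = min(.data$start0), end0 = max(.data$end0),
                  cn_major = .data$cn_major[1], cn_minor = .data$cn_minor[1],
                  .groups = "drop") %>%
        select(-"block")
    }) %>%
    ungroup()

  ids <- out %>%
    distinct(.data$chrom, .data$start0, .data$end0) %>%
    arrange(match(.data$chrom, unique(segments$chrom)), .data$start0) %>%
    mutate(segment_id = dplyr::row_number())
  out %>%
    inner_join(ids, by = c("chrom", "start0", "end0")) %>%
    arrange(.data$segment_id, .data$sample) %>%
    select("segment_id", "chrom", "start0", "end0", "sample",
           "cn_major", "cn_minor")
}

# two-sided exact binomial p-value for pooled B counts vs 0.5
binom_p <- function(b, d) {
  if (d == 0) return(1)
  stats::binom.test(b, d, p = 0.5)$p.value
}

#' Multi-region reference phasing of allele-specific copy number
#'
#' For each joint segment with enough heterozygous SNPs, the sample with the
#' strongest significant allelic imbalance (exact binomial test of pooled
#' B counts vs 0.5 at `p_threshold`; reference score `|BAF - 0.5| *
#' sqrt(depth)`) anchors the phase: SNP alleles with BAF > 0.5 in the
#' reference are assigned to the amplified haplotype, called A. Every
#' sample's phased haplotype-A BAF is then computed on this fixed phase and
#' `(cnA, cnB)` is assigned by orienting `(cn_major, cn_minor)` to the
#' haplotype with the higher phased BAF. Segments with no imbalanced sample
#' are left unphased.
#'
#' @param joint tibble from [joint_segment()].
#' @param snp_baf tibble `chrom`, `pos`, `sample`, `b_count`, `depth`.
#' @param min_snps minimum het SNPs per segment (default 10).
#' @param p_threshold significance level for allelic imbalance (default 0.01).
#' @return tibble: one row per segment x sample with `segment_id`, `chrom`,
#'   `start0`, `end0`, `sample`, `cn_major`, `cn_minor`, `cnA`, `cnB`,
#'   `baf_a` (phased haplotype-A BAF), `n_snps`, `phase_p` (imbalance
#'   p-value), `imbalanced`, `favoured_hap`, `unphased`.
#' @export
phase_haplotypes <- function(joint, snp_baf, min_snps = 10,
                             p_threshold = 0.01) {
  joint <- as_tibble(joint)
  snp_baf <- as_tibble(snp_baf)[, c("chrom", "pos", "sample", "b_count", "depth")]
  segs <- distinct(joint, .data$segment_id, .data$chrom, .data$start0, .data$end0)
  # locate SNPs in segments
  snp <- snp_baf %>%
    inner_join(segs, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$start0, .data$pos < .data$end0) %>%
    select("segment_id", "pos", "sample", "b_count", "depth")

  purrr::map_dfr(segs$segment_id, function(sid) {
    seg_rows <- filter(joint, .data$segment_id == sid)
    ssnp <- filter(snp, .data$segment_id == sid)
    n_snps <- length(unique(ssnp$pos))
    base <- seg_rows %>%
      mutate(cnA = NA_integer_, cnB = NA_integer_, baf_a = NA_real_,
             n_snps = n_snps, phase_p = NA_real_, imbalanced = FALSE,
             favoured_hap = NA_character_, unphased = TRUE)
    if (n_snps < min_snps) return(base)

    pooled <- ssnp %>%
      group_by(.data$sample) %>%
      summarise(b = sum(.data$b_count), d = sum(.data$depth), .groups = "drop") %>%
      mutate(p = purrr::map2_dbl(.data$b, .data$d, binom_p),
             score = abs(.data$b / .data$d - 0.5) * sqrt(.data$d))
    sig <- filter(pooled, .data$p < p_threshold)
    if (nrow(sig) == 0) return(base)
    ref <- sig$sample[which.max(sig$score)]

    # per-SNP phase from the reference: BAF > 0.5 -> B allele on haplotype A
    ref_snp <- filter(ssnp, .data$sample == ref) %>%
      mutate(flip = .data$b_count / .data$depth <= 0.5) %>%
      select("pos", "flip")
    phased <- ssnp %>%
      inner_join(ref_snp, by = "pos") %>%
      mutate(a_count = ifelse(.data$flip, .data$depth - .data$b_count,
                              .data$b_count)) %>%
      group_by(.data$sample) %>%
      summarise(a = sum(.data$a_count), d = sum(.data$depth), .groups = "drop") %>%
      mutate(baf_a = .data$a / .data$d,
             phase_p = purrr::map2_dbl(.data$a, .data$d, binom_p),
             imbalanced = .data$phase_p < p_threshold,
             favoured_hap = dplyr::case_when(
               !.data$imbalanced ~ NA_character_,
               .data$baf_a > 0.5 ~ "A",
               TRUE ~ "B"
             ))

    seg_rows %>%
      left_join(select(phased, "sample", "baf_a", "phase_p", "imbalanced",
                       "favoured_hap"), by = "sample") %>%
      mutate(
        n_snps = n_snps,
        cnA = ifelse(!is.na(.data$baf_a) & .data$baf_a >= 0.5,
                     .data$cn_major, .data$cn_minor),
        cnB = ifelse(!is.na(.data$baf_a) & .data$baf_a >= 0.5,
                     .data$cn_minor, .data$cn_major),
        unphased = is.na(.data$baf_a),
        cnA = ifelse(.data$unphased, NA_integer_, .data$cnA),
        cnB = ifelse(.data$unphased, NA_integer_, .data$cnB)
      )
  })
}

#' Phasing-based correction of copy-number orientation
#'
#' Where a sample's phased haplotype-A BAF significantly contradicts its
#' `(cnA, cnB)` orientation, the orientation is flipped. Total copy number
#' is never altered.
#'
#' @param phased tibble from [phase_haplotypes()].
#' @return the tibble with corrected `cnA`, `cnB` and a logical `corrected`.
#' @export
correct_cn_states <- function(phased) {
  phased %>%
    mutate(
      contradicts = !.data$unphased & .data$imbalanced &
        ((.data$favoured_hap == "A" & .data$cnA < .data$cnB) |
           (.data$favoured_hap == "B" & .data$cnB < .data$cnA)),
      cnA_new = ifelse(.data$contradicts, .data$cnB, .data$cnA),
      cnB_new = ifelse(.data$contradicts, .data$cnA, .data$cnB),
      cnA = .data$cnA_new, cnB = .data$cnB_new,
      corrected = .data$contradicts
    ) %>%
    select(-"cnA_new", -"cnB_new", -"contradicts")
}

#' Detect mirrored subclonal allelic imbalance (MSAI)
#'
#' Emits an event for every joint segment where at least one sample shows
#' significant allelic imbalance favouring haplotype A and at least one
#' favouring haplotype B (each at the phasing p-value threshold, with at
#' least `min_snps` SNPs). Parallel gains of opposite parental haplotypes
#' in different tumour regions are evidence of parallel evolution.
#'
#' @param phased tibble from [phase_haplotypes()] (optionally corrected).
#' @param min_snps minimum SNPs supporting the segment.
#' @return tibble: `segment_id`, `chrom`, `start0`, `end0`, `samples_a`,
#'   `samples_b` (comma-separated), `n_snps`, `min_p`.
#' @export
detect_msai <- function(phased, min_snps = 10) {
  cand <- phased %>%
    filter(!.data$unphased, .data$imbalanced, .data$n_snps >= min_snps)
  if (nrow(cand) == 0) {
    return(tibble(segment_id = integer(), chrom = character(),
                  start0 = numeric(), end0 = numeric(),
                  samples_a = character(), samples_b = character(),
                  n_snps = integer(), min_p = numeric()))
  }
  cand %>%
    group_by(.data$segment_id, .data$chrom, .data$start0, .data$end0) %>%
    summarise(
      samples_a = paste(sort(.data$sample[.data$favoured_hap == "A"]),
                        collapse = ","),
      samples_b = paste(sort(.data$sample[.data$favoured_hap == "B"]),
                        collapse = ","),
      n_snps = .data$n_snps[1],
      min_p = min(.data$phase_p),
      .groups = "drop"
    ) %>%
    filter(.data$samples_a != "", .data$samples_b != "")
}
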