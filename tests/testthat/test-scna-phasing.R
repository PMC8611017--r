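test_that("joint segmentation unions breakpoints and merges back", {
  # identical segmentation in both samples is returned unchanged
  s1 <- seg_tbl("S1", "chr1", c(0, 50, 100), c(2, 3), c(1, 1))
  s2 <- seg_tbl("S2", "chr1", c(0, 50, 100), c(2, 2), c(1, 0))
  js <- joint_segment(dplyr::bind_rows(s1, s2))
  expect_equal(dplyr::n_distinct(js$segment_id), 2)
  expect_equal(sort(unique(js$start0)), c(0, 50))

  # breakpoints at 50 and 70 refine to three joint segments
  a <- seg_tbl("S1", "chr1", c(0, 50, 100), c(2, 3), c(1, 1))
  b <- seg_tbl("S2", "chr1", c(0, 70, 100), c(2, 1), c(1, 0))
  js2 <- joint_segment(dplyr::bind_rows(a, b))
  segs <- dplyr::distinct(js2, .data$start0, .data$end0)
  expect_equal(segs$start0, c(0, 50, 70))
  expect_equal(segs$end0, c(50, 70, 100))
  # states carried onto refined intervals
  expect_equal(js2$cn_major[js2$sample == "S1" & js2$start0 == 50], 3)
  expect_equal(js2$cn_major[js2$sample == "S2" & js2$start0 == 50], 2)

  # merge-back: refined pieces equal everywhere re-merge
  c1 <- seg_tbl("S1", "chr1", c(0, 30, 100), c(2, 2), c(1, 1))
  c2 <- seg_tbl("S2", "chr1", c(0, 60, 100), c(2, 2), c(1, 1))
  js3 <- joint_segment(dplyr::bind_rows(c1, c2))
  expect_equal(dplyr::n_distinct(js3$segment_id), 1)

  # overlapping input segments are rejected
  bad <- seg_tbl("S1", "chr1", c(0, 60, 100), c(2, 2), c(1, 1))
  bad$start0[2] <- 40
  expect_error(joint_segment(bad), "overlapping")
})

test_that("balanced segments stay unphased and produce no MSAI", {
  joint <- dplyr::bind_rows(
    seg_tbl("S1", "chr1", c(0, 100), 1, 1),
    seg_tbl("S2", "chr1", c(0, 100), 1, 1)
  ) %>% dplyr::mutate(segment_id = 1L)
  baf <- dplyr::bind_rows(
    snp_baf_tbl("S1", "chr1", seq(5, 95, by = 2), 0.5, seed = 2),
    snp_baf_tbl("S2", "chr1", seq(5, 95, by = 2), 0.5, seed = 3)
  )
  ph <- phase_haplotypes(joint, baf)
  expect_true(all(ph$unphased))
  expect_equal(nrow(detect_msai(ph)), 0)
})

test_that("a 3:1 imbalance anchors the phase at BAF about 0.75", {
  joint <- dplyr::bind_rows(
    seg_tbl("S1", "chr1", c(0, 5100), 3, 1),
    seg_tbl("S2", "chr1", c(0, 5100), 1, 1)
  ) %>% dplyr::mutate(segment_id = 1L)
  pos <- seq(100, 5000, by = 100)  # 50 SNPs
  baf <- dplyr::bind_rows(
    snp_baf_tbl("S1", "chr1", pos, 0.75, depth = 100, seed = 4),
    snp_baf_tbl("S2", "chr1", pos, 0.50, depth = 100, seed = 5)
  )
  ph <- phase_haplotypes(joint, baf, min_snps = 10)
  s1 <- ph[ph$sample == "S1", ]
  expect_false(s1$unphased)
  expect_true(s1$imbalanced)
  expect_equal(s1$baf_a, 0.75, tolerance = 0.03)
  expect_equal(s1$cnA, 3)
  expect_equal(s1$cnB, 1)
})

test_that("opposite-haplotype gains phase to mirrored BAFs", {
  joint <- dplyr::bind_rows(
    seg_tbl("S1", "chr1", c(0, 5100), 2, 1),
    seg_tbl("S2", "chr1", c(0, 5100), 2, 1)
  ) %>% dplyr::mutate(segment_id = 1L)
  pos <- seq(100, 5000, by = 100)
  # B allele oriented to haplotype B: S1 gains A (BAF_B 1/3), S2 gains B (2/3)
  baf <- dplyr::bind_rows(
    snp_baf_tbl("S1", "chr1", pos, 1 / 3, depth = 100, seed = 6),
    snp_baf_tbl("S2", "chr1", pos, 2 / 3, depth = 100, seed = 7)
  )
  ph <- phase_haplotypes(joint, baf, min_snps = 10)
  bafs <- sort(ph$baf_a)
  expect_equal(bafs, c(1 / 3, 2 / 3), tolerance = 0.05)
  ev <- detect_msai(ph)
  expect_equal(nrow(ev), 1)
  expect_true(ev$samples_a != "" && ev$samples_b != "")

  # single-sample imbalance never emits an event
  baf1 <- dplyr::bind_rows(
    snp_baf_tbl("S1", "chr1", pos, 1 / 3, depth = 100, seed = 8),
    snp_baf_tbl("S2", "chr1", pos, 0.5, depth = 100, seed = 9)
  )
  ph1 <- phase_haplotypes(joint, baf1, min_snps = 10)
  expect_equal(nrow(detect_msai(ph1)), 0)
})

test_that("phase assignment is invariant to global A/B relabelling", {
  joint <- dplyr::bind_rows(
    seg_tbl("S1", "chr1", c(0, 5100), 2, 1),
    seg_tbl("S2", "chr1", c(0, 5100), 2, 1)
  ) %>% dplyr::mutate(segment_id = 1L)
  pos <- seq(100, 5000, by = 100)
  baf <- dplyr::bind_rows(
    snp_baf_tbl("S1", "chr1", pos, 1 / 3, depth = 100, seed = 10),
    snp_baf_tbl("S2", "chr1", pos, 2 / 3, depth = 100, seed = 11)
  )
  flipped <- dplyr::mutate(baf, b_count = .data$depth - .data$b_count)
  ph <- phase_haplotypes(joint, baf, min_snps = 10)
  ph_f <- phase_haplotypes(joint, flipped, min_snps = 10)
  # canonical form: per-sample haplotype copy numbers as unordered pairs
  canon <- function(x) {
    x %>% dplyr::arrange(.data$sample) %>%
      dplyr::mutate(lo = pmin(.data$cnA, .data$cnB),
                    hi = pmax(.data$cnA, .data$cnB)) %>%
      dplyr::select("sample", "lo", "hi")
  }
  expect_equal(canon(ph), canon(ph_f))
  # mirrored events survive relabelling
  expect_equal(nrow(detect_msai(ph)), nrow(detect_msai(ph_f)))
})

test_that("orientation correction flips contradictions, conserving totals", {
  ph <- tibble::tibble(
    segment_id = 1L, chrom = "chr1", start0 = 0, end0 = 100,
    sample = c("S1", "S2"),
    cn_major = c(2, 2), cn_minor = c(1, 1),
    cnA = c(2L, 1L), cnB = c(1L, 2L),
    baf_a = c(0.33, 0.33), n_snps = 50,
    phase_p = c(1e-6, 1e-6), imbalanced = TRUE,
    favoured_hap = "B", unphased = FALSE
  )
  out <- correct_cn_states(ph)
  # S1 contradicted (cnA > cnB but B favoured) -> flipped
  expect_equal(out$cnA[1], 1L)
  expect_equal(out$cnB[1], 2L)
  expect_true(out$corrected[1])
  # S2 already consistent -> unchanged
  expect_equal(out$cnA[2], 1L)
  expect_false(out$corrected[2])
  expect_equal(out$cnA + out$cnB, ph$cnA + ph$cnB)
})

test_that("MSAI detection hits the stated operating point", {
  # 100 planted mirrored events: 2 samples gain A, 2 gain B; purity 0.7,
  # 50 SNPs per segment at depth 100
  rho <- 0.7
  n_snp <- 50
  mk_seg <- function(sid, cns, seed) {
    joint <- purrr::imap_dfr(cns, function(cn, s) {
      tibble::tibble(segment_id = sid, chrom = "chr1",
                     start0 = (sid - 1) * 1e5, end0 = sid * 1e5, sample = s,
                     cn_major = max(cn), cn_minor = min(cn))
    })
    baf <- purrr::imap_dfr(cns, function(cn, s) {
      bB <- (rho * cn[2] + (1 - rho)) / (rho * sum(cn) + 2 * (1 - rho))
      snp_baf_tbl(s, "chr1", (sid - 1) * 1e5 + seq_len(n_snp) * 1000, bB,
                  depth = 100, seed = seed + match(s, names(cns)))
    })
    list(joint = joint, baf = baf)
  }
  planted <- lapply(1:100, function(i) {
    mk_seg(i, list(S1 = c(2, 1), S2 = c(2, 1), S3 = c(1, 2), S4 = c(1, 2)),
           seed = 1000 + 10 * i)
  })
  joint <- dplyr::bind_rows(lapply(planted, `[[`, "joint"))
  baf <- dplyr::bind_rows(lapply(planted, `[[`, "baf"))
  ph <- phase_haplotypes(joint, baf, min_snps = 10, p_threshold = 0.01)
  ev <- detect_msai(ph, min_snps = 10)
  expect_gte(nrow(ev) / 100, 0.9)

  # null: 1000 balanced segment-samples -> false events within the p = 0.01
  # budget (events need opposite significant calls on one segment)
  null <- lapply(1:100, function(i) {
    mk_seg(i, stats::setNames(rep(list(c(1, 1)), 10), paste0("S", 1:10)),
           seed = 5000 + 20 * i)
  })
  joint0 <- dplyr::bind_rows(lapply(null, `[[`, "joint"))
  baf0 <- dplyr::bind_rows(lapply(null, `[[`, "baf"))
  ph0 <- phase_haplotypes(joint0, baf0, min_snps = 10, p_threshold = 0.01)
  ev0 <- detect_msai(ph0, min_snps = 10)
  # per segment, about a 0.2% chance of opposite significant pairs; allow
  # a generous Poisson upper bound on 100 segments
  expect_lte(nrow(ev0), 4)
})
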