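test_that("clone-tree simulation covers the trivial and deterministic cases", {
  t1 <- simulate_clone_tree(1, seed = 1)
  expect_equal(nrow(t1), 1)
  expect_true(is.na(t1$parent[1]))

  t2 <- simulate_clone_tree(2, seed = 99)
  expect_equal(t2$parent, c(NA, 1L))

  a <- simulate_clone_tree(5, seed = 7)
  b <- simulate_clone_tree(5, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_clone_tree(0), "integer >= 1")

  # both linear and branched shapes are reachable
  shapes <- vapply(1:40, function(s) {
    tr <- simulate_clone_tree(4, seed = s)
    max(table(tr$parent))
  }, 1)
  expect_true(any(shapes == 1))  # chain
  expect_true(any(shapes > 1))   # branching
})

test_that("CCF matrices are lineage-consistent with planted designs honoured", {
  tree <- simulate_clone_tree(1, seed = 1)
  ccf <- simulate_ccf_matrix(tree, 3, seed = 1)
  expect_equal(unname(ccf), matrix(1, 1, 3))

  tree5 <- simulate_clone_tree(5, seed = 3)
  ccf5 <- simulate_ccf_matrix(tree5, 4, seed = 3)
  for (i in seq_len(nrow(tree5))) {
    p <- tree5$parent[i]
    if (!is.na(p)) expect_true(all(ccf5[i, ] <= ccf5[p, ] + 1e-9))
  }
  # sibling sums never exceed the parent
  kids <- split(tree5$clone, tree5$parent)
  for (p in names(kids)) {
    expect_true(all(colSums(ccf5[kids[[p]], , drop = FALSE]) <=
                      ccf5[as.integer(p), ] + 1e-9))
  }

  # fixed design replay
  chain <- tibble::tibble(clone = 1:3, parent = c(NA, 1L, 2L))
  planted <- rbind(1.0, 0.6, 0.2)
  got <- simulate_ccf_matrix(chain, 1, fixed_ccf = planted)
  expect_equal(unname(got), unname(planted))
  bad <- rbind(1.0, 0.2, 0.6)
  expect_error(simulate_ccf_matrix(chain, 1, fixed_ccf = bad),
               "lineage")
})

test_that("copy-number evolution respects irreversible loss and MSAI knobs", {
  tree <- simulate_clone_tree(6, seed = 5)
  cfg0 <- sim_config(n_clones = 6, msai_probability = 0, seed = 5)
  cn0 <- simulate_cn_evolution(tree, cfg0, seed = 5)
  expect_equal(nrow(cn0$msai_truth), 0)

  cfg1 <- sim_config(n_clones = 6, msai_probability = 0.3,
                     cn_event_rate = 2, seed = 6)
  cn1 <- simulate_cn_evolution(tree, cfg1, seed = 6)
  # loss irreversibility along every lineage
  prof <- cn1$profiles
  for (i in tree$clone) {
    p <- tree$parent[match(i, tree$clone)]
    if (is.na(p)) next
    pp <- dplyr::filter(prof, .data$clone == p)
    cc <- dplyr::filter(prof, .data$clone == i)
    expect_true(all(!(pp$cnA == 0 & cc$cnA > 0)))
    expect_true(all(!(pp$cnB == 0 & cc$cnB > 0)))
  }
  # planted MSAI shows opposite-haplotype imbalance in the two clades
  if (nrow(cn1$msai_truth) > 0) {
    ev <- cn1$msai_truth[1, ]
    a <- dplyr::filter(prof, .data$clone == ev$clone_a,
                       .data$segment_id == ev$segment_id)
    b <- dplyr::filter(prof, .data$clone == ev$clone_b,
                       .data$segment_id == ev$segment_id)
    expect_gt(a$cnA, a$cnB)
    expect_gt(b$cnB, b$cnA)
  }

  # whole-chromosome fraction 1 never yields segmental chromosomes
  cfg2 <- sim_config(n_clones = 6, whole_chromosome_event_fraction = 1,
                     cn_event_rate = 2, msai_probability = 0, seed = 7)
  cn2 <- simulate_cn_evolution(tree, cfg2, seed = 7)
  expect_false(any(cn2$chromosome_events$type == "segmental"))
})

test_that("read simulation matches the closed-form expected VAF", {
  # clonal het SNV, purity 0.6, diploid: expected VAF 0.30
  chain <- tibble::tibble(clone = 1L, parent = NA_integer_)
  cfg <- sim_config(n_clones = 1, n_trunk_snvs = 40,
                    n_branch_snvs_per_clone = 1, cn_event_rate = 0,
                    msai_probability = 0, mean_coverage_wes = 400, seed = 8)
  ccf <- matrix(1, 1, 2)
  cn <- simulate_cn_evolution(chain, cfg, seed = 8)
  tabs <- simulate_reads(list(tree = chain, ccf = ccf, cn = cn), cfg,
                         seed = 8, purity = c(S1 = 0.6, S2 = 1.0))
  v <- tabs$variants
  m1 <- with(v[v$sample == "S1", ], sum(alt_count) / sum(depth))
  m2 <- with(v[v$sample == "S2", ], sum(alt_count) / sum(depth))
  n_reads <- sum(v$depth[v$sample == "S1"])
  se <- sqrt(0.3 * 0.7 / n_reads)
  expect_lt(abs(m1 - 0.30), 3 * se)   # within 3 standard errors
  expect_lt(abs(m2 - 0.50), 3 * sqrt(0.25 / n_reads))

  # balanced diploid segments give phased BAF about one half
  baf <- tabs$snp_baf
  pooled <- sum(baf$b_count) / sum(baf$depth)
  expect_lt(abs(pooled - 0.5), 3 * sqrt(0.25 / sum(baf$depth)))
})

test_that("cohort writing round-trips through loading", {
  co <- simulate_cohort(sim_config(n_samples = 2, n_clones = 3,
                                   n_trunk_snvs = 6,
                                   n_branch_snvs_per_clone = 3,
                                   n_segments = 22,
                                   n_het_snps_per_segment = 5, seed = 9))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- load_cohort(dir)
  expect_equal(nrow(back$variants), nrow(co$tables$variants))
  expect_equal(back$variants$alt_count, co$tables$variants$alt_count)
  expect_equal(back$segments$start0, co$tables$segments$start0)
  expect_equal(back$segments$end0, co$tables$segments$end0)
  expect_equal(back$snp_baf$b_count, co$tables$snp_baf$b_count)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$seed, 9)

  # byte-identical rerun under the same config
  dir2 <- withr::local_tempdir()
  co2 <- simulate_cohort(sim_config(n_samples = 2, n_clones = 3,
                                    n_trunk_snvs = 6,
                                    n_branch_snvs_per_clone = 3,
                                    n_segments = 22,
                                    n_het_snps_per_segment = 5, seed = 9))
  write_cohort(co2, dir2)
  for (f in c("variants.tsv", "segments.tsv", "snp_baf.tsv")) {
    expect_identical(readLines(file.path(dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("validation rejects malformed cohort tables", {
  co <- simulate_cohort(sim_config(n_samples = 2, n_clones = 2,
                                   n_trunk_snvs = 4,
                                   n_branch_snvs_per_clone = 2,
                                   n_segments = 22,
                                   n_het_snps_per_segment = 3, seed = 10))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  v <- readr::read_tsv(file.path(dir, "variants.tsv"),
                       show_col_types = FALSE)
  v$alt_count[2] <- v$depth[2] + 5
  readr::write_tsv(v, file.path(dir, "variants.tsv"))
  expect_error(load_cohort(dir), "alt_count > depth")

  write_cohort(co, dir)
  s <- readr::read_tsv(file.path(dir, "segments.tsv"),
                       show_col_types = FALSE)
  s$end[1] <- s$start[1] - 10
  readr::write_tsv(s, file.path(dir, "segments.tsv"))
  expect_error(load_cohort(dir), "end < start")
})

test_that("simulation configuration is validated", {
  expect_error(sim_config(n_clones = 0), "n_clones")
  expect_error(sim_config(purity_range = c(0, 1.2)), "purity_range")
  expect_error(sim_config(msai_probability = 1.5), "msai_probability")
})
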