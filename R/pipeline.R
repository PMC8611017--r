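#' Pipeline configuration
#'
#' Collects every stage threshold with its documented default. All
#' thresholds are echoed verbatim into the results of [run_pipeline()].
#'
#' @param t_cand candidate tumour VAF threshold (default 0.10).
#' @param t_ctrl matched-normal VAF ceiling (default 0.05).
#' @param p_max error-model tail probability (default 0.001).
#' @param t_clonal clonality presence anchor (default 0.10).
#' @param founding_cf founding-clone cellular fraction (default 0.90).
#' @param presence_cf clone presence cutoff (default 0.05).
#' @param uhr_vaf UHR mutation VAF threshold (default 0.05).
#' @param k_max maximum VAF clusters (default 20).
#' @param msai_p allelic-imbalance significance (default 0.01).
#' @param min_snps het SNPs required to phase a segment (default 10).
#' @param jackknife_replicates,jackknife_drop jackknife parameters.
#' @param n_restarts EM restarts.
#' @param seed master seed.
#' @param sim a [sim_config()] for the synthetic cohort stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(t_cand = 0.10, t_ctrl = 0.05, p_max = 0.001,
                            t_clonal = 0.10, founding_cf = 0.90,
                            presence_cf = 0.05, uhr_vaf = 0.05,
                            k_max = 20, msai_p = 0.01, min_snps = 10,
                            jackknife_replicates = 100, jackknife_drop = 0.5,
                            n_restarts = 10, seed = 1,
                            sim = sim_config(seed = seed)) {
  assert_prob(t_cand, "t_cand"); assert_prob(t_ctrl, "t_ctrl")
  assert_prob(p_max, "p_max"); assert_prob(t_clonal, "t_clonal")
  assert_prob(founding_cf, "founding_cf"); assert_prob(presence_cf, "presence_cf")
  assert_prob(uhr_vaf, "uhr_vaf"); assert_prob(msai_p, "msai_p")
  assert_prob(jackknife_drop, "jackknife_drop")
  assert_count(k_max, "k_max"); assert_count(min_snps, "min_snps")
  assert_count(jackknife_replicates, "jackknife_replicates")
  structure(list(
    t_cand = t_cand, t_ctrl = t_ctrl, p_max = p_max, t_clonal = t_clonal,
    founding_cf = founding_cf, presence_cf = presence_cf, uhr_vaf = uhr_vaf,
    k_max = k_max, msai_p = msai_p, min_snps = min_snps,
    jackknife_replicates = jackknife_replicates,
    jackknife_drop = jackknife_drop, n_restarts = n_restarts,
    seed = seed, sim = sim
  ), class = "pipeline_config")
}

#' Write a synthetic cohort to disk
#'
#' Writes the variant, normal, panel-of-normals, SNP-BAF, segment and
#' biopsy-profile tables as TSV (segment coordinates 1-based inclusive on
#' disk), the ground truth, and a JSON manifest with the configuration and
#' seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t <- cohort$tables
  seg_disk <- t$segments %>%
    mutate(start = .data$start0 + 1, end = .data$end0) %>%
    select("patient", "sample", "chrom", "start", "end",
           "cn_major", "cn_minor", "purity", "ploidy")
  files <- list(
    variants = "variants.tsv", normals = "normals.tsv",
    pon = "panel_of_normals.tsv", snp_baf = "snp_baf.tsv",
    segments = "segments.tsv", sample_info = "sample_info.tsv",
    biopsy_profiles = "biopsy_profiles.tsv"
  )
  readr::write_tsv(t$variants, file.path(out_dir, files$variants))
  readr::write_tsv(t$normals, file.path(out_dir, files$normals))
  readr::write_tsv(t$pon, file.path(out_dir, files$pon))
  readr::write_tsv(select(t$snp_baf, -"segment_id"),
                   file.path(out_dir, files$snp_baf))
  readr::write_tsv(seg_disk, file.path(out_dir, files$segments))
  readr::write_tsv(t$sample_info, file.path(out_dir, files$sample_info))
  readr::write_tsv(t$biopsy_profiles, file.path(out_dir, files$biopsy_profiles))

  gt_dir <- file.path(out_dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  readr::write_tsv(cohort$truth$tree, file.path(gt_dir, "clone_tree.tsv"))
  ccf_tbl <- as_tibble(cohort$truth$ccf, .name_repair = "minimal")
  names(ccf_tbl) <- cohort$tables$sample_info$sample
  ccf_tbl$clone <- cohort$truth$tree$clone
  readr::write_tsv(ccf_tbl, file.path(gt_dir, "ccf.tsv"))
  readr::write_tsv(cohort$truth$cn$profiles, file.path(gt_dir, "profiles.tsv"))
  readr::write_tsv(cohort$truth$cn$msai_truth, file.path(gt_dir, "msai.tsv"))
  readr::write_tsv(cohort$truth$cn$chromosome_events,
                   file.path(gt_dir, "chromosome_events.tsv"))
  readr::write_tsv(cohort$tables$snv_truth, file.path(gt_dir, "snv_truth.tsv"))

  manifest <- list(config = unclass(cohort$config),
                   seed = cohort$config$seed,
                   files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Load and validate a cohort directory
#'
#' Reads the tables written by [write_cohort()] with schema validation
#' (row-numbered errors) and converts on-disk 1-based inclusive segment
#' coordinates to the internal 0-based half-open convention.
#'
#' @param dir cohort directory.
#' @return list of validated tibbles mirroring [simulate_reads()] output.
#' @export
load_cohort <- function(dir) {
  assert_that(dir.exists(dir), sprintf("no such directory: %s", dir))
  rd <- function(f) readr::read_tsv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  variants <- rd("variants.tsv")
  bad <- which(variants$alt_count > variants$depth)
  assert_that(length(bad) == 0,
              sprintf("variants.tsv: alt_count > depth at row(s) %s",
                      paste(head(bad, 5), collapse = ", ")))
  segments <- rd("segments.tsv")
  bad <- which(segments$end < segments$start)
  assert_that(length(bad) == 0,
              sprintf("segments.tsv: end < start at row(s) %s",
                      paste(head(bad, 5), collapse = ", ")))
  segments <- segments %>%
    mutate(start0 = .data$start - 1, end0 = .data$end) %>%
    select(-"start", -"end")
  snp_baf <- rd("snp_baf.tsv")
  bad <- which(snp_baf$b_count > snp_baf$depth)
  assert_that(length(bad) == 0,
              sprintf("snp_baf.tsv: b_count > depth at row(s) %s",
                      paste(head(bad, 5), collapse = ", ")))
  list(
    variants = variants,
    normals = rd("normals.tsv"),
    pon = rd("panel_of_normals.tsv"),
    snp_baf = snp_baf,
    segments = segments,
    sample_info = rd("sample_info.tsv"),
    biopsy_profiles = rd("biopsy_profiles.tsv")
  )
}

# map each variant to the total copy number of its containing segment
variant_total_cn <- function(variants, segments) {
  seg <- segments %>%
    transmute(.data$sample, .data$chrom, .data$start0, .data$end0,
              c_t = .data$cn_major + .data$cn_minor)
  variants %>%
    left_join(seg, by = c("sample", "chrom"),
              relationship = "many-to-many") %>%
    filter(is.na(.data$start0) | (.data$pos > .data$start0 &
                                    .data$pos <= .data$end0)) %>%
    distinct(.data$variant_id, .data$sample, .keep_all = TRUE) %>%
    select(-"start0", -"end0")
}

#' Run the full multi-region analysis pipeline
#'
#' Simulates (or loads) a cohort, then runs somatic calling, clonality
#' stratification, VAF clustering, clone-tree reconstruction, joint
#' segmentation, haplotype phasing with MSAI detection, copy-number
#' summaries, the copy-number phylogeny with jackknife support, and
#' per-biopsy UHR classification. Fully deterministic under the master
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (as from [simulate_cohort()] or
#'   [load_cohort()]); simulated from `config$sim` when NULL.
#' @return object of class `mrclone_result`: a list of stage outputs plus
#'   the echoed configuration.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must be a pipeline_config")
  if (is.null(cohort)) cohort <- simulate_cohort(config$sim)
  t <- cohort$tables %||% cohort
  truth <- cohort$truth

  # --- somatic calling against the panel of normals ---
  pon_by_site <- t$pon %>%
    group_by(.data$variant_id) %>%
    summarise(controls = list(dplyr::pick("mismatch_count", "depth")),
              .groups = "drop")
  models <- purrr::map(pon_by_site$controls, fit_site_error_model)
  names(models) <- pon_by_site$variant_id

  norm <- t$normals %>% select("variant_id", n_alt = "alt_count", n_depth = "depth")
  calls <- t$variants %>%
    inner_join(norm, by = "variant_id") %>%
    (function(df) {
      res <- call_somatic_variant(
        tumour = tibble(alt_count = df$alt_count, depth = df$depth),
        normal = tibble(alt_count = df$n_alt, depth = df$n_depth),
        model = models[df$variant_id],
        t_cand = config$t_cand, t_ctrl = config$t_ctrl, p_max = config$p_max
      )
      bind_cols(df, res)
    })
  somatic_ids <- calls %>%
    filter(.data$status == "somatic") %>%
    distinct(.data$variant_id) %>% pull()

  # --- clonality stratification (purity / copy-number adjusted) ---
  purities <- setNames(t$sample_info$purity, t$sample_info$sample)
  vcn <- variant_total_cn(filter(t$variants, .data$variant_id %in% somatic_ids),
                          t$segments)
  clonality <- classify_clonality(
    vcn %>% transmute(.data$variant_id, .data$sample,
                      vaf = .data$alt_count / .data$depth, .data$c_t),
    purities, t_clonal = config$t_clonal
  )

  # --- VAF clustering on copy-number-neutral variants ---
  neutral_ids <- vcn %>%
    group_by(.data$variant_id) %>%
    summarise(neutral = all(.data$c_t == 2), .groups = "drop") %>%
    filter(.data$neutral) %>% pull(.data$variant_id)
  clust_tbl <- t$variants %>%
    filter(.data$variant_id %in% neutral_ids) %>%
    select("variant_id", "sample", "alt_count", "depth")
  est_purity <- estimate_purity(clust_tbl, fallback = purities,
                                seed = child_seed(config$seed, 11))
  mixture <- select_mixture_model(clust_tbl, K_max = config$k_max,
                                  n_restarts = config$n_restarts,
                                  seed = child_seed(config$seed, 12))
  cf <- cluster_cellular_fractions(mixture, est_purity)

  # --- clone tree ---
  clone_tree <- build_clone_tree(cf, founding_cf = config$founding_cf,
                                 presence_cf = config$presence_cf)
  sample_annotation <- if (!clone_tree$insufficient_signal) {
    annotate_samples(clone_tree)
  } else NULL

  # --- joint segmentation, phasing, MSAI ---
  joint <- joint_segment(t$segments)
  phased <- phase_haplotypes(joint, t$snp_baf, min_snps = config$min_snps,
                             p_threshold = config$msai_p)
  phased <- correct_cn_states(phased)
  msai <- detect_msai(phased, min_snps = config$min_snps)

  # --- copy-number summaries ---
  ploidies <- setNames(t$sample_info$ploidy, t$sample_info$sample)
  events <- phased %>%
    mutate(ploidy = unname(ploidies[.data$sample])) %>%
    classify_segment_events()
  scna_summary <- stratify_scna_clonality(events)
  chrom_class <- classify_chromosomes(events)
  cytobands <- synthetic_cytobands(distinct(events, .data$chrom, .data$start0,
                                            .data$end0))
  band_events <- aggregate_cytobands(events, cytobands)

  # --- copy-number phylogeny ---
  profiles <- events %>%
    mutate(cnA = dplyr::coalesce(.data$cnA, .data$cn_major),
           cnB = dplyr::coalesce(.data$cnB, .data$cn_minor)) %>%
    select("sample", "segment_id", "chrom", "cnA", "cnB")
  cn_tree <- NULL
  support <- NULL
  if (length(unique(profiles$sample)) >= 3) {
    jk <- jackknife_support(profiles,
                            n_replicates = config$jackknife_replicates,
                            drop_fraction = config$jackknife_drop,
                            seed = child_seed(config$seed, 13))
    cn_tree <- jk$tree
    support <- jk$support
  } else if (length(unique(profiles$sample)) == 2) {
    cn_tree <- build_cn_tree(profiles)
  }

  # --- UHR classification ---
  mycn_amp <- events %>%
    filter(.data$chrom == "chr2", .data$event == "amplification") %>%
    distinct(.data$sample) %>% pull()
  pathway_muts <- vcn %>%
    filter(.data$pathway %in% c("TP53", "RAS_MAPK")) %>%
    mutate(vaf = .data$alt_count / .data$depth) %>%
    group_by(.data$sample) %>%
    group_map(~ setNames(list(select(.x, "gene", "pathway", "vaf")),
                         .y$sample)) %>%
    purrr::flatten()
  bp <- t$biopsy_profiles %>%
    mutate(mycn_amplified = .data$sample %in% mycn_amp,
           pathway_mutations = purrr::map(.data$sample,
                                          ~ pathway_muts[[.x]]))
  uhr <- classify_biopsy_uhr(bp, uhr_vaf = config$uhr_vaf)
  uhr_patient <- patient_uhr_profile(uhr)

  structure(list(
    config = config,
    cohort = cohort,
    calls = calls,
    clonality = clonality,
    purity = est_purity,
    mixture = mixture,
    cluster_cf = cf,
    clone_tree = clone_tree,
    sample_annotation = sample_annotation,
    joint_segments = joint,
    phased = phased,
    msai = msai,
    segment_events = events,
    scna_summary = scna_summary,
    chromosome_classes = chrom_class,
    cytoband_events = band_events,
    cn_tree = cn_tree,
    jackknife = support,
    uhr = uhr,
    uhr_patient = uhr_patient
  ), class = "mrclone_result")
}

#' @export
print.mrclone_result <- function(x, ...) {
  cat("<mrclone_result>\n")
  cat(sprintf("  somatic SNVs: %d of %d candidate sites\n",
              dplyr::n_distinct(x$calls$variant_id[x$calls$status == "somatic"]),
              dplyr::n_distinct(x$calls$variant_id)))
  cat(sprintf("  clusters: K=%d; clones: %s\n", x$mixture$K,
              if (x$clone_tree$insufficient_signal) "insufficient signal"
              else nrow(x$clone_tree$clones)))
  cat(sprintf("  MSAI events: %d; UHR biopsies: %d/%d\n",
              nrow(x$msai), sum(x$uhr$classification == "UHR"), nrow(x$uhr)))
  invisible(x)
}

#' Figure-ready report tables from a pipeline result
#'
#' Emits the oncoplot-style per-sample SNV clonality counts, the per-patient
#' SCNA clonality summary, the chromosome class fractions, and the UHR
#' matrix. When `out_dir` is given the tables and a machine-readable
#' results JSON (with every threshold echoed) are written to disk.
#'
#' @param result an `mrclone_result`.
#' @param out_dir optional output directory.
#' @return list of tibbles: `snv_clonality`, `scna_clonality`,
#'   `chromosome_fractions`, `uhr_matrix`.
#' @export
write_report <- function(result, out_dir = NULL) {
  assert_that(inherits(result, "mrclone_result"),
              "`result` must be an mrclone_result")
  somatic <- result$calls %>% filter(.data$status == "somatic")
  snv_clonality <- somatic %>%
    inner_join(select(result$clonality, "variant_id", "category"),
               by = "variant_id") %>%
    group_by(.data$sample, .data$category) %>%
    summarise(n = dplyr::n(), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "category", values_from = "n",
                       values_fill = 0L)
  scna_clonality <- result$scna_summary
  chromosome_fractions <- result$chromosome_classes$fractions
  uhr_matrix <- result$uhr %>%
    select("sample", "tmm_positive", "uhr_mutation_present", "classification")

  out <- list(snv_clonality = snv_clonality,
              scna_clonality = scna_clonality,
              chromosome_fractions = chromosome_fractions,
              uhr_matrix = uhr_matrix)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(out, function(tbl, nm) {
      readr::write_tsv(tbl, file.path(out_dir, paste0(nm, ".tsv")))
    })
    results_json <- list(
      thresholds = unclass(result$config)[setdiff(names(result$config),
                                                  "sim")],
      sim = unclass(result$config$sim),
      seed = result$config$seed,
      n_somatic = sum(result$calls$status == "somatic"),
      snv_clonality = snv_clonality,
      scna_clonality = scna_clonality,
      chromosome_fractions = chromosome_fractions,
      n_msai = nrow(result$msai),
      uhr = uhr_matrix,
      newick = if (!result$clone_tree$insufficient_signal)
        tree_to_newick(result$clone_tree)$newick else NULL
    )
    jsonlite::write_json(results_json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
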