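#' Configuration for the synthetic multi-region cohort generator
#'
#' Defaults emulate the structure of a multi-region neuroblastoma study:
#' whole-exome coverage around 346x, ultra-deep targeted re-sequencing at
#' 2500x, biopsies macrodissected to purity above 0.6, and a handful of
#' spatially localised subclones per patient.
#'
#' @param n_samples biopsies per patient.
#' @param n_clones clones in the planted tree (including the founding clone).
#' @param n_trunk_snvs SNVs on the trunk (founding clone).
#' @param n_branch_snvs_per_clone SNVs per non-founding clone.
#' @param purity_range tumour cell content range, drawn uniformly per sample.
#' @param mean_coverage_wes,mean_coverage_targeted Poisson mean read depths.
#' @param n_segments copy-number segments tiling the 22-autosome synthetic
#'   genome (each autosome 100 Mb).
#' @param n_het_snps_per_segment germline heterozygous SNPs per segment.
#' @param cn_event_rate mean copy-number events per clone (Poisson).
#' @param msai_probability per-segment probability of a planted mirrored
#'   allelic-imbalance event (requires two incomparable clones).
#' @param whole_chromosome_event_fraction fraction of planted events that
#'   span a whole chromosome.
#' @param n_pon panel-of-normals samples.
#' @param error_rate technical mismatch rate per base in normal samples.
#' @param min_ccf_gap minimum pairwise clone separation in CCF space (the
#'   largest per-sample difference between two clones must reach this).
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 3, n_clones = 5, n_trunk_snvs = 20,
                       n_branch_snvs_per_clone = 10,
                       purity_range = c(0.6, 0.95),
                       mean_coverage_wes = 346,
                       mean_coverage_targeted = 2500,
                       n_segments = 44, n_het_snps_per_segment = 20,
                       cn_event_rate = 1, msai_probability = 0.05,
                       whole_chromosome_event_fraction = 0.3,
                       n_pon = 8, error_rate = 0.002,
                       min_ccf_gap = 0.15, seed = 1) {
  cfg <- list(
    n_samples = n_samples, n_clones = n_clones, n_trunk_snvs = n_trunk_snvs,
    n_branch_snvs_per_clone = n_branch_snvs_per_clone,
    purity_range = purity_range, mean_coverage_wes = mean_coverage_wes,
    mean_coverage_targeted = mean_coverage_targeted,
    n_segments = n_segments,
    n_het_snps_per_segment = n_het_snps_per_segment,
    cn_event_rate = cn_event_rate, msai_probability = msai_probability,
    whole_chromosome_event_fraction = whole_chromosome_event_fraction,
    n_pon = n_pon, error_rate = error_rate, min_ccf_gap = min_ccf_gap,
    seed = seed
  )
  for (f in c("n_samples", "n_clones", "n_trunk_snvs",
              "n_branch_snvs_per_clone", "n_segments",
              "n_het_snps_per_segment", "n_pon")) {
    assert_count(cfg[[f]], f)
  }
  assert_that(length(purity_range) == 2 && purity_range[1] <= purity_range[2] &&
                purity_range[1] > 0 && purity_range[2] <= 1,
              "`purity_range` must be an increasing interval within (0, 1]")
  assert_that(cn_event_rate >= 0, "`cn_event_rate` must be >= 0")
  assert_prob(msai_probability, "msai_probability")
  assert_prob(whole_chromosome_event_fraction, "whole_chromosome_event_fraction")
  assert_prob(error_rate, "error_rate")
  structure(cfg, class = "sim_config")
}

#' Simulate a rooted clone tree by uniform attachment
#'
#' Each new clone attaches to an existing clone chosen uniformly, producing
#' both linear and branched topologies.
#'
#' @param n_clones number of clones (>= 1); clone 1 is the founding clone.
#' @param seed RNG seed.
#' @return tibble `clone`, `parent` (NA for the root).
#' @export
simulate_clone_tree <- function(n_clones, seed = 1) {
  assert_count(n_clones, "n_clones")
  parent <- rep(NA_integer_, n_clones)
  if (n_clones > 1) {
    parent[2:n_clones] <- with_seed(seed, {
      vapply(2:n_clones, function(k) {
        if (k == 2) 1L else sample.int(k - 1L, 1L)
      }, integer(1))
    })
  }
  tibble(clone = seq_len(n_clones), parent = parent)
}

tree_children <- function(tree) split(tree$clone, tree$parent)

tree_descendants <- function(tree, id) {
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- id
  while (length(stack)) {
    x <- stack[1]
    stack <- stack[-1]
    kids <- ch[[as.character(x)]]
    out <- c(out, kids)
    stack <- c(stack, kids)
  }
  out
}

tree_ancestors <- function(tree, id) {
  out <- integer(0)
  p <- tree$parent[match(id, tree$clone)]
  while (!is.na(p)) {
    out <- c(out, p)
    p <- tree$parent[match(p, tree$clone)]
  }
  out
}

# parent each clone would receive from the reconstruction rules, given true
# CCFs; used by the generator to reject unidentifiable configurations.
# Also reports the smallest mean-CF margin over tie-break decisions: noisy
# CF estimates flip decisions whose margin is small.
rule_parents <- function(tree, ccf, presence_cf = 0.05) {
  n <- nrow(tree)
  sets <- purrr::map(seq_len(n), ~ which(ccf[.x, ] >= presence_cf))
  mcf <- rowMeans(ccf)
  out <- rep(NA_integer_, n)
  margin <- Inf
  for (i in setdiff(seq_len(n), 1L)) {
    sup <- purrr::map_lgl(seq_len(n), function(k) {
      k != i && all(sets[[i]] %in% sets[[k]])
    })
    same <- purrr::map_lgl(seq_len(n), function(k) {
      setequal(sets[[k]], sets[[i]])
    })
    ok <- sup & (!same | mcf > mcf[i])
    if (!any(ok)) { out[i] <- 1L; next }
    cand <- which(ok)
    if (any(same[cand])) {
      cand <- cand[same[cand]]
      if (length(cand) > 1) {
        ms <- sort(mcf[cand])
        margin <- min(margin, diff(ms)[1])
      }
      margin <- min(margin, mcf[cand] - mcf[i])
      cand <- cand[which.min(mcf[cand])]
    } else {
      sizes <- lengths(sets[cand])
      cand <- cand[sizes == min(sizes)]
      if (length(cand) > 1) {
        ms <- sort(mcf[cand], decreasing = TRUE)
        margin <- min(margin, ms[1] - ms[2])
      }
      cand <- cand[which.max(mcf[cand])]
    }
    out[i] <- cand
  }
  attr(out, "margin") <- margin
  out
}

#' Simulate a clone-by-sample CCF matrix
#'
#' Cellular fractions are allocated top-down: each non-founding clone is
#' present in a random subset of its parent's samples (spatial localisation
#' of subclones), and present children split a random fraction of the
#' parent's CCF (stick-breaking), so lineage consistency holds exactly.
#' By default the sampled configuration is rejected until (i) non-zero CCFs
#' stay in \[0.15, 0.85\] for non-founding clones, (ii) all pairwise clone
#' separations reach `min_gap`, and (iii) the configuration is recoverable
#' by the reconstruction rules (identifiable ground truth).
#'
#' @param tree tibble from [simulate_clone_tree()].
#' @param n_samples number of samples.
#' @param seed RNG seed.
#' @param min_gap minimum pairwise clone CCF separation (max over samples).
#' @param identifiable reject configurations the rule-based reconstruction
#'   cannot recover (default TRUE).
#' @param fixed_ccf optional user-planted clone x sample matrix; validated
#'   for lineage consistency and returned as-is.
#' @param max_tries rejection-sampling budget.
#' @return matrix clones x samples of CCFs; founding clone row is all ones.
#' @export
simulate_ccf_matrix <- function(tree, n_samples, seed = 1, min_gap = 0.15,
                                identifiable = TRUE, fixed_ccf = NULL,
                                max_tries = 5000) {
  n <- nrow(tree)
  if (!is.null(fixed_ccf)) {
    fixed_ccf <- as.matrix(fixed_ccf)
    assert_that(nrow(fixed_ccf) == n, "fixed_ccf must have one row per clone")
    for (i in seq_len(n)) {
      p <- tree$parent[i]
      if (!is.na(p)) {
        assert_that(all(fixed_ccf[i, ] <= fixed_ccf[match(p, tree$clone), ] + 1e-9),
                    "fixed_ccf violates lineage consistency")
      }
    }
    return(fixed_ccf)
  }
  assert_count(n_samples, "n_samples")
  ch <- tree_children(tree)
  order_bfs <- tree$clone  # clones are created in topological order

  draw_once <- function() {
    ccf <- matrix(0, n, n_samples)
    ccf[1, ] <- 1
    for (id in order_bfs) {
      kids <- ch[[as.character(id)]]
      if (is.null(kids)) next
      pat_parent <- which(ccf[id, ] >= 0.15)
      if (!length(pat_parent)) next
      # presence subsets per child
      pats <- purrr::map(kids, function(k) {
        keep <- pat_parent[runif(length(pat_parent)) < 0.7]
        if (!length(keep)) keep <- sample(pat_parent, 1)
        keep
      })
      for (s in pat_parent) {
        here <- which(purrr::map_lgl(pats, ~ s %in% .x))
        if (!length(here)) next
        w <- runif(length(here), 0.25, 1)
        r <- runif(1, 0.45, 0.8)
        ccf[kids[here], s] <- ccf[id, s] * r * w / sum(w)
      }
    }
    ccf
  }

  ok_config <- function(ccf, margin, want_identifiable) {
    nz <- ccf[-1, , drop = FALSE]
    if (any(nz > 0 & (nz < 0.15 | nz > 0.85))) return(FALSE)
    # every planted clone must be captured by at least one biopsy
    if (any(apply(ccf, 1, max) < 0.15)) return(FALSE)
    if (n > 1) {
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          if (max(abs(ccf[i, ] - ccf[j, ])) < min_gap) return(FALSE)
        }
      }
    }
    if (want_identifiable) {
      rp <- rule_parents(tree, ccf)
      if (!identical(as.integer(rp[-1]), tree$parent[-1])) return(FALSE)
      # tie-break decisions must be robust to CF estimation noise
      if (attr(rp, "margin") < margin) return(FALSE)
    }
    TRUE
  }

  # progressively relax the robustness margin, then identifiability, so
  # hard tree shapes still yield a cohort (with a warning)
  stages <- if (identifiable) {
    list(list(margin = 0.10, ident = TRUE), list(margin = 0.05, ident = TRUE),
         list(margin = 0, ident = TRUE), list(margin = 0, ident = FALSE))
  } else {
    list(list(margin = 0, ident = FALSE))
  }
  with_seed(seed, {
    for (si in seq_along(stages)) {
      st <- stages[[si]]
      for (t in seq_len(max_tries)) {
        ccf <- draw_once()
        if (ok_config(ccf, st$margin, st$ident)) {
          if (identifiable && !st$ident) {
            warn("CCF configuration is not rule-identifiable for this tree shape")
          }
          return(ccf)
        }
      }
    }
    abort("could not sample an admissible CCF configuration; relax min_gap or use fewer clones",
          class = "mrclone_error")
  })
}

# synthetic genome: 22 equal autosomes of 100 Mb, segments tiling each
make_genome <- function(n_segments) {
  n_chrom <- min(22L, n_segments)
  per <- rep(floor(n_segments / n_chrom), n_chrom)
  extra <- n_segments - sum(per)
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom_len <- 1e8
  purrr::map_dfr(seq_len(n_chrom), function(ci) {
    k <- per[ci]
    bounds <- round(seq(0, chrom_len, length.out = k + 1))
    tibble(chrom = paste0("chr", ci),
           start0 = bounds[-(k + 1)], end0 = bounds[-1])
  }) %>%
    mutate(segment_id = dplyr::row_number(), .before = 1)
}

#' Simulate haplotype-specific copy-number evolution on a clone tree
#'
#' Copy-number events (contiguous segmental or whole-chromosome gains and
#' losses of one haplotype) are assigned to clones and inherited by their
#' descendants. A lost haplotype (copy number 0) is never regained. With
#' probability `msai_probability` a segment receives a planted mirrored
#' event: a gain of haplotype A in one clade and of haplotype B in a
#' disjoint clade. Gains occasionally escalate to focal amplification.
#'
#' @param tree clone tree tibble.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list: `profiles` (tibble clone, segment_id, chrom, cnA, cnB),
#'   `msai_truth` (tibble segment_id, clone_a, clone_b), `chromosome_events`
#'   (tibble chrom, type in none/whole/segmental), `events`, `genome`.
#' @export
simulate_cn_evolution <- function(tree, config, seed = 1) {
  genome <- make_genome(config$n_segments)
  n_seg <- nrow(genome)
  n <- nrow(tree)
  segs_of_chrom <- split(genome$segment_id, genome$chrom)

  with_seed(seed, {
    events <- list()
    # regular events per clone
    for (id in tree$clone) {
      k <- rpois(1, config$cn_event_rate)
      for (e in seq_len(k)) {
        whole <- runif(1) < config$whole_chromosome_event_fraction
        chrom <- sample(names(segs_of_chrom), 1)
        segs <- segs_of_chrom[[chrom]]
        if (!whole) {
          len <- min(length(segs), 1 + rgeom(1, 0.5))
          start <- sample(length(segs) - len + 1, 1)
          segs <- segs[start:(start + len - 1)]
        }
        gain <- runif(1) < 0.5
        delta <- if (gain && !whole && runif(1) < 0.1) {
          sample(3:12, 1)  # focal amplification escalation
        } else if (gain) 1L else -1L
        events[[length(events) + 1]] <- tibble(
          clone = id, chrom = chrom,
          seg_start = min(segs), seg_end = max(segs),
          hap = sample(c("A", "B"), 1), delta = delta, whole = whole,
          msai = FALSE
        )
      }
    }
    # planted MSAI events on incomparable clone pairs
    msai_rows <- list()
    pairs <- list()
    if (n >= 3) {
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (i < j && !(i %in% tree_ancestors(tree, j)) &&
              !(j %in% tree_ancestors(tree, i)) && i != 1 && j != 1) {
            pairs[[length(pairs) + 1]] <- c(i, j)
          }
        }
      }
    }
    if (length(pairs) > 0 && config$msai_probability > 0) {
      hit <- which(runif(n_seg) < config$msai_probability)
      for (s in hit) {
        pr <- pairs[[sample.int(length(pairs), 1)]]
        events[[length(events) + 1]] <- tibble(
          clone = pr[1], chrom = genome$chrom[s], seg_start = s, seg_end = s,
          hap = "A", delta = 1L, whole = FALSE, msai = TRUE)
        events[[length(events) + 1]] <- tibble(
          clone = pr[2], chrom = genome$chrom[s], seg_start = s, seg_end = s,
          hap = "B", delta = 1L, whole = FALSE, msai = TRUE)
        msai_rows[[length(msai_rows) + 1]] <- tibble(
          segment_id = s, clone_a = pr[1], clone_b = pr[2])
      }
    }
    events <- if (length(events)) bind_rows(events) else
      tibble(clone = integer(), chrom = character(), seg_start = integer(),
             seg_end = integer(), hap = character(), delta = integer(),
             whole = logical(), msai = logical())

    # apply events along the tree (inheritance; losses never resurrect)
    prof <- list()
    prof[["0"]] <- matrix(1L, n_seg, 2, dimnames = list(NULL, c("A", "B")))
    apply_events <- function(p, ev) {
      for (i in seq_len(nrow(ev))) {
        segs <- ev$seg_start[i]:ev$seg_end[i]
        h <- ev$hap[i]
        cur <- p[segs, h]
        live <- cur > 0  # events only act on surviving copies
        if (ev$delta[i] > 0) {
          p[segs[live], h] <- cur[live] + ev$delta[i]
        } else {
          p[segs[live], h] <- pmax(0L, cur[live] - 1L)
        }
      }
      p
    }
    for (id in tree$clone) {
      par <- tree$parent[match(id, tree$clone)]
      base <- if (is.na(par)) prof[["0"]] else prof[[as.character(par)]]
      prof[[as.character(id)]] <- apply_events(base, filter(events, .data$clone == id))
    }

    profiles <- purrr::map_dfr(tree$clone, function(id) {
      p <- prof[[as.character(id)]]
      tibble(clone = id, segment_id = genome$segment_id,
             chrom = genome$chrom, cnA = p[, "A"], cnB = p[, "B"])
    })

    chrom_type <- purrr::map_dfr(names(segs_of_chrom), function(cc) {
      ev <- filter(events, .data$chrom == cc)
      type <- if (nrow(ev) == 0) "none"
      else if (all(ev$whole)) "whole"
      else "segmental"
      tibble(chrom = cc, type = type)
    })

    list(
      profiles = profiles,
      msai_truth = if (length(msai_rows)) bind_rows(msai_rows) else
        tibble(segment_id = integer(), clone_a = integer(), clone_b = integer()),
      chromosome_events = chrom_type,
      events = events,
      genome = genome
    )
  })
}

# exclusive cell fraction of each clone per sample (cells in the clone but
# in none of its children)
exclusive_fractions <- function(tree, ccf) {
  ch <- tree_children(tree)
  excl <- ccf
  for (id in tree$clone) {
    kids <- ch[[as.character(id)]]
    if (!is.null(kids)) {
      excl[id, ] <- pmax(0, ccf[id, ] - colSums(ccf[kids, , drop = FALSE]))
    }
  }
  excl
}

PATHWAY_GENES <- tibble::tibble(
  gene = c("TP53", "ALK", "HRAS", "NRAS", "KRAS", "BRAF", "NF1",
           "PTPN11", "FGFR1", "RAF1"),
  pathway = c("TP53", rep("RAS_MAPK", 9))
)

#' Simulate read-count tables for a planted ground truth
#'
#' Draws sequencing depths (Poisson) and alt counts (binomial at the
#' closed-form expected VAF given clone CCFs, purity and local haplotype
#' copy numbers), germline heterozygous SNP B-allele counts, matched-normal
#' and panel-of-normals mismatch counts, and per-sample integer
#' allele-specific segment tables derived from the clone mixture.
#'
#' @param truth list with `tree`, `ccf`, `cn` (from
#'   [simulate_cn_evolution()]).
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param coverage mean depth; defaults to `config$mean_coverage_wes`.
#' @param purity optional named per-sample purity; drawn from
#'   `config$purity_range` when NULL.
#' @return list of tibbles: `variants`, `normals`, `pon`, `snp_baf`,
#'   `segments`, `sample_info`, `snv_truth`, `biopsy_profiles`.
#' @export
simulate_reads <- function(truth, config, seed = 1, coverage = NULL,
                           purity = NULL) {
  coverage <- coverage %||% config$mean_coverage_wes
  tree <- truth$tree
  ccf <- truth$ccf
  cn <- truth$cn
  genome <- cn$genome
  n <- nrow(tree)
  n_samples <- ncol(ccf)
  samples <- paste0("S", seq_len(n_samples))

  with_seed(seed, {
    if (is.null(purity)) {
      purity <- setNames(runif(n_samples, config$purity_range[1],
                               config$purity_range[2]), samples)
    }
    excl <- exclusive_fractions(tree, ccf)

    # clone x segment haplotype copy numbers as matrices
    cnA <- tidyr::pivot_wider(cn$profiles[, c("clone", "segment_id", "cnA")],
                              names_from = "segment_id", values_from = "cnA")
    cnB <- tidyr::pivot_wider(cn$profiles[, c("clone", "segment_id", "cnB")],
                              names_from = "segment_id", values_from = "cnB")
    cnA <- as.matrix(cnA[order(cnA$clone), -1])
    cnB <- as.matrix(cnB[order(cnB$clone), -1])
    n_seg <- ncol(cnA)

    # tumour-average haplotype copy number per sample x segment
    mixA <- t(excl) %*% cnA  # samples x segments
    mixB <- t(excl) %*% cnB
    mixT <- mixA + mixB

    # --- SNVs ---
    snv_clone <- c(rep(1L, config$n_trunk_snvs),
                   rep(setdiff(tree$clone, 1L),
                       each = config$n_branch_snvs_per_clone))
    n_snv <- length(snv_clone)
    snv_seg <- sample.int(n_seg, n_snv, replace = TRUE)
    snv_hap <- sample(c("A", "B"), n_snv, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    snv_ref <- sample(bases, n_snv, replace = TRUE)
    snv_alt <- vapply(snv_ref, function(b) sample(setdiff(bases, b), 1), "")
    in_pathway <- runif(n_snv) < 0.04
    pg <- PATHWAY_GENES[sample.int(nrow(PATHWAY_GENES), n_snv, replace = TRUE), ]
    gene <- ifelse(in_pathway, pg$gene, paste0("GENE", seq_len(n_snv)))
    pathway <- ifelse(in_pathway, pg$pathway, "none")
    pos <- genome$start0[snv_seg] +
      sample.int(1e6, n_snv, replace = TRUE)

    snv_truth <- tibble(
      variant_id = paste0("v", seq_len(n_snv)),
      clone = snv_clone, segment_id = snv_seg, hap = snv_hap,
      chrom = genome$chrom[snv_seg], pos = pos,
      ref = snv_ref, alt = unname(snv_alt), gene = gene, pathway = pathway
    )

    # expected VAF per variant x sample from the clone mixture: mutated
    # copies follow the copy number of the variant's haplotype in each
    # carrier clone (the variant's clone and its descendants)
    carriers <- purrr::map(tree$clone, function(id) c(id, tree_descendants(tree, id)))
    evaf <- matrix(0, n_snv, n_samples)
    for (i in seq_len(n_snv)) {
      cs <- carriers[[snv_clone[i]]]
      hap_cn <- if (snv_hap[i] == "A") cnA else cnB
      mut_copies <- colSums(excl[cs, , drop = FALSE] * hap_cn[cs, snv_seg[i]])
      denom <- purity * mixT[, snv_seg[i]] + 2 * (1 - purity)
      evaf[i, ] <- pmin(1, purity * mut_copies / denom)
    }

    variants <- purrr::map_dfr(seq_len(n_samples), function(s) {
      depth <- pmax(1L, rpois(n_snv, coverage))
      p <- pmax(evaf[, s], config$error_rate)
      tibble(
        patient = "P1", sample = samples[s],
        chrom = snv_truth$chrom, pos = snv_truth$pos,
        ref = snv_truth$ref, alt = snv_truth$alt,
        alt_count = rbinom(n_snv, depth, p), depth = depth,
        gene = snv_truth$gene, pathway = snv_truth$pathway,
        variant_id = snv_truth$variant_id
      )
    })

    ndepth <- pmax(1L, rpois(n_snv, coverage))
    normals <- tibble(
      patient = "P1", variant_id = snv_truth$variant_id,
      alt_count = rbinom(n_snv, ndepth, config$error_rate), depth = ndepth
    )
    pon <- purrr::map_dfr(seq_len(config$n_pon), function(j) {
      d <- pmax(1L, rpois(n_snv, coverage))
      tibble(pon_sample = paste0("N", j), variant_id = snv_truth$variant_id,
             mismatch_count = rbinom(n_snv, d, config$error_rate), depth = d)
    })

    # --- germline het SNP BAFs (B allele oriented to haplotype B) ---
    snp <- tidyr::expand_grid(segment_id = seq_len(n_seg),
                              k = seq_len(config$n_het_snps_per_segment)) %>%
      mutate(chrom = genome$chrom[.data$segment_id],
             pos = genome$start0[.data$segment_id] +
               round((genome$end0[.data$segment_id] -
                        genome$start0[.data$segment_id]) *
                       .data$k / (config$n_het_snps_per_segment + 1)))
    snp_baf <- purrr::map_dfr(seq_len(n_samples), function(s) {
      baf <- (purity[s] * mixB[s, snp$segment_id] + (1 - purity[s])) /
        (purity[s] * mixT[s, snp$segment_id] + 2 * (1 - purity[s]))
      depth <- pmax(1L, rpois(nrow(snp), coverage))
      tibble(chrom = snp$chrom, pos = snp$pos, sample = samples[s],
             b_count = rbinom(nrow(snp), depth, pmin(pmax(baf, 0), 1)),
             depth = depth, segment_id = snp$segment_id)
    })

    # --- per-sample integer segment tables (consensus of the mixture) ---
    segments <- purrr::map_dfr(seq_len(n_samples), function(s) {
      a <- round(mixA[s, ])
      b <- round(mixB[s, ])
      seg <- tibble(
        patient = "P1", sample = samples[s],
        chrom = genome$chrom, start0 = genome$start0, end0 = genome$end0,
        cn_major = pmax(a, b), cn_minor = pmin(a, b)
      )
      # merge adjacent equal-state segments so per-sample segmentations differ
      seg <- seg %>%
        group_by(.data$chrom) %>%
        mutate(new_block = cumsum(
          dplyr::row_number() == 1 |
            .data$cn_major != dplyr::lag(.data$cn_major, default = -1L) |
            .data$cn_minor != dplyr::lag(.data$cn_minor, default = -1L)
        )) %>%
        group_by(.data$patient, .data$sample, .data$chrom, .data$new_block) %>%
        summarise(start0 = min(.data$start0), end0 = max(.data$end0),
                  cn_major = .data$cn_major[1], cn_minor = .data$cn_minor[1],
                  .groups = "drop") %>%
        select(-"new_block")
      len <- seg$end0 - seg$start0
      ploidy <- sum((seg$cn_major + seg$cn_minor) * len) / sum(len)
      seg$purity <- unname(purity[s])
      seg$ploidy <- ploidy
      seg
    })

    sample_info <- tibble(
      patient = "P1", sample = samples, purity = unname(purity),
      ploidy = purrr::map_dbl(samples, function(ss) {
        segments$ploidy[match(ss, segments$sample)]
      })
    )

    # telomere-maintenance indicators per biopsy (booleans; MYCN-like
    # amplification is derived downstream from the copy-number profile)
    biopsy_profiles <- tibble(
      patient = "P1", sample = samples,
      tert_high = runif(n_samples) < 0.3,
      tert_rearranged = runif(n_samples) < 0.1,
      alt_positive = runif(n_samples) < 0.1
    )

    list(variants = variants, normals = normals, pon = pon,
         snp_baf = snp_baf, segments = segments, sample_info = sample_info,
         snv_truth = snv_truth, biopsy_profiles = biopsy_profiles)
  })
}

#' Simulate a full synthetic multi-region cohort
#'
#' Chains [simulate_clone_tree()], [simulate_ccf_matrix()],
#' [simulate_cn_evolution()] and [simulate_reads()] under one master seed.
#'
#' @param config a [sim_config()].
#' @param coverage mean depth (default WES coverage from config).
#' @return list with `truth` (tree, ccf, cn, purity), `tables`, `config`.
#' @export
simulate_cohort <- function(config = sim_config(), coverage = NULL) {
  seed <- config$seed
  tree <- simulate_clone_tree(config$n_clones, seed = child_seed(seed, 1))
  ccf <- simulate_ccf_matrix(tree, config$n_samples,
                             seed = child_seed(seed, 2),
                             min_gap = config$min_ccf_gap)
  cn <- simulate_cn_evolution(tree, config, seed = child_seed(seed, 3))
  truth <- list(tree = tree, ccf = ccf, cn = cn)
  tables <- simulate_reads(truth, config, seed = child_seed(seed, 4),
                           coverage = coverage)
  truth$purity <- setNames(tables$sample_info$purity,
                           tables$sample_info$sample)
  list(truth = truth, tables = tables, config = config)
}
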