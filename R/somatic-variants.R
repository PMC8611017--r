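#' Fit a beta-binomial site error model from control samples
#'
#' Models the technical mismatch rate at a candidate site from a panel of
#' normal (control) samples. Mismatch fractions are regularised with a
#' 0.5 / 1.0 pseudocount and fitted by method of moments for the
#' beta-binomial; when the estimated overdispersion is not positive the fit
#' falls back to a pooled binomial (represented as a beta with a large
#' concentration).
#'
#' @param controls data frame with columns `mismatch_count` and `depth`,
#'   one row per control sample at this site.
#' @return an object of class `site_error_model` with fields `alpha`,
#'   `beta`, `mean`, `overdispersed`.
#' @export
fit_site_error_model <- function(controls) {
  controls <- as_tibble(controls)
  assert_that(all(c("mismatch_count", "depth") %in% names(controls)),
              "`controls` needs columns mismatch_count, depth")
  controls <- filter(controls, .data$depth > 0)
  assert_that(nrow(controls) >= 1, "no control sample has positive depth")
  assert_that(nrow(controls) >= 2, "need >= 2 controls with positive depth")
  x <- controls$mismatch_count
  d <- controls$depth
  assert_that(all(x >= 0 & x <= d), "mismatch_count must lie in [0, depth]")

  # pseudocounted mismatch fractions
  p <- (x + 0.5) / (d + 1)
  mu <- mean(p)
  v <- stats::var(p)
  nbar <- mean(d)

  # method of moments for beta-binomial: Var(x/n) = mu(1-mu)/n * (1+(n-1)rho)
  rho <- if (mu > 0 && mu < 1) {
    (v * nbar / (mu * (1 - mu)) - 1) / (nbar - 1)
  } else {
    0
  }

  if (is.na(rho) || rho <= 0) {
    # pooled binomial fallback: beta with large concentration at pooled mean
    mu_pool <- (sum(x) + 0.5) / (sum(d) + 1)
    s <- 1e6
    model <- list(alpha = mu_pool * s, beta = (1 - mu_pool) * s,
                  mean = mu_pool, overdispersed = FALSE)
  } else {
    rho <- min(rho, 0.99)
    s <- 1 / rho - 1
    model <- list(alpha = mu * s, beta = (1 - mu) * s,
                  mean = mu, overdispersed = TRUE)
  }
  structure(model, class = "site_error_model")
}

#' @export
print.site_error_model <- function(x, ...) {
  cat(sprintf(
    "<site_error_model> alpha=%.4g beta=%.4g mean=%.4g (%s)\n",
    x$alpha, x$beta, x$mean,
    if (x$overdispersed) "beta-binomial" else "pooled binomial"
  ))
  invisible(x)
}

# upper tail P(X >= k | n, alpha, beta) of the beta-binomial, by summation
betabinom_upper_tail <- function(k, n, alpha, beta) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + lbeta(j + alpha, n - j + beta) - lbeta(alpha, beta)))
}

#' Call a candidate somatic variant in one tumour sample
#'
#' Applies the three-stage somatic filter: the tumour VAF must reach the
#' candidate threshold (default 10%), the matched-normal VAF must stay below
#' the control threshold (default 5%), and the tumour alt count must be
#' highly unlikely (default p < 0.001) under the beta-binomial technical
#' error model fitted from the panel of normals.
#'
#' @param tumour,normal length-2 numeric vectors `c(alt, depth)` or data
#'   frames with columns `alt_count`, `depth` (vectorised over rows).
#' @param model a [fit_site_error_model()] object (one site) or a list of
#'   such models parallel to the rows.
#' @param t_cand,t_ctrl,p_max filter thresholds.
#' @return tibble with columns `tumour_vaf`, `normal_vaf`, `p_value`,
#'   `status` (one of `somatic`, `rejected_candidate`,
#'   `rejected_error_model`).
#' @export
call_somatic_variant <- function(tumour, normal, model,
                                 t_cand = 0.10, t_ctrl = 0.05,
                                 p_max = 0.001) {
  as_counts <- function(x, what) {
    if (is.numeric(x) && length(x) == 2) {
      x <- tibble(alt_count = x[1], depth = x[2])
    }
    x <- as_tibble(x)
    assert_that(all(c("alt_count", "depth") %in% names(x)),
                sprintf("`%s` needs alt_count and depth", what))
    assert_that(all(x$depth > 0), sprintf("`%s` has zero depth", what))
    assert_that(all(x$alt_count >= 0 & x$alt_count <= x$depth),
                sprintf("`%s` has alt_count outside [0, depth]", what))
    x
  }
  tumour <- as_counts(tumour, "tumour")
  normal <- as_counts(normal, "normal")
  assert_that(nrow(tumour) == nrow(normal),
              "tumour and normal must have the same number of rows")
  models <- if (inherits(model, "site_error_model")) {
    rep(list(model), nrow(tumour))
  } else {
    model
  }
  assert_that(length(models) == nrow(tumour),
              "one error model per row is required")

  tvaf <- tumour$alt_count / tumour$depth
  nvaf <- normal$alt_count / normal$depth
  p <- purrr::map2_dbl(seq_len(nrow(tumour)), models, function(i, m) {
    betabinom_upper_tail(tumour$alt_count[i], tumour$depth[i], m$alpha, m$beta)
  })
  status <- dplyr::case_when(
    tvaf < t_cand | nvaf >= t_ctrl ~ "rejected_candidate",
    p >= p_max ~ "rejected_error_model",
    TRUE ~ "somatic"
  )
  tibble(tumour_vaf = tvaf, normal_vaf = nvaf, p_value = p, status = status)
}

#' Expected variant allele frequency of a mutation
#'
#' For a mutation carried by a fraction `ccf` of tumour cells on `m` of the
#' `c_t` tumour copies in a sample of purity `rho`, the expected VAF is
#' `ccf * rho * m / (rho * c_t + 2 * (1 - rho))`. Vectorised.
#'
#' @param ccf cancer cell fraction in \[0, 1\].
#' @param rho sample tumour purity in (0, 1\].
#' @param c_t total tumour copy number at the site (>= 0).
#' @param m mutation multiplicity (mutated copies per tumour cell).
#' @return expected VAF in \[0, 1\].
#' @export
expected_vaf <- function(ccf, rho, c_t, m = 1) {
  assert_that(all(ccf >= 0 & ccf <= 1), "`ccf` must be in [0, 1]")
  assert_that(all(rho > 0 & rho <= 1), "`rho` must be in (0, 1]")
  assert_that(all(c_t >= 0), "`c_t` must be >= 0")
  assert_that(all(m >= 0), "`m` must be >= 0")
  denom <- rho * c_t + 2 * (1 - rho)
  assert_that(all(denom > 0),
              "degenerate site: no DNA present (rho*c_t + 2(1-rho) = 0)")
  pmin(1, ccf * rho * m / denom)
}

# per-sample presence threshold: the 10% clonality cutoff is anchored at the
# diploid heterozygous reference (expected VAF 0.30 at 60% purity) and scaled
# proportionally to the expected VAF under the sample's purity / local total
# copy number.
clonality_threshold <- function(rho, c_t, t_clonal = 0.10) {
  t_clonal * expected_vaf(1, rho, c_t, 1) / 0.30
}

#' Stratify a variant as clonal, subclonal or subclonal-specific
#'
#' A variant is *present* in a sample when its VAF reaches the per-sample
#' threshold, the 10% rule rescaled for purity and local copy number (see
#' [expected_vaf()]; the reference point is a clonal heterozygous diploid
#' variant at 60% purity, expected VAF 0.30). The variant is `clonal` when
#' present in every sample of the patient, `subclonal_specific` when present
#' in exactly one, and `subclonal` otherwise.
#'
#' @param vafs data frame with one row per (variant, sample): columns
#'   `variant_id`, `sample`, `vaf`, and optionally `c_t` (total copy number
#'   at the site in that sample; missing values assume diploid and are
#'   flagged) .
#' @param purities named vector (by sample) of tumour purities.
#' @param t_clonal presence threshold anchor (default 0.10).
#' @return tibble with one row per variant: `variant_id`, `category`,
#'   `n_present`, `n_samples`, plus a nested `presence` list-column of
#'   per-sample flags and thresholds.
#' @export
classify_clonality <- function(vafs, purities, t_clonal = 0.10) {
  vafs <- as_tibble(vafs)
  assert_that(all(c("variant_id", "sample", "vaf") %in% names(vafs)),
              "`vafs` needs variant_id, sample, vaf")
  assert_that(nrow(vafs) > 0, "no samples supplied")
  samples <- unique(vafs$sample)
  assert_that(all(samples %in% names(purities)),
              "every sample needs a purity in `purities`")
  if (!"c_t" %in% names(vafs)) vafs$c_t <- NA_real_
  vafs <- vafs %>%
    mutate(
      cn_missing = is.na(.data$c_t),
      c_t = ifelse(is.na(.data$c_t), 2, .data$c_t),
      rho = unname(purities[.data$sample]),
      threshold = clonality_threshold(.data$rho, .data$c_t, t_clonal),
      present = .data$vaf >= .data$threshold
    )
  n_samples <- length(samples)
  vafs %>%
    group_by(.data$variant_id) %>%
    summarise(
      n_present = sum(.data$present),
      n_samples = n_samples,
      cn_assumed_diploid = any(.data$cn_missing),
      presence = list(dplyr::pick("sample", "present", "threshold")),
      .groups = "drop"
    ) %>%
    mutate(category = dplyr::case_when(
      .data$n_present == n_samples ~ "clonal",
      .data$n_present == 1 ~ "subclonal_specific",
      .data$n_present > 1 ~ "subclonal",
      TRUE ~ "absent"
    )) %>%
    select("variant_id", "category", "n_present", "n_samples",
           "cn_assumed_diploid", "presence")
}

#' Concordance of clonality assignments between two platforms
#'
#' Compares clonal/subclonal assignments of the same variants called from
#' two datasets (e.g. whole-exome vs ultra-deep targeted re-sequencing) and
#' reports the fraction of shared variants with identical assignment.
#'
#' @param calls_a,calls_b tibbles with columns `variant_id`, `category`
#'   (as returned by [classify_clonality()]).
#' @param collapse_subclonal treat `subclonal` and `subclonal_specific` as
#'   one class (default TRUE: the comparison is clonal vs subclonal).
#' @return list with `concordance` (fraction), `n_shared`, and
#'   `disagreements` (tibble).
#' @export
platform_concordance <- function(calls_a, calls_b, collapse_subclonal = TRUE) {
  simplify <- function(x) {
    x <- as_tibble(x)[, c("variant_id", "category")]
    if (collapse_subclonal) {
      x$category <- ifelse(x$category == "clonal", "clonal", "subclonal")
    }
    x
  }
  a <- simplify(calls_a)
  b <- simplify(calls_b)
  shared <- inner_join(a, b, by = "variant_id", suffix = c("_a", "_b"))
  assert_that(nrow(shared) > 0, "no shared variant identifiers")
  agree <- shared$category_a == shared$category_b
  list(
    concordance = mean(agree),
    n_shared = nrow(shared),
    disagreements = shared[!agree, ]
  )
}
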