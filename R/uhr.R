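#' Default TP53 / RAS-MAPK pathway gene list
#'
#' Shipped default pathway membership used for ultra-high-risk calling;
#' fully overridable.
#'
#' @return tibble `gene`, `pathway`.
#' @export
uhr_pathway_genes <- function() PATHWAY_GENES

#' Classify one biopsy as UHR, HR-TMM+ or TMM-negative
#'
#' A biopsy is telomere-maintenance positive (TMM+) when any of high TERT
#' expression, MYCN amplification, TERT rearrangement or ALT is present.
#' Mutations in the TP53 or RAS/MAPK pathways with VAF above `uhr_vaf`
#' (default 5%) are UHR mutations. Classification: `UHR` = TMM+ with a
#' UHR mutation; `HR_TMM` = TMM+ without one; `TMM_negative` otherwise.
#'
#' @param profiles tibble with one row per biopsy: `sample`, logicals
#'   `tert_high`, `mycn_amplified`, `tert_rearranged`, `alt_positive`
#'   (missing indicators are treated as FALSE and flagged), and a
#'   list-column `pathway_mutations` of tibbles `gene`, `pathway`, `vaf`
#'   (or NULL).
#' @param uhr_vaf VAF threshold for UHR mutations.
#' @return tibble: `sample`, `tmm_positive`, `uhr_mutation_present`,
#'   `classification`, `missing_indicators`.
#' @export
classify_biopsy_uhr <- function(profiles, uhr_vaf = 0.05) {
  profiles <- as_tibble(profiles)
  assert_that("sample" %in% names(profiles), "`profiles` needs a sample column")
  inds <- c("tert_high", "mycn_amplified", "tert_rearranged", "alt_positive")
  missing_any <- rep(FALSE, nrow(profiles))
  for (f in inds) {
    if (!f %in% names(profiles)) {
      profiles[[f]] <- FALSE
      missing_any <- rep(TRUE, nrow(profiles))
    } else {
      missing_any <- missing_any | is.na(profiles[[f]])
      profiles[[f]] <- dplyr::coalesce(profiles[[f]], FALSE)
    }
  }
  if (!"pathway_mutations" %in% names(profiles)) {
    profiles$pathway_mutations <- list(NULL)
  }
  has_uhr_mut <- purrr::map_lgl(profiles$pathway_mutations, function(pm) {
    if (is.null(pm) || nrow(as_tibble(pm)) == 0) return(FALSE)
    pm <- as_tibble(pm)
    assert_that(all(pm$vaf >= 0 & pm$vaf <= 1), "VAF outside [0, 1]")
    any(pm$pathway %in% c("TP53", "RAS_MAPK") & pm$vaf > uhr_vaf)
  })
  tmm <- profiles$tert_high | profiles$mycn_amplified |
    profiles$tert_rearranged | profiles$alt_positive
  tibble(
    sample = profiles$sample,
    tmm_positive = tmm,
    uhr_mutation_present = has_uhr_mut,
    classification = dplyr::case_when(
      tmm & has_uhr_mut ~ "UHR",
      tmm ~ "HR_TMM",
      TRUE ~ "TMM_negative"
    ),
    missing_indicators = missing_any
  )
}

#' Patient-level UHR heterogeneity summary
#'
#' A patient is heterogeneous when not all biopsies share one
#' classification. With a `timepoint` column a direction is reported:
#' `acquired` when later timepoints add UHR calls absent earlier, `lost`
#' when UHR calls disappear, `mixed`/`stable` otherwise.
#'
#' @param calls tibble from [classify_biopsy_uhr()], optionally with
#'   `timepoint` (orderable) per biopsy.
#' @return one-row tibble: `n_biopsies`, `n_uhr`, `heterogeneous`,
#'   `direction`, and a nested `by_timepoint` breakdown when available.
#' @export
patient_uhr_profile <- function(calls) {
  calls <- as_tibble(calls)
  assert_that(nrow(calls) >= 1, "need >= 1 biopsy")
  het <- dplyr::n_distinct(calls$classification) > 1
  direction <- NA_character_
  by_tp <- NULL
  if ("timepoint" %in% names(calls) && dplyr::n_distinct(calls$timepoint) > 1) {
    by_tp <- calls %>%
      group_by(.data$timepoint) %>%
      summarise(n = dplyr::n(),
                n_uhr = sum(.data$classification == "UHR"),
                all_uhr = all(.data$classification == "UHR"),
                any_uhr = any(.data$classification == "UHR"),
                .groups = "drop") %>%
      arrange(.data$timepoint)
    first_uhr <- by_tp$any_uhr[1]
    last_uhr <- by_tp$any_uhr[nrow(by_tp)]
    direction <- dplyr::case_when(
      !first_uhr & last_uhr ~ "acquired",
      first_uhr & !last_uhr ~ "lost",
      het ~ "mixed",
      TRUE ~ "stable"
    )
  } else if (het) {
    direction <- "mixed"
  } else {
    direction <- "stable"
  }
  tibble(
    n_biopsies = nrow(calls),
    n_uhr = sum(calls$classification == "UHR"),
    heterogeneous = het,
    direction = direction,
    by_timepoint = list(by_tp)
  )
}
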