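#' Weighted genetic risk score from allele dosages
#'
#' Computes the conventional weighted allele count: the dosage-weighted
#' average effect is formed per individual and multiplied by the number of
#' variants, `value = n_snps * sum(w_j d_j) / sum(w_j)`, making the score a
#' weighted total number of trait-increasing alleles. Any SNP whose weight is
#' negative is first re-oriented (dosage `d -> 2 - d`, weight negated) so all
#' weights count the trait-increasing allele.
#'
#' Missing dosages are mean-imputed from `2 * eaf` when `eaf` is supplied
#' (otherwise from the observed dosage mean), with the count of non-missing
#' SNPs per individual reported as `n_snps_used`.
#'
#' @param dosages Numeric matrix or data frame, individuals x SNPs, entries
#'   in `[0, 2]` (`NA` allowed).
#' @param weights Per-allele weights in phenotype-SD units, length =
#'   `ncol(dosages)`.
#' @param eaf Optional effect-allele frequencies for imputing missing
#'   dosages.
#' @return A tibble with columns `value` and `n_snps_used`, one row per
#'   individual.
#' @examples
#' weighted_grs(rbind(c(0, 1, 2)), weights = c(0.1, 0.2, 0.3)) # value 4.0
#' @export
weighted_grs <- function(dosages, weights, eaf = NULL) {
  d <- as.matrix(dosages)
  storage.mode(d) <- "double"
  if (length(weights) != ncol(d)) stop("length(weights) must equal ncol(dosages)", call. = FALSE)
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]", call. = FALSE)
  neg <- weights < 0
  if (any(neg)) {
    d[, neg] <- 2 - d[, neg]
    weights[neg] <- -weights[neg]
    if (!is.null(eaf)) eaf[neg] <- 1 - eaf[neg]
  }
  if (sum(weights) <= 0) {
    stop("sum of weights is zero: the score is undefined for an all-null panel", call. = FALSE)
  }
  n_used <- rowSums(!is.na(d))
  if (anyNA(d)) {
    fill <- if (!is.null(eaf)) 2 * eaf else colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- fill[idx[, 2]]
  }
  tibble::tibble(
    value = ncol(d) * drop(d %*% weights) / sum(weights),
    n_snps_used = as.integer(n_used)
  )
}

#' Attach a genetic risk score to a cohort table
#'
#' Convenience wrapper applying [weighted_grs()] to a cohort's `snp_*` dosage
#' columns with a panel's weights (SNPs with `include_flag = FALSE` are
#' skipped), adding `grs` and `grs_n_snps_used` columns.
#'
#' @param cohort A `kin_cohort` tibble with per-SNP dosage columns named by
#'   `snp_id`.
#' @param panel An `snp_panel` tibble.
#' @return The cohort with `grs` and `grs_n_snps_used` columns.
#' @export
add_grs <- function(cohort, panel) {
  use <- panel[panel$include_flag %||% TRUE, , drop = FALSE]
  missing <- setdiff(use$snp_id, names(cohort))
  if (length(missing)) {
    stop("cohort lacks dosage columns for panel SNPs: ", paste(head(missing, 5), collapse = ", "),
      call. = FALSE
    )
  }
  score <- weighted_grs(as.matrix(cohort[use$snp_id]), use$weight, use$eaf)
  out <- dplyr::mutate(cohort, grs = score$value, grs_n_snps_used = score$n_snps_used)
  atts <- attributes(cohort)
  attr(out, "true_params") <- atts$true_params
  attr(out, "seed") <- atts$seed
  tibble::new_tibble(out, class = "kin_cohort")
}

STRAND_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) STRAND_COMPLEMENT[a1] == a2

#' Harmonize cohort dosages onto a panel's effect-allele coding
#'
#' Aligns a dosage matrix counted on the cohort's `a1` allele so that every
#' column counts the panel's effect allele. Per SNP, the eight possible
#' allele-pair configurations are resolved as: identical coding kept;
#' effect/other swapped flipped (`d -> 2 - d`); strand-complement coding
#' complemented then matched (with or without a flip); anything else excluded
#' as irreconcilable. Palindromic SNPs (A/T or C/G) with panel effect-allele
#' frequency in `ambiguous_eaf_window` are dropped with a warning because
#' strand cannot be resolved; outside the window they are aligned by
#' frequency concordance when a cohort `eaf` column is available, otherwise
#' assumed same-strand.
#'
#' @param panel An `snp_panel` tibble.
#' @param cohort_alleles Tibble with columns `snp_id`, `a1`, `a2` (and
#'   optionally `eaf`, the frequency of `a1`), describing the coding of
#'   `dosages`.
#' @param dosages Matrix, individuals x SNPs, columns named by `snp_id`,
#'   counting the `a1` allele.
#' @param ambiguous_eaf_window Frequency window treated as strand-ambiguous
#'   for palindromic SNPs.
#' @return A list with `dosages` (aligned matrix restricted to usable SNPs)
#'   and `report` (tibble: `snp_id`, `action`, `note`).
#' @export
harmonize_panel <- function(panel, cohort_alleles, dosages,
                            ambiguous_eaf_window = c(0.42, 0.58)) {
  assert_cols(cohort_alleles, c("snp_id", "a1", "a2"), "cohort_alleles")
  shared <- intersect(panel$snp_id, cohort_alleles$snp_id)
  shared <- intersect(shared, colnames(dosages))
  if (length(shared) == 0L) {
    stop("no SNPs shared between panel and cohort: cannot harmonize", call. = FALSE)
  }
  ca <- cohort_alleles[match(shared, cohort_alleles$snp_id), ]
  pa <- panel[match(shared, panel$snp_id), ]
  d <- as.matrix(dosages[, shared, drop = FALSE])

  action <- character(length(shared))
  note <- rep("", length(shared))
  for (j in seq_along(shared)) {
    ea <- pa$effect_allele[j]; oa <- pa$other_allele[j]
    a1 <- ca$a1[j]; a2 <- ca$a2[j]
    if (!all(c(ea, oa, a1, a2) %in% names(STRAND_COMPLEMENT))) {
      action[j] <- "drop_irreconcilable"
      note[j] <- "non-ACGT allele"
      next
    }
    pal <- isTRUE(is_palindromic(ea, oa))
    if (pal) {
      if (pa$eaf[j] >= ambiguous_eaf_window[1] && pa$eaf[j] <= ambiguous_eaf_window[2]) {
        action[j] <- "drop_palindromic"
        note[j] <- sprintf("palindromic, eaf %.2f in ambiguity window", pa$eaf[j])
        next
      }
      if (!setequal(c(a1, a2), c(ea, oa))) {
        action[j] <- "drop_irreconcilable"
        note[j] <- "palindromic with non-matching alleles"
        next
      }
      # Outside the ambiguity window, frequency identifies the effect allele.
      if (!is.null(ca$eaf) && !is.na(ca$eaf[j])) {
        freq_as_is <- if (a1 == ea) ca$eaf[j] else 1 - ca$eaf[j]
        action[j] <- if (abs(freq_as_is - pa$eaf[j]) <= abs(1 - freq_as_is - pa$eaf[j])) {
          if (a1 == ea) "keep" else "flip"
        } else {
          if (a1 == ea) "flip" else "keep"
        }
        note[j] <- "palindromic, aligned by frequency"
      } else {
        action[j] <- if (a1 == ea) "keep" else "flip"
        note[j] <- "palindromic, assumed same strand"
      }
      next
    }
    if (a1 == ea && a2 == oa) {
      action[j] <- "keep"
    } else if (a1 == oa && a2 == ea) {
      action[j] <- "flip"
    } else if (STRAND_COMPLEMENT[a1] == ea && STRAND_COMPLEMENT[a2] == oa) {
      action[j] <- "strand"
    } else if (STRAND_COMPLEMENT[a1] == oa && STRAND_COMPLEMENT[a2] == ea) {
      action[j] <- "strand_flip"
    } else {
      action[j] <- "drop_irreconcilable"
      note[j] <- sprintf("panel %s/%s vs cohort %s/%s", ea, oa, a1, a2)
    }
  }
  flip <- action %in% c("flip", "strand_flip")
  d[, flip] <- 2 - d[, flip]
  keep <- !startsWith(action, "drop")
  report <- tibble::tibble(snp_id = shared, action = action, note = note)
  n_drop <- sum(!keep)
  if (n_drop) {
    warning(sprintf(
      "harmonization excluded %d SNP(s): %s", n_drop,
      paste(shared[!keep], collapse = ", ")
    ), call. = FALSE)
  }
  list(dosages = d[, keep, drop = FALSE], report = report)
}
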