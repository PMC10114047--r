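#' Simulate a GWAS-style SNP panel for a BMI genetic risk score
#'
#' Generates a panel of independent biallelic loci with effect-allele
#' frequencies and per-allele weights on BMI in phenotype-SD units, scaled so
#' that under Hardy-Weinberg genotype frequencies the expected variance
#' explained, \eqn{\sum_j 2 p_j (1 - p_j) w_j^2}, equals `total_h2` exactly.
#' The panel stands in for an external consortium weight set (e.g. the 97
#' index SNPs commonly used for BMI scores).
#'
#' Weights are oriented so the effect allele is always the BMI-increasing
#' allele (all weights non-negative), matching the usual risk-score
#' convention. `weight_se` mimics a large-consortium standard error,
#' \eqn{1/\sqrt{2 p (1 - p) N}} with `n_gwas` notional samples.
#'
#' @param n_snps Number of loci (>= 1).
#' @param eaf_range Length-2 interval inside (0, 1) from which effect-allele
#'   frequencies are drawn uniformly.
#' @param total_h2 Fraction of phenotype variance the panel explains, in
#'   `[0, 1)`.
#' @param seed Integer seed; required.
#' @param n_gwas Notional discovery-sample size used only for `weight_se`.
#'
#' @return A tibble of class `snp_panel` with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `weight`, `weight_se`,
#'   `include_flag`.
#' @examples
#' panel <- simulate_snp_panel(97, total_h2 = 0.0185, seed = 1)
#' sum(2 * panel$eaf * (1 - panel$eaf) * panel$weight^2)
#' @export
simulate_snp_panel <- function(n_snps, eaf_range = c(0.05, 0.95), total_h2 = 0.02,
                               seed = NULL, n_gwas = 240000) {
  stopifnot(n_snps >= 1, length(eaf_range) == 2)
  assert_prob(eaf_range, "eaf_range")
  if (total_h2 < 0 || total_h2 >= 1) {
    stop("`total_h2` must lie in [0, 1): a score cannot explain all variance", call. = FALSE)
  }
  with_seed(seed, {
    eaf <- runif(n_snps, eaf_range[1], eaf_range[2])
    w <- abs(rnorm(n_snps))
    denom <- sum(2 * eaf * (1 - eaf) * w^2)
    w <- if (total_h2 == 0 || denom == 0) rep(0, n_snps) else w * sqrt(total_h2 / denom)
    alleles <- c("A", "C", "G", "T")
    ea <- sample(alleles, n_snps, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1L), character(1))
    tibble::new_tibble(
      tibble::tibble(
        snp_id = sprintf("snp_%03d", seq_len(n_snps)),
        effect_allele = ea,
        other_allele = unname(oa),
        eaf = eaf,
        weight = w,
        weight_se = 1 / sqrt(2 * eaf * (1 - eaf) * n_gwas),
        include_flag = TRUE
      ),
      class = "snp_panel"
    )
  })
}

#' Restrict a SNP panel to a subset of loci
#'
#' Used for SNP-subset sensitivity analyses (e.g. re-running the score and the
#' per-SNP estimators on the genome-wide-significant subset of a larger
#' panel), keeping the corresponding per-SNP weights.
#'
#' @param panel An `snp_panel` tibble.
#' @param keep_ids Character vector of `snp_id` values to keep; must be a
#'   subset of the panel's ids and non-empty.
#' @return The restricted panel.
#' @export
filter_panel <- function(panel, keep_ids) {
  assert_cols(panel, c("snp_id", "weight"), "panel")
  extra <- setdiff(keep_ids, panel$snp_id)
  if (length(extra)) {
    stop("keep_ids not present in panel: ", paste(head(extra, 5), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::filter(panel, .data$snp_id %in% keep_ids)
  if (nrow(out) == 0L) stop("filter_panel() would produce an empty panel", call. = FALSE)
  tibble::new_tibble(out, class = "snp_panel")
}

#' Read/write SNP panels as GWAS-summary-style TSV
#'
#' Columns follow the conventional summary-statistic layout: `SNP`, `EA`
#' (effect allele), `OA` (other allele), `EAF`, `BETA` (per-allele effect in
#' phenotype-SD units), `SE`, plus `INCLUDE` for subset flags. Missing values
#' are encoded as `NA`.
#'
#' @param panel An `snp_panel` tibble.
#' @param path File path.
#' @return `write_snp_panel()` returns `path` invisibly; `read_snp_panel()`
#'   returns an `snp_panel` tibble.
#' @export
write_snp_panel <- function(panel, path) {
  out <- tibble::tibble(
    SNP = panel$snp_id, EA = panel$effect_allele, OA = panel$other_allele,
    EAF = panel$eaf, BETA = panel$weight, SE = panel$weight_se,
    INCLUDE = panel$include_flag
  )
  readr::write_tsv(out, path, na = "NA")
  invisible(path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  assert_cols(raw, c("SNP", "EA", "OA", "EAF", "BETA", "SE"), "panel file")
  tibble::new_tibble(
    tibble::tibble(
      snp_id = raw$SNP, effect_allele = raw$EA, other_allele = raw$OA,
      eaf = raw$EAF, weight = raw$BETA, weight_se = raw$SE,
      include_flag = if ("INCLUDE" %in% names(raw)) as.logical(raw$INCLUDE) else TRUE
    ),
    class = "snp_panel"
  )
}
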