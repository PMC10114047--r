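test_that("weighted score matches hand arithmetic and limiting cases", {
  # hand-worked: 3 * (0.1*0 + 0.2*1 + 0.3*2) / 0.6 = 4.0
  expect_equal(weighted_grs(rbind(c(0, 1, 2)), c(0.1, 0.2, 0.3))$value, 4.0)
  # equal weights collapse to the plain allele count
  d <- rbind(c(0, 1, 2, 2), c(1, 1, 0, 2))
  expect_equal(weighted_grs(d, rep(0.25, 4))$value, rowSums(d))
  # all dosages 2 give the maximum 2 * n_snps whatever the weights
  expect_equal(weighted_grs(rbind(rep(2, 5)), runif(5, 0.1, 1))$value, 10)
})

test_that("score is invariant to rescaling weights and to allele re-orientation", {
  withr::with_seed(1, {
    d <- matrix(rbinom(60, 2, 0.3), 10, 6)
    w <- runif(6, 0.05, 0.5)
  })
  expect_equal(weighted_grs(d, w)$value, weighted_grs(d, 7.3 * w)$value)
  # negating a weight and flipping its dosage is the identical score
  w2 <- w
  w2[3] <- -w2[3]
  d2 <- d
  d2[, 3] <- 2 - d2[, 3]
  expect_equal(weighted_grs(d, w)$value, weighted_grs(d2, w2)$value)
})

test_that("missing dosages are mean-imputed and counted", {
  d <- rbind(c(0, 1, NA), c(2, NA, NA))
  w <- c(0.2, 0.3, 0.5)
  out <- weighted_grs(d, w, eaf = c(0.5, 0.2, 0.4))
  expect_identical(out$n_snps_used, c(2L, 1L))
  manual1 <- 3 * (0.2 * 0 + 0.3 * 1 + 0.5 * (2 * 0.4)) / 1
  expect_equal(out$value[1], manual1)
})

test_that("harmonization resolves every allele-pair configuration correctly", {
  # Enumeration oracle: one SNP per configuration, panel side fixed.
  panel <- tibble::tibble(
    snp_id = paste0("s", 1:7),
    effect_allele = c("A", "A", "A", "A", "A", "C", "A"),
    other_allele  = c("G", "G", "G", "G", "T", "G", "G"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.5, 0.2, 0.3),
    weight = 0.1, weight_se = 0.01, include_flag = TRUE
  )
  cohort_alleles <- tibble::tibble(
    snp_id = paste0("s", 1:7),
    a1 = c("A", "G", "T", "C", "A", "C", "A"),
    a2 = c("G", "A", "C", "T", "T", "G", "C"),
    eaf = c(0.3, 0.7, 0.3, 0.7, 0.5, 0.2, 0.3)
  )
  dos <- matrix(2, nrow = 3, ncol = 7, dimnames = list(NULL, paste0("s", 1:7)))
  dos[1, ] <- rep_len(0:1, 7)
  out <- suppressWarnings(harmonize_panel(panel, cohort_alleles, dos))
  acts <- setNames(out$report$action, out$report$snp_id)
  expect_identical(unname(acts[c("s1", "s2", "s3", "s4")]),
    c("keep", "flip", "strand", "strand_flip"))
  expect_identical(unname(acts["s5"]), "drop_palindromic") # A/T at eaf 0.5
  expect_identical(unname(acts["s7"]), "drop_irreconcilable") # A/G vs A/C
  # dosage transforms: kept as-is for keep/strand, 2-d for flip/strand_flip
  expect_equal(unname(out$dosages[1, c("s1", "s3")]), c(0, 0))
  expect_equal(unname(out$dosages[1, c("s2", "s4")]), c(2 - 1, 2 - 1))
  expect_false("s5" %in% colnames(out$dosages))
  # strand flip with matching frequencies aligned without a dosage flip
  expect_equal(unname(out$dosages[2, "s3"]), 2)
})

test_that("palindromic SNPs outside the ambiguity window align by frequency", {
  panel <- tibble::tibble(
    snp_id = "p1", effect_allele = "A", other_allele = "T",
    eaf = 0.2, weight = 0.1, weight_se = 0.01, include_flag = TRUE
  )
  # cohort reports the complementary strand: its A allele is the panel's T,
  # so the a1 frequency matches 1 - 0.2
  ca <- tibble::tibble(snp_id = "p1", a1 = "A", a2 = "T", eaf = 0.8)
  dos <- matrix(2, 1, 1, dimnames = list(NULL, "p1"))
  out <- harmonize_panel(panel, ca, dos)
  expect_identical(out$report$action, "flip")
  expect_equal(unname(out$dosages[1, 1]), 0)
})

test_that("harmonization fails loudly on an empty intersection", {
  ca <- tibble::tibble(snp_id = "zzz", a1 = "A", a2 = "G")
  dos <- matrix(1, 1, 1, dimnames = list(NULL, "zzz"))
  expect_error(harmonize_panel(tiny_panel, ca, dos), "no SNPs shared")
})

test_that("add_grs respects include flags and matches a direct computation", {
  co <- small_cohort
  panel <- small_panel
  direct <- weighted_grs(as.matrix(co[panel$snp_id]), panel$weight, panel$eaf)
  expect_equal(co$grs, direct$value)
  panel77 <- panel
  panel77$include_flag[1:5] <- FALSE
  co77 <- add_grs(co, panel77)
  expect_false(isTRUE(all.equal(co77$grs, co$grs)))
  expect_equal(
    co77$grs,
    weighted_grs(as.matrix(co[panel$snp_id[-(1:5)]]), panel$weight[-(1:5)])$value
  )
})

test_that("offspring score is the mid-parent mean plus Mendelian noise", {
  co <- simulate_trios(small_panel, 6000, trio_params(), seed = 31) |>
    add_grs(small_panel)
  m <- co[co$parent_sex == "mother", ]
  f <- co[co$parent_sex == "father", ]
  mid <- (m$true_parent_grs + f$true_parent_grs) / 2
  dev <- m$grs - mid
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(nrow(m))) # zero-mean deviation
  expect_equal(unname(coef(lm(m$grs ~ mid))[2]), 1, tolerance = 0.05)
})
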