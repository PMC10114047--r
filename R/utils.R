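# Internal helpers shared across modules.

#' Derive a deterministic child seed from a master seed and a stream label
#'
#' Lets every stochastic stage of an analysis own an independent random
#' stream while remaining bit-reproducible from one master seed. The result
#' always fits a 32-bit integer.
#'
#' @param seed Master seed (finite numeric scalar).
#' @param stream Character label of the consuming stage.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

# Run code under a local RNG state so library calls never disturb the caller.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required; reproducibility is mandatory", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_prob <- function(x, name, open = TRUE) {
  ok <- if (open) all(x > 0 & x < 1) else all(x >= 0 & x <= 1)
  if (!ok) stop(sprintf("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1]"), call. = FALSE)
  invisible(x)
}

assert_cols <- function(df, cols, what = "data") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what, paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard 95% normal interval on an estimate/SE pair.
ci95 <- function(est, se) {
  tibble::tibble(ci_lower = est - 1.96 * se, ci_upper = est + 1.96 * se)
}

dosage_cols <- function(cohort) grep("^snp_", names(cohort), value = TRUE)
pc_cols <- function(cohort) grep("^pc_", names(cohort), value = TRUE)
covariate_cols <- function(cohort) grep("^cov_", names(cohort), value = TRUE)
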