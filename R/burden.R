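#' Linear-combination (burden) test for case-parent trios
#'
#' Unweighted burden baseline on the transmission scale: pools the per-variant
#' transmission deviations into a single normal statistic
#' `Z = sum(b - c) / sqrt(sum(b + c))`, with a two-sided p-value. With a
#' single variant `Z^2` equals the single-variant TDT chi-square. Because all
#' variants are summed with equal sign, variants with opposing effect
#' directions cancel — the usual burden-test weakness the adaptive
#' combination avoids.
#'
#' @param counts Output of [count_transmissions()].
#' @return A one-row tibble: `method`, `L` (informative variants),
#'   `statistic` (Z), `p_value`, `direction` (sign of Z).
#' @export
burden_test_trio <- function(counts) {
  counts <- as_tibble(counts)
  use <- (counts$b + counts$c_) > 0
  if (!any(use)) stop("all variants uninformative", call. = FALSE)
  b <- counts$b[use]
  cc <- counts$c_[use]
  z <- sum(b - cc) / sqrt(sum(b + cc))
  tibble(method = "TLC", L = sum(use), statistic = z,
         p_value = 2 * stats::pnorm(-abs(z)),
         direction = sign(z))
}

#' Linear-combination (burden) test for unrelated subjects
#'
#' Regresses the outcome on the unweighted per-subject sum of minor-allele
#' counts over the region's variants (logistic for binary traits, linear for
#' quantitative), adjusting for any covariates, and reports the Wald test of
#' the burden coefficient. Subjects missing a genotype at any region variant
#' are excluded (complete-case burden score).
#'
#' @inheritParams regression_effect
#' @param variants Optional character vector of region variant ids (default:
#'   all variants).
#' @return A one-row tibble: `method`, `L`, `beta_hat`, `statistic` (1-df
#'   Wald chi-square), `p_value`, `direction`.
#' @export
burden_test_unrelated <- function(gm, phenotypes, trait = c("binary", "quantitative"),
                                  outcome = "y", covariates = character(),
                                  variants = NULL) {
  trait <- match.arg(trait)
  gm <- orient_minor(gm)
  phenotypes <- as_tibble(phenotypes)
  vids <- variants %||% gm$variants$variant_id
  j <- match(vids, gm$variants$variant_id)
  assert_that(!anyNA(j), "unknown variant id requested")
  poly <- gm$variants$maf[j] > 0
  if (!any(poly)) stop("no polymorphic variant in region", call. = FALSE)
  j <- j[poly]
  idx <- match(phenotypes$sample_id, gm$samples$sample_id)
  assert_that(!anyNA(idx), "phenotype sample ids not found in genotype matrix")

  burden <- rowSums(gm$geno[idx, j, drop = FALSE])
  y <- phenotypes[[outcome]]
  covmat <- if (length(covariates)) {
    as.matrix(phenotypes[, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  keep <- !is.na(burden) & stats::complete.cases(covmat) & !is.na(y)
  X <- cbind(`(Intercept)` = 1, g = burden[keep], covmat[keep, , drop = FALSE])
  res <- fit_one_variant(X, y[keep], trait, vid = "burden", maf_j = NA_real_)
  tibble(method = "TLC", L = length(j), beta_hat = res$beta_hat,
         statistic = res$statistic, p_value = res$p_value,
         direction = sign(res$beta_hat))
}
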