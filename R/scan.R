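#' Region-by-region association scan
#'
#' Applies one of the region tests to every region of a region table,
#' handling the per-variant summaries (TDT transmission counts for trios,
#' per-variant regression for unrelated subjects), variant filtering,
#' genotype-correlation estimation and sequential resampling. This is the
#' function behind the command-line `test` subcommand.
#'
#' @param gm A [genotype_matrix()].
#' @param trios A [trio_set()] (trio design) or `NULL`.
#' @param phenotypes Phenotype table (unrelated design) or `NULL`.
#' @param regions Output of [map_variants_to_regions()], or `NULL` to test
#'   all variants as a single region.
#' @param design `"trio"` or `"cc"`.
#' @param method `"adabf"`, `"adabf1"`, `"ada"` or `"burden"`.
#' @param trait,outcome,covariates Passed to [regression_effect()] for the
#'   unrelated design.
#' @param prior_sd Prior standard deviation override (`NULL` uses the method
#'   preset).
#' @param B_min,B_max Sequential resampling bounds.
#' @param seed Master seed; per-region seeds derive from it.
#' @param verbose Log per-region progress to stderr.
#' @return A tibble with one row per region: `region`, `L` (variants used),
#'   `method`, `prior_sd`, `minp`, `adjusted_p`, `b_used`, `selected_k`,
#'   `selected_variants` (comma-joined, ranked), `floor`. Burden rows carry
#'   `NA` for the resampling-specific columns.
#' @export
region_scan <- function(gm, trios = NULL, phenotypes = NULL, regions = NULL,
                        design = c("trio", "cc"),
                        method = c("adabf", "adabf1", "ada", "burden"),
                        trait = c("binary", "quantitative"), outcome = "y",
                        covariates = character(), prior_sd = NULL,
                        B_min = 100, B_max = 1e7, seed = 1L, verbose = FALSE) {
  design <- match.arg(design)
  method <- match.arg(method)
  trait <- match.arg(trait)
  if (design == "trio") assert_that(!is.null(trios), "trio design needs `trios`")
  if (design == "cc") assert_that(!is.null(phenotypes), "cc design needs `phenotypes`")
  gm <- orient_minor(gm)
  if (is.null(regions)) {
    regions <- tibble(region = "all", chrom = NA_character_,
                      start = NA_integer_, end = NA_integer_,
                      variant_ids = list(gm$variants$variant_id),
                      n_variants = ncol(gm$geno))
  }

  rows <- purrr::map(seq_len(nrow(regions)), function(i) {
    rid <- regions$region[i]
    vids <- intersect(regions$variant_ids[[i]], gm$variants$variant_id)
    if (length(vids) == 0) {
      if (verbose) message("region ", rid, ": no variants, skipped")
      return(NULL)
    }
    sub <- subset_variants(gm, match(vids, gm$variants$variant_id))
    sub <- drop_monomorphic(sub)
    if (ncol(sub$geno) == 0) {
      if (verbose) message("region ", rid, ": all variants monomorphic, skipped")
      return(NULL)
    }
    rseed <- derive_seed(seed, 10000L + i)

    if (method == "burden") {
      res <- if (design == "trio") {
        burden_test_trio(count_transmissions(sub, trios))
      } else {
        burden_test_unrelated(sub, phenotypes, trait = trait,
                              outcome = outcome, covariates = covariates)
      }
      if (verbose) message("region ", rid, ": TLC p = ", signif(res$p_value, 3))
      return(tibble(region = rid, L = res$L, method = "TLC",
                    prior_sd = NA_real_, minp = NA_real_,
                    adjusted_p = res$p_value, b_used = NA_real_,
                    selected_k = NA_integer_, selected_variants = NA_character_,
                    floor = NA))
    }

    eff <- if (design == "trio") {
      tdt_effect(count_transmissions(sub, trios))
    } else {
      regression_effect(sub, phenotypes, trait = trait, outcome = outcome,
                        covariates = covariates, check_scale = FALSE)
    }
    n_filtered <- sum(eff$flag == "dropped")
    eff <- eff %>% filter(flag != "dropped")
    if (nrow(eff) == 0) {
      if (verbose) message("region ", rid, ": no informative variants, skipped")
      return(NULL)
    }
    R <- if (nrow(eff) > 1) {
      genotype_correlation(sub, founders_only = design == "trio",
                           variants = eff$variant_id)
    } else {
      matrix(1, 1, 1)
    }
    fit <- adabf_test_region(eff, R, method = method, prior_sd = prior_sd,
                             B_min = B_min, B_max = B_max, seed = rseed)
    if (verbose) {
      message("region ", rid, ": ", fit$method, " adjusted p = ",
              signif(fit$adjusted_p, 3), " (B = ", format(fit$B, big.mark = ","),
              ", ", n_filtered, " variant(s) filtered)")
    }
    tibble(region = rid, L = fit$L, method = fit$method,
           prior_sd = sqrt(fit$prior_w), minp = fit$minp,
           adjusted_p = fit$adjusted_p, b_used = fit$B,
           selected_k = fit$selected_k,
           selected_variants = paste(fit$selected_variants, collapse = ","),
           floor = fit$floor)
  })
  bind_rows(rows)
}
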