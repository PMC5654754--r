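# Region-level analysis of one simulated replicate, shared by the
# calibration/power harnesses and the CLI `calibrate` subcommand. Uses the
# vectorized no-covariate fits for speed; agreement with the general
# regression path is covered by tests.

analyze_trio_replicate <- function(sim, methods, B_min = 100, B_max = 1e5,
                                   seed = 1L) {
  counts <- count_transmissions(sim$gm, sim$trios)
  eff <- tdt_effect(counts) %>% filter(flag != "dropped")
  out <- list()
  resampling <- intersect(methods, c("adabf", "adabf1", "ada"))
  if (length(resampling) && nrow(eff) >= 1) {
    R <- if (nrow(eff) > 1) {
      genotype_correlation(sim$gm, founders_only = TRUE,
                           variants = eff$variant_id)
    } else {
      matrix(1, 1, 1)
    }
    for (m in resampling) {
      fit <- adabf_test_region(eff, R, method = m, B_min = B_min,
                               B_max = B_max, seed = seed)
      out[[m]] <- tibble(method = fit$method, p_value = fit$adjusted_p)
    }
  }
  if ("burden" %in% methods) {
    bt <- burden_test_trio(counts)
    out$burden <- tibble(method = "TLC", p_value = bt$p_value)
  }
  bind_rows(out)
}

analyze_cc_replicate <- function(sim, methods, B_min = 100, B_max = 1e5,
                                 seed = 1L) {
  gm <- drop_monomorphic(sim$gm)
  y <- sim$phenotypes$y
  fit0 <- batch_wald(gm$geno, y, trait = "binary")
  eff <- tibble(variant_id = gm$variants$variant_id,
                beta_hat = fit0$beta_hat, var_hat = fit0$var_hat) %>%
    mutate(statistic = beta_hat^2 / var_hat, p_value = chisq1_p(statistic)) %>%
    filter(is.finite(beta_hat), is.finite(var_hat), var_hat > 0)
  out <- list()
  resampling <- intersect(methods, c("adabf", "adabf1", "ada"))
  if (length(resampling) && nrow(eff) >= 1) {
    R <- if (nrow(eff) > 1) {
      genotype_correlation(gm, founders_only = FALSE, variants = eff$variant_id)
    } else {
      matrix(1, 1, 1)
    }
    for (m in resampling) {
      fit <- adabf_test_region(eff, R, method = m, B_min = B_min,
                               B_max = B_max, seed = seed)
      out[[m]] <- tibble(method = fit$method, p_value = fit$adjusted_p)
    }
  }
  if ("burden" %in% methods) {
    bt <- burden_test_unrelated(gm, sim$phenotypes, trait = "binary")
    out$burden <- tibble(method = "TLC", p_value = bt$p_value)
  }
  bind_rows(out)
}

#' Type-I-error and power study
#'
#' Repeatedly simulates a region under the configured disease model, analyses
#' it with the requested methods, and reports empirical rejection rates. With
#' `d = 0` the study is a type-I-error calibration; with `d > 0` it measures
#' power. All methods within a replicate see the same simulated data, and the
#' resampling methods share stage seeds, so method comparisons are matched.
#'
#' @param design `"trio"` or `"cc"` (unrelated case-control).
#' @param methods Any of `"adabf"`, `"adabf1"`, `"ada"`, `"burden"`.
#' @param n_reps Number of simulation replicates.
#' @param d Number of causal variants (0 for the null).
#' @param effect_or Causal odds-ratio magnitude.
#' @param scenario `"deleterious"` or `"mixed"` (about half protective).
#' @param n_trios Trios per replicate (trio design).
#' @param n_cases,n_controls Case/control quotas (cc design).
#' @param alpha_levels Significance levels for the rejection summary.
#' @param n_pools Number of distinct haplotype pools cycled over (emulating
#'   replication across regions).
#' @param pool_args List of extra arguments to [make_pool()].
#' @param maf_range Pool-MAF range causal variants are drawn from.
#' @param B_min,B_max Resampling schedule bounds passed to
#'   [adabf_test_region()].
#' @param seed Master seed; every pool, replicate and ensemble seed derives
#'   from it.
#' @return A list with `replicates` (tibble: `rep`, `method`, `p_value`) and
#'   `summary` (tibble: `method`, `alpha`, `rate`, `n`, 99% binomial
#'   confidence bounds `lo`/`hi`).
#' @export
error_and_power_study <- function(design = c("trio", "cc"),
                                  methods = c("adabf", "adabf1", "ada", "burden"),
                                  n_reps = 200, d = 0, effect_or = 1.5,
                                  scenario = c("deleterious", "mixed"),
                                  n_trios = 500, n_cases = 500, n_controls = 500,
                                  alpha_levels = c(0.05, 0.01),
                                  n_pools = 20, pool_args = list(),
                                  maf_range = c(0, 0.5),
                                  B_min = 100, B_max = 1e5, seed = 1L) {
  design <- match.arg(design)
  scenario <- match.arg(scenario)
  pools <- purrr::map(seq_len(n_pools), function(i) {
    do.call(make_pool, c(list(seed = derive_seed(seed, 900000 + i)), pool_args))
  })
  reps <- purrr::map(seq_len(n_reps), function(r) {
    pool <- pools[[(r - 1L) %% n_pools + 1L]]
    sim_seed <- derive_seed(seed, 2L * r)
    ens_seed <- derive_seed(seed, 2L * r + 1L)
    sim <- if (design == "trio") {
      simulate_trios(pool, n_trios = n_trios, d = d, effect_or = effect_or,
                     scenario = scenario, maf_range = maf_range, seed = sim_seed)
    } else {
      simulate_case_control(pool, n_cases = n_cases, n_controls = n_controls,
                            d = d, effect_or = effect_or, scenario = scenario,
                            maf_range = maf_range, seed = sim_seed)
    }
    res <- if (design == "trio") {
      analyze_trio_replicate(sim, methods, B_min, B_max, ens_seed)
    } else {
      analyze_cc_replicate(sim, methods, B_min, B_max, ens_seed)
    }
    res$rep <- r
    res
  })
  replicates <- bind_rows(reps)
  list(replicates = replicates,
       summary = summarize_rejection(replicates, alpha_levels))
}

#' Empirical rejection rates with 99% binomial confidence bounds
#'
#' @param replicates Tibble with `method` and `p_value` (one row per method
#'   per replicate), e.g. `error_and_power_study()$replicates`.
#' @param alpha_levels Significance levels.
#' @return Tibble: `method`, `alpha`, `n`, `rate`, `lo`, `hi` (normal-
#'   approximation 99% interval around `alpha` for calibration checks).
#' @export
summarize_rejection <- function(replicates, alpha_levels = c(0.05, 0.01)) {
  purrr::map_dfr(alpha_levels, function(a) {
    replicates %>%
      group_by(method) %>%
      summarise(alpha = a, n = n(), rate = mean(p_value <= a), .groups = "drop") %>%
      mutate(lo = alpha - stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / n),
             hi = alpha + stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / n))
  })
}

#' Causal-variant ranking: Bayes factor versus p-value
#'
#' Repeats the single-causal-variant experiment: a region is simulated with
#' one causal variant of odds ratio `effect_or` under the case-control
#' design, per-variant logistic Wald summaries and Wakefield Bayes factors
#' are computed, and the rank of the causal variant under each ordering is
#' recorded (rank 1 = most significant; ties broken by ascending variant
#' index). Replicates where the causal variant is monomorphic in the drawn
#' sample are redrawn, since neither ranking is defined for an untestable
#' variant; stratification uses the causal variant's pool frequency.
#'
#' @param n_reps Number of recorded replicates.
#' @param n_cases,n_controls Sample quotas per replicate.
#' @param effect_or Causal odds ratio (default 1.5).
#' @param prior_sd Prior standard deviation for the Bayes factor.
#' @param alpha Disease-model intercept (default `log(0.05/0.95)`).
#' @param n_pools,pool_args As in [error_and_power_study()].
#' @param seed Master seed.
#' @return Tibble with one row per replicate: `rep`, `causal_maf` (pool
#'   frequency), `L_eff` (variants polymorphic in the sample), `rank_bf`,
#'   `rank_p`. Summarise with [summarize_ranking()].
#' @export
ranking_experiment <- function(n_reps = 1000, n_cases = 1000, n_controls = 1000,
                               effect_or = 1.5, prior_sd = 0.2,
                               alpha = log(0.05 / 0.95),
                               n_pools = 20, pool_args = list(), seed = 1L) {
  pools <- purrr::map(seq_len(n_pools), function(i) {
    do.call(make_pool, c(list(seed = derive_seed(seed, 800000 + i)), pool_args))
  })
  W <- prior_sd^2
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    pool <- pools[[(r - 1L) %% n_pools + 1L]]
    for (attempt in 1:200) {
      sim_seed <- derive_seed(seed, 1000L * r + attempt)
      set.seed(derive_seed(seed, 500000L + 1000L * r + attempt))
      causal <- sample.int(pool$L, 1L)
      sim <- simulate_case_control(pool, n_cases = n_cases,
                                   n_controls = n_controls,
                                   causal_sites = causal,
                                   causal_beta = log(effect_or),
                                   alpha = alpha, seed = sim_seed)
      gm <- drop_monomorphic(sim$gm)
      cid <- pool$variants$variant_id[causal]
      if (cid %in% gm$variants$variant_id) break
      sim <- NULL
    }
    if (is.null(sim)) {
      stop("causal variant monomorphic in 200 consecutive draws", call. = FALSE)
    }
    fit0 <- batch_wald(gm$geno, sim$phenotypes$y, trait = "binary")
    lbf <- wakefield_log_bf(fit0$beta_hat, fit0$var_hat, W)
    pv <- chisq1_p(fit0$beta_hat^2 / fit0$var_hat)
    ci <- match(cid, gm$variants$variant_id)
    rows[[r]] <- tibble(
      rep = r,
      causal_maf = pool$maf[causal],
      L_eff = ncol(gm$geno),
      rank_bf = rank(-lbf, ties.method = "first")[ci],
      rank_p = rank(pv, ties.method = "first")[ci]
    )
  }
  bind_rows(rows)
}

#' Stratified summary of a ranking experiment
#'
#' @param records Output of [ranking_experiment()].
#' @param breaks MAF stratum boundaries (default the conventional
#'   `<= 0.1%`, `0.1-1%`, `1-5%`, `> 5%` strata).
#' @return Tibble per stratum: `n`, `mean_rank_bf`, `mean_rank_p`,
#'   `n_bf_better`, `n_equal`, `n_p_better`.
#' @export
summarize_ranking <- function(records,
                              breaks = c(0, 0.001, 0.01, 0.05, 0.5)) {
  labs <- paste0("(", head(breaks, -1) * 100, "%,", breaks[-1] * 100, "%]")
  records %>%
    mutate(stratum = cut(causal_maf, breaks = breaks, labels = labs,
                         include.lowest = TRUE)) %>%
    group_by(stratum) %>%
    summarise(n = n(),
              mean_rank_bf = mean(rank_bf),
              mean_rank_p = mean(rank_p),
              n_bf_better = sum(rank_bf < rank_p),
              n_equal = sum(rank_bf == rank_p),
              n_p_better = sum(rank_bf > rank_p),
              .groups = "drop")
}
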