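#' Synthetic haplotype pool with an L-shaped allele-frequency spectrum
#'
#' Generates a pool of `H` binary haplotypes over `L` sites whose target
#' minor-allele frequencies follow a density proportional to `1/f` on
#' `[1/H, 0.5]` — the L-shaped spectrum typical of sequence data, dominated
#' by rare variants. Local linkage disequilibrium is induced by a latent
#' Gaussian first-order autoregressive process with parameter `ld`
#' (thresholded per site at its target frequency); the realized correlation
#' between adjacent binary sites is attenuated below `ld`, increasingly so
#' for rare sites, because binary margins bound the attainable correlation.
#' Columns monomorphic after thresholding are redrawn (independently of
#' their neighbours) so every site is polymorphic; sites with realized
#' frequency above 0.5 are flipped.
#'
#' @param L Number of variant sites (default 150, a typical 20 kb region).
#' @param H Number of haplotypes in the pool (default 10,000).
#' @param ld Latent autoregressive correlation in `[0, 1)` (default 0.5,
#'   moderate local LD; 0 gives independent sites).
#' @param region_bp Length of the emulated region in base pairs; site
#'   positions are drawn uniformly along it (default 20,000).
#' @param chrom Chromosome label for the emitted variants (default `"1"`).
#' @param seed Integer seed; the pool is bit-reproducible.
#' @return An object of class `haplotype_pool`: list with `hap` (`H x L` 0/1
#'   matrix), `maf` (realized frequencies in `(0, 0.5]`), `variants` (tibble
#'   of ids/positions/alleles) and the generation parameters.
#' @export
make_pool <- function(L = 150, H = 10000, ld = 0.5, region_bp = 20000,
                      chrom = "1", seed = 1L) {
  assert_that(H >= 2 && L >= 1, "need H >= 2 and L >= 1")
  assert_that(ld >= 0 && ld < 1, "ld must be in [0, 1)")
  set.seed(seed)
  fmin <- 1 / H
  fmax <- 0.5
  # inverse CDF of density proportional to 1/f on [fmin, fmax]
  f <- fmin * (fmax / fmin)^stats::runif(L)
  thr <- stats::qnorm(f)

  Z <- matrix(stats::rnorm(H * L), nrow = H)
  if (ld > 0 && L > 1) {
    for (l in 2:L) Z[, l] <- ld * Z[, l - 1] + sqrt(1 - ld^2) * Z[, l]
  }
  hap <- matrix(as.integer(Z < rep(thr, each = H)), nrow = H)

  # redraw monomorphic columns (expected count at f ~ 1/H is 1) until every
  # site segregates; redrawn columns lose LD with neighbours
  repeat {
    cnt <- colSums(hap)
    mono <- cnt == 0L | cnt == H
    if (!any(mono)) break
    for (l in which(mono)) {
      hap[, l] <- as.integer(stats::rnorm(H) < thr[l])
    }
  }
  freq <- colMeans(hap)
  flip <- freq > 0.5
  if (any(flip)) {
    hap[, flip] <- 1L - hap[, flip, drop = FALSE]
    freq[flip] <- 1 - freq[flip]
  }

  pos <- sort(sample.int(region_bp, L))
  variants <- tibble(
    variant_id = sprintf("v%03d", seq_len(L)),
    chrom = chrom, pos = pos,
    allele_minor = "A", allele_major = "G"
  )
  colnames(hap) <- variants$variant_id
  structure(list(hap = hap, maf = freq, variants = variants,
                 H = H, L = L, ld = ld, region_bp = region_bp, seed = seed),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("<haplotype_pool> %d haplotypes x %d sites, MAF in [%.2g, %.2g], ld = %.2f\n",
              x$H, x$L, min(x$maf), max(x$maf), x$ld))
  invisible(x)
}

# Pick causal sites and signed effects for a disease model.
# scenario "deleterious": all betas positive; "mixed": alternate +/- so ~50%
# of the causal variants are protective.
pick_causal <- function(pool, d, effect_or, scenario, maf_range = c(0, 0.5)) {
  if (d == 0) return(list(sites = integer(0), beta = numeric(0)))
  eligible <- which(pool$maf >= maf_range[1] & pool$maf <= maf_range[2])
  assert_that(d <= length(eligible), "fewer eligible sites than causal variants")
  sites <- sort(sample(eligible, d))
  beta <- rep(log(effect_or), d)
  if (scenario == "mixed") {
    sgn <- rep(c(1, -1), length.out = d)
    beta <- beta * sample(sgn)
  }
  list(sites = sites, beta = beta)
}

#' Simulate ascertained case-parent trios from a haplotype pool
#'
#' Each family draws four parental haplotypes with replacement from the pool;
#' each parent transmits one haplotype to the child at random. The child's
#' disease status follows the logistic model
#' `logit P(Y = 1) = alpha + sum_k beta_k G_k` over the causal sites'
#' genotype scores, and families are retained only when the child is affected
#' (case-parent ascertainment), until `n_trios` have been collected. The
#' default `alpha = log(0.05/0.95) = -2.94` gives a 5% disease prevalence.
#' Rejection happens on haplotype indices; full genotype vectors are
#' materialized only for accepted families, so ascertainment at a 5%
#' prevalence stays cheap.
#'
#' @param pool A [make_pool()] result.
#' @param n_trios Number of ascertained trios to collect.
#' @param d Number of causal variants (0 for a null region).
#' @param effect_or Odds ratio magnitude of a causal allele (e.g. 1.5 or
#'   1.25); protective alleles get `1/effect_or`.
#' @param scenario `"deleterious"` (all causal alleles risk-increasing) or
#'   `"mixed"` (about half protective).
#' @param alpha Intercept on the log-odds scale (default `log(0.05/0.95)`).
#' @param causal_sites,causal_beta Explicit causal specification overriding
#'   `d`/`effect_or`/`scenario` (column indices into the pool and signed
#'   log-odds-ratios).
#' @param maf_range Eligible pool-MAF range for random causal selection.
#' @param seed Integer seed.
#' @return A list: `gm` (a [genotype_matrix()] of parents and children),
#'   `trios` (a [trio_set()]), `causal` (tibble of causal sites with pool
#'   MAF and signed effect) and `prevalence` (acceptance rate actually
#'   observed).
#' @export
simulate_trios <- function(pool, n_trios = 2000, d = 0, effect_or = 1.5,
                           scenario = c("deleterious", "mixed"),
                           alpha = log(0.05 / 0.95),
                           causal_sites = NULL, causal_beta = NULL,
                           maf_range = c(0, 0.5), seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  if (is.null(causal_sites)) {
    cz <- pick_causal(pool, d, effect_or, scenario, maf_range)
    causal_sites <- cz$sites
    causal_beta <- cz$beta
  }
  H <- pool$H
  null_model <- length(causal_sites) == 0

  acc_f <- stats::plogis(alpha)
  if (acc_f < 1e-4) stop("expected ascertainment probability below 1e-4", call. = FALSE)

  hf1 <- hf2 <- hm1 <- hm2 <- tf <- tm <- integer(0)
  n_drawn <- 0L
  n_affected <- 0L
  while (length(hf1) < n_trios) {
    batch <- max(1000L, ceiling((n_trios - length(hf1)) / acc_f * 1.3))
    f1 <- sample.int(H, batch, replace = TRUE)
    f2 <- sample.int(H, batch, replace = TRUE)
    m1 <- sample.int(H, batch, replace = TRUE)
    m2 <- sample.int(H, batch, replace = TRUE)
    wf <- sample.int(2L, batch, replace = TRUE)  # which paternal haplotype transmitted
    wm <- sample.int(2L, batch, replace = TRUE)
    if (null_model) {
      prob <- rep(acc_f, batch)
    } else {
      cf <- ifelse(wf == 1L, f1, f2)
      cm <- ifelse(wm == 1L, m1, m2)
      gc_causal <- pool$hap[cf, causal_sites, drop = FALSE] +
        pool$hap[cm, causal_sites, drop = FALSE]
      prob <- stats::plogis(alpha + drop(gc_causal %*% causal_beta))
    }
    keep <- stats::runif(batch) < prob
    n_drawn <- n_drawn + batch
    n_affected <- n_affected + sum(keep)
    hf1 <- c(hf1, f1[keep]); hf2 <- c(hf2, f2[keep])
    hm1 <- c(hm1, m1[keep]); hm2 <- c(hm2, m2[keep])
    tf <- c(tf, wf[keep]); tm <- c(tm, wm[keep])
    if (n_drawn > 200 * n_trios / acc_f) {
      stop("ascertainment too inefficient; check the disease model", call. = FALSE)
    }
  }
  idx <- seq_len(n_trios)
  hf1 <- hf1[idx]; hf2 <- hf2[idx]; hm1 <- hm1[idx]; hm2 <- hm2[idx]
  tf <- tf[idx]; tm <- tm[idx]
  prevalence <- n_affected / n_drawn

  cf <- ifelse(tf == 1L, hf1, hf2)
  cm <- ifelse(tm == 1L, hm1, hm2)
  gfa <- pool$hap[hf1, , drop = FALSE] + pool$hap[hf2, , drop = FALSE]
  gmo <- pool$hap[hm1, , drop = FALSE] + pool$hap[hm2, , drop = FALSE]
  gch <- pool$hap[cf, , drop = FALSE] + pool$hap[cm, , drop = FALSE]

  fid <- sprintf("fam%05d", idx)
  samples <- tibble(
    sample_id = c(paste0(fid, "_f"), paste0(fid, "_m"), paste0(fid, "_c")),
    role = rep(c("founder", "founder", "offspring"), each = n_trios)
  )
  geno <- rbind(gfa, gmo, gch)
  gm <- genotype_matrix(geno, pool$variants, samples)
  gm <- orient_minor(gm)
  trios <- trio_set(father = paste0(fid, "_f"), mother = paste0(fid, "_m"),
                    child = paste0(fid, "_c"), family_id = fid)
  causal <- tibble(variant_id = pool$variants$variant_id[causal_sites],
                   site = causal_sites, pool_maf = pool$maf[causal_sites],
                   beta = causal_beta)
  list(gm = gm, trios = trios, causal = causal, prevalence = prevalence)
}

#' Simulate an ascertained case-control sample from a haplotype pool
#'
#' Subjects are formed from two pool haplotypes drawn with replacement;
#' disease status follows the same logistic model as [simulate_trios()].
#' Subjects are accepted into the case or control quota according to their
#' simulated status until both quotas are met.
#'
#' @inheritParams simulate_trios
#' @param n_cases,n_controls Quotas (defaults 1000 and 1000).
#' @return A list: `gm` (a [genotype_matrix()] with role `"unrelated"`),
#'   `phenotypes` (tibble `sample_id`, `y`), `causal`, `prevalence`.
#' @export
simulate_case_control <- function(pool, n_cases = 1000, n_controls = 1000,
                                  d = 0, effect_or = 1.5,
                                  scenario = c("deleterious", "mixed"),
                                  alpha = log(0.05 / 0.95),
                                  causal_sites = NULL, causal_beta = NULL,
                                  maf_range = c(0, 0.5), seed = 1L) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  if (is.null(causal_sites)) {
    cz <- pick_causal(pool, d, effect_or, scenario, maf_range)
    causal_sites <- cz$sites
    causal_beta <- cz$beta
  }
  H <- pool$H
  null_model <- length(causal_sites) == 0
  prev <- stats::plogis(alpha)
  if (min(prev, 1 - prev) < 1e-4) {
    stop("expected ascertainment probability below 1e-4", call. = FALSE)
  }

  ca1 <- ca2 <- co1 <- co2 <- integer(0)
  n_drawn <- 0L
  n_affected <- 0L
  while (length(ca1) < n_cases || length(co1) < n_controls) {
    need_cases <- n_cases - length(ca1)
    need_controls <- n_controls - length(co1)
    batch <- max(2000L, ceiling(1.3 * max(need_cases / prev,
                                          need_controls / (1 - prev))))
    h1 <- sample.int(H, batch, replace = TRUE)
    h2 <- sample.int(H, batch, replace = TRUE)
    if (null_model) {
      prob <- rep(prev, batch)
    } else {
      gc_causal <- pool$hap[h1, causal_sites, drop = FALSE] +
        pool$hap[h2, causal_sites, drop = FALSE]
      prob <- stats::plogis(alpha + drop(gc_causal %*% causal_beta))
    }
    yy <- stats::runif(batch) < prob
    n_drawn <- n_drawn + batch
    n_affected <- n_affected + sum(yy)
    take_case <- which(yy)[seq_len(min(sum(yy), need_cases))]
    take_ctrl <- which(!yy)[seq_len(min(sum(!yy), need_controls))]
    ca1 <- c(ca1, h1[take_case]); ca2 <- c(ca2, h2[take_case])
    co1 <- c(co1, h1[take_ctrl]); co2 <- c(co2, h2[take_ctrl])
    if (n_drawn > 200 * (n_cases + n_controls) / min(prev, 1 - prev)) {
      stop("ascertainment too inefficient; check the disease model", call. = FALSE)
    }
  }
  h1 <- c(ca1, co1)
  h2 <- c(ca2, co2)
  y <- rep(c(1L, 0L), c(n_cases, n_controls))
  geno <- pool$hap[h1, , drop = FALSE] + pool$hap[h2, , drop = FALSE]
  samples <- tibble(sample_id = sprintf("s%05d", seq_along(y)), role = "unrelated")
  gm <- genotype_matrix(geno, pool$variants, samples)
  gm <- orient_minor(gm)
  phenotypes <- tibble(sample_id = samples$sample_id, y = y)
  causal <- tibble(variant_id = pool$variants$variant_id[causal_sites],
                   site = causal_sites, pool_maf = pool$maf[causal_sites],
                   beta = causal_beta)
  list(gm = gm, phenotypes = phenotypes, causal = causal,
       prevalence = n_affected / n_drawn)
}
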