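test_that("summary scores are top-k sums with deterministic ties", {
  sc <- summary_scores(c(2, 1, -1))
  expect_equal(sc$s_k, c(2, 3, 2))  # not monotone once scores go negative

  sc <- summary_scores(rep(1.5, 4))
  expect_equal(sc$s_k, 1.5 * (1:4))
  expect_equal(sc$variant_id, paste0("v", 1:4))  # ties by ascending index

  # exhaustive subset oracle: top-k sum is the max subset sum of size k
  set.seed(41)
  x <- rnorm(8)
  sc <- summary_scores(x)
  for (k in 1:8) {
    best <- max(combn(8, k, function(ix) sum(x[ix])))
    expect_equal(sc$s_k[k], best)
  }

  expect_error(summary_scores(c(1, NA)), "finite")
  expect_error(summary_scores(c(1, Inf)), "finite")
})

test_that("genotype correlation matches direct computation and stays PSD", {
  set.seed(42)
  g <- matrix(rbinom(600, 2, 0.3), ncol = 3)
  g[, 3] <- g[, 1]  # duplicated column
  gm <- fix_gm(g)
  R <- genotype_correlation(gm, founders_only = FALSE)
  expect_equal(R[1, 3], 1)
  # the duplicated column makes R singular, so the PSD repair perturbs
  # entries at the eigenvalue-clip floor
  expect_equal(R[1, 2], cor(g[, 1], g[, 2]), tolerance = 1e-8)
  expect_equal(diag(R), setNames(rep(1, 3), colnames(R)))
  expect_true(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)

  # independent columns at large n: near-zero correlation
  set.seed(43)
  big <- matrix(rbinom(2 * 10000, 2, 0.3), ncol = 2)
  Rb <- genotype_correlation(fix_gm(big), founders_only = FALSE)
  expect_lt(abs(Rb[1, 2]), 0.05)

  # monomorphic column is rejected
  mono <- cbind(rbinom(50, 2, 0.4), 0L)
  expect_error(genotype_correlation(fix_gm(mono), founders_only = FALSE),
               "monomorphic")
})

test_that("trio correlation uses founder genotypes only", {
  fx <- fix_random_trios(n_trios = 60, L = 4, maf = rep(0.4, 4), seed = 44)
  R <- genotype_correlation(fx$gm, founders_only = TRUE)
  founders <- fx$gm$geno[fx$gm$samples$role == "founder", ]
  expect_equal(unname(R), unname(cor(founders)), tolerance = 1e-12)
})

test_that("PSD repair clips negative eigenvalues and keeps unit diagonal", {
  # a plausible-looking matrix that is not PSD
  R <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.9,
                -0.9, 0.9, 1), 3, 3)
  expect_lt(min(eigen(R, only.values = TRUE)$values), 0)
  R2 <- adabf:::make_psd(R)
  expect_gte(min(eigen(R2, only.values = TRUE)$values), 0)
  expect_equal(diag(R2), rep(1, 3))
  expect_equal(R2, t(R2))
})

test_that("null resampling reproduces the target variances and correlation", {
  v <- c(0.5, 0.02, 0.1)
  R <- diag(3)
  draws <- resample_null(v, R, B = 1e5, seed = 51)
  expect_equal(dim(draws), c(1e5, 3))
  expect_lt(max(abs(apply(draws, 2, var) / v - 1)), 0.03)

  R2 <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  d2 <- resample_null(c(1, 1), R2, B = 1e5, seed = 52)
  expect_lt(abs(cor(d2[, 1], d2[, 2]) - 0.9), 0.01)

  one <- resample_null(v, R, B = 1, seed = 53)
  expect_equal(one, resample_null(v, R, B = 1, seed = 53))
  expect_equal(nrow(one), 1)
})

test_that("min-P counting equals a hand-enumerated oracle", {
  # hand-listed tiny score matrices, L = 2, B = 5
  obs <- c(1.4, 2.1)
  S <- rbind(c(0.5, 2.5), c(1.4, 2.1), c(2.0, 0.3), c(-1.0, 1.0), c(1.5, 2.2))
  got <- adabf:::artp_counting(obs, S)
  want <- oracle_artp(obs, S)
  expect_equal(got$p_k, want$p_k)
  expect_equal(got$minp, want$minp)
  expect_equal(got$adjusted_p, want$adjusted_p)

  # random small ensembles, exact equality including tie handling
  set.seed(61)
  for (i in 1:25) {
    L <- sample(1:3, 1)
    B <- sample(2:10, 1)
    S <- matrix(sample(seq(-2, 2, 0.5), B * L, replace = TRUE), B, L)
    obs <- sample(seq(-2, 2, 0.5), L, replace = TRUE)
    got <- adabf:::artp_counting(obs, S)
    want <- oracle_artp(obs, S)
    expect_equal(got$p_k, want$p_k)
    expect_equal(got$adjusted_p, want$adjusted_p)
  }
})

test_that("an observed region dominating every resample is floored at 1/B", {
  eff <- fix_effects(c(8, -7), c(0.01, 0.01))  # overwhelming signal
  res <- artp_pvalue(eff, diag(2), B = 50, transform = "adabf", seed = 7)
  expect_equal(res$adjusted_p, 1 / 50)
  expect_true(res$floor)
})

test_that("counting is invariant to variant order and to positive rescaling", {
  set.seed(62)
  B <- 40; L <- 6
  S <- matrix(rnorm(B * L), B, L)
  obs <- rnorm(L)
  base <- adabf:::artp_counting(sort_curve(obs), topk_matrix(S))
  # permuting variants permutes columns before the top-k sort: identical
  perm <- sample(L)
  permuted <- adabf:::artp_counting(sort_curve(obs[perm]), topk_matrix(S[, perm]))
  expect_equal(permuted$adjusted_p, base$adjusted_p)
  expect_equal(permuted$minp, base$minp)
  # jointly rescaling all scores by a positive constant: identical
  scaled <- adabf:::artp_counting(sort_curve(3 * obs), topk_matrix(3 * S))
  expect_equal(scaled$adjusted_p, base$adjusted_p)
  expect_equal(scaled$p_k, base$p_k)
})

test_that("a region that is itself a null draw has a calibrated adjusted p", {
  set.seed(63)
  L <- 5
  v <- runif(L, 0.01, 0.2)
  R <- diag(L)
  pvals <- replicate(400, {
    eff <- fix_effects(rnorm(L, 0, sqrt(v)), v)
    artp_pvalue(eff, R, B = 150, transform = "adabf",
                seed = sample.int(1e6, 1))$adjusted_p
  })
  expect_true(all(pvals >= 1 / 150 & pvals <= 1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("with a single variant the adjusted p converges to the Wald p", {
  set.seed(64)
  beta <- 0.35; v <- 0.03
  eff <- fix_effects(beta, v)
  wald_p <- pchisq(beta^2 / v, 1, lower.tail = FALSE)
  for (tr in c("adabf", "ada")) {
    res <- artp_pvalue(eff, matrix(1, 1, 1), B = 2e4, transform = tr, seed = 9)
    expect_lt(abs(res$adjusted_p - wald_p),
              3 * sqrt(wald_p * (1 - wald_p) / 2e4) + 1e-4)
  }
})

test_that("sequential escalation follows the 10/B stopping rule", {
  set.seed(65)
  # a null-looking region stops at the first stage
  effn <- fix_effects(rnorm(4, 0, 0.05), rep(0.04, 4))
  fit <- adabf_test_region(effn, diag(4), method = "adabf",
                           B_min = 100, B_max = 1e5, seed = 10)
  expect_equal(fit$B, 100)
  expect_gt(fit$adjusted_p, 10 / 100)

  # a strong region escalates and satisfies the loop invariant
  effs <- fix_effects(c(1.2, 0.9, 0.1), rep(0.02, 3))
  fit2 <- adabf_test_region(effs, diag(3), method = "adabf",
                            B_min = 100, B_max = 1e4, seed = 11)
  expect_true(fit2$adjusted_p <= 10 / fit2$B || fit2$B == 1e4)
  expect_gt(fit2$B, 100)

  # determinism: identical calls give identical results
  fit3 <- adabf_test_region(effs, diag(3), method = "adabf",
                            B_min = 100, B_max = 1e4, seed = 11)
  expect_identical(glance(fit2), glance(fit3))
})

test_that("method presets set the prior and the ADA transform", {
  eff <- fix_effects(c(0.4, -0.2), c(0.02, 0.05))
  f1 <- adabf_test_region(eff, diag(2), method = "adabf", seed = 1, B_max = 100)
  f2 <- adabf_test_region(eff, diag(2), method = "adabf1", seed = 1, B_max = 100)
  f3 <- adabf_test_region(eff, diag(2), method = "ada", seed = 1, B_max = 100)
  expect_equal(f1$prior_w, 0.04)
  expect_equal(f2$prior_w, 0.01)
  expect_equal(f3$transform, "ada")
  expect_equal(f3$method, "ADA")
  # ADA scores are -log p of the observed Wald statistics
  expect_equal(f3$score_curve$s_k[1], max(-log(eff$p_value)))
})
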