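test_that("transmission counting handles the canonical trio configurations", {
  trios <- fix_one_trio()

  # both parents heterozygous, child homozygous minor: two minor transmissions
  cnt <- count_transmissions(fix_trio_gm(1L, 1L, 2L), trios)
  expect_equal(cnt$b, 2L)
  expect_equal(cnt$c_, 0L)

  # het x hom-major, het child: the het parent must have given the minor
  cnt <- count_transmissions(fix_trio_gm(1L, 0L, 1L), trios)
  expect_equal(cnt$b, 1L)
  expect_equal(cnt$c_, 0L)

  # double-het parents with het child: ambiguous pair counted once each way
  cnt <- count_transmissions(fix_trio_gm(1L, 1L, 1L), trios)
  expect_equal(cnt$b, 1L)
  expect_equal(cnt$c_, 1L)

  # homozygous parents contribute nothing
  cnt <- count_transmissions(fix_trio_gm(2L, 0L, 1L), trios)
  expect_equal(cnt$n_informative, 0L)
  expect_equal(cnt$n_mendel, 0L)

  # Mendelian inconsistency is skipped and tallied
  cnt <- count_transmissions(fix_trio_gm(0L, 0L, 2L), trios)
  expect_equal(cnt$n_informative, 0L)
  expect_equal(cnt$n_mendel, 1L)

  # missing genotype in the trio: skipped and tallied
  cnt <- count_transmissions(fix_trio_gm(1L, NA_integer_, 1L), trios)
  expect_equal(cnt$n_informative, 0L)
  expect_equal(cnt$n_missing, 1L)
})

test_that("transmission counts match a per-trio brute-force oracle", {
  for (seed in 1:4) {
    fx <- fix_random_trios(n_trios = sample(5:20, 1), L = sample(3:10, 1),
                           miss_rate = if (seed > 2) 0.1 else 0, seed = seed)
    cnt <- count_transmissions(fx$gm, fx$trios)
    # the oracle counts on the raw (pool-oriented) genotypes; orientation can
    # flip rare columns, swapping b and c there
    gm_o <- orient_minor(fx$gm)
    orc <- oracle_count(fx$gf, fx$gmo, fx$gc)
    same <- which(gm_o$variants$allele_minor == "A")
    expect_equal(cnt$b[same], orc$b[same])
    expect_equal(cnt$c_[same], orc$c_[same])
    flipped <- which(gm_o$variants$allele_minor == "G")
    expect_equal(cnt$b[flipped], orc$c_[flipped])
    expect_equal(cnt$c_[flipped], orc$b[flipped])
    expect_equal(cnt$n_mendel, orc$mendel)
    expect_equal(cnt$n_missing, orc$missing)
    expect_equal(sum(cnt$n_informative), sum(orc$b + orc$c_))
  }
})

test_that("TDT effect summaries reproduce the published worked examples", {
  counts <- tibble::tibble(
    variant_id = c("rs580984", "rs747990", "rs525420"),
    b = c(607L, 481L, 474L), c_ = c(484L, 604L, 618L))
  eff <- tdt_effect(counts)
  expect_equal(round(eff$or, 3), c(1.254, 0.796, 0.767))
  expect_equal(round(eff$statistic, 2), c(13.87, 13.94, 18.99))
  expect_equal(eff$statistic, ((eff$b - eff$c_) / sqrt(eff$b + eff$c_))^2)
  expect_equal(eff$or, eff$b / eff$c_)
  expect_equal(exp(eff$beta_hat), eff$b / eff$c_)
})

test_that("TDT handles symmetry, zero cells and uninformative variants", {
  eff <- tdt_effect(tibble::tibble(b = 50L, c_ = 50L))
  expect_equal(eff$beta_hat, 0)
  expect_equal(eff$statistic, 0)
  expect_equal(eff$p_value, 1)

  eff <- tdt_effect(tibble::tibble(b = c(5L, 0L, 0L), c_ = c(0L, 7L, 0L)))
  expect_equal(eff$flag, c("corrected", "corrected", "dropped"))
  expect_true(all(is.finite(eff$beta_hat[1:2])))
  expect_equal(eff$beta_hat[1], log(5.5 / 0.5))
  expect_true(is.na(eff$p_value[3]))

  eff_drop <- tdt_effect(tibble::tibble(b = 0L, c_ = 7L), zero_cell = "drop")
  expect_equal(eff_drop$flag, "dropped")
})

test_that("allele-label flip maps b<->c and negates the effect", {
  fx <- fix_random_trios(n_trios = 30, L = 5, maf = rep(0.4, 5), seed = 9)
  cnt <- count_transmissions(fx$gm, fx$trios)
  flipped_gm <- fx$gm
  flipped_gm$geno <- 2L - flipped_gm$geno
  tmp <- flipped_gm$variants$allele_minor
  flipped_gm$variants$allele_minor <- flipped_gm$variants$allele_major
  flipped_gm$variants$allele_major <- tmp
  cnt2 <- count_transmissions(flipped_gm, fx$trios)
  # orientation restores the minor-allele coding, so counts are unchanged
  expect_equal(cnt2$b, cnt$b)
  expect_equal(cnt2$c_, cnt$c_)

  # a literal swap of the counts negates beta and preserves the statistic
  e1 <- tdt_effect(cnt)
  e2 <- tdt_effect(dplyr::mutate(cnt, tmp = b, b = c_, c_ = tmp))
  expect_equal(e2$beta_hat, -e1$beta_hat)
  expect_equal(e2$var_hat, e1$var_hat)
  expect_equal(e2$statistic, e1$statistic)
  expect_equal(e2$p_value, e1$p_value)
})

test_that("quantitative regression recovers a simulated effect", {
  set.seed(31)
  n <- 10000
  g <- rbinom(n, 2, 0.3)
  y <- 0.5 * g + rnorm(n)
  gm <- fix_gm(matrix(as.integer(g), ncol = 1))
  phen <- tibble::tibble(sample_id = paste0("s", 1:n), y = y)
  eff <- regression_effect(gm, phen, trait = "quantitative", check_scale = FALSE)
  # closed-form OLS oracle
  bhat <- cov(g, y) / var(g)
  se <- sqrt(sum((y - mean(y) - bhat * (g - mean(g)))^2) / (n - 2) /
               sum((g - mean(g))^2))
  expect_equal(eff$beta_hat, bhat, tolerance = 1e-8)
  expect_lt(abs(eff$beta_hat - 0.5), 3 * se)
  expect_equal(eff$flag, "ok")
})

test_that("binary regression agrees with an independent IRLS fit", {
  set.seed(32)
  n <- 1200
  g <- rbinom(n, 2, 0.25)
  age <- rnorm(n, 50, 8)
  y <- rbinom(n, 1, plogis(-1 + 0.4 * g + 0.01 * age))
  gm <- fix_gm(matrix(as.integer(g), ncol = 1))
  phen <- tibble::tibble(sample_id = paste0("s", 1:n), y = y, age = age)
  eff <- regression_effect(gm, phen, trait = "binary", covariates = "age")

  # hand-rolled IRLS, independent of glm and of the package path
  X <- cbind(1, g, age)
  beta <- rep(0, 3)
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X * sqrt(w)), crossprod(X * w, z))
    if (max(abs(beta_new - beta)) < 1e-12) { beta <- beta_new; break }
    beta <- beta_new
  }
  vb <- solve(crossprod(X * sqrt(drop(plogis(X %*% beta)) *
                                   (1 - drop(plogis(X %*% beta))))))
  expect_equal(eff$beta_hat, unname(beta[2]), tolerance = 1e-6)
  expect_equal(eff$var_hat, unname(vb[2, 2]), tolerance = 1e-6)
})

test_that("degenerate regression inputs are caught", {
  set.seed(33)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  gm <- fix_gm(cbind(as.integer(g), 1L))
  phen <- tibble::tibble(sample_id = paste0("s", 1:n), y = rnorm(n),
                         dup = as.numeric(g))
  # genotype identical to a covariate: rank-deficient design
  expect_error(
    suppressWarnings(regression_effect(gm, phen, trait = "quantitative",
                                       covariates = "dup", variants = "v1",
                                       check_scale = FALSE)),
    "rank-deficient")
  # monomorphic variant is dropped, not fitted
  eff <- suppressWarnings(regression_effect(gm, phen, trait = "quantitative",
                                            variants = "v2", check_scale = FALSE))
  expect_equal(eff$flag, "dropped")
})

test_that("separated logistic fits fall back to a finite Firth estimate", {
  set.seed(34)
  n <- 300
  g <- c(rep(1L, 4), rep(0L, n - 4))
  y <- c(rep(1L, 4), rbinom(n - 4, 1, 0.3))  # all carriers are cases
  gm <- fix_gm(matrix(g, ncol = 1))
  phen <- tibble::tibble(sample_id = paste0("s", 1:n), y = y)
  eff <- regression_effect(gm, phen, trait = "binary")
  expect_equal(eff$flag, "corrected")
  expect_true(is.finite(eff$beta_hat) && is.finite(eff$var_hat))
  expect_true(eff$var_hat > 0)
})

test_that("batch no-covariate fits agree with glm and lm", {
  set.seed(35)
  n <- 800
  L <- 12
  G <- sapply(runif(L, 0.02, 0.45), function(f) rbinom(n, 2, f))
  yb <- rbinom(n, 1, 0.35)
  yq <- rnorm(n)
  bw <- adabf:::batch_wald(G, yb, "binary")
  qw <- adabf:::batch_wald(G, yq, "quantitative")
  for (l in seq_len(L)) {
    if (l %in% bw$corrected) next
    fb <- glm(yb ~ G[, l], family = binomial())
    expect_equal(bw$beta_hat[l], unname(coef(fb)[2]), tolerance = 1e-6)
    expect_equal(bw$var_hat[l], unname(vcov(fb)[2, 2]), tolerance = 1e-4)
    fq <- lm(yq ~ G[, l])
    expect_equal(qw$beta_hat[l], unname(coef(fq)[2]), tolerance = 1e-10)
    expect_equal(qw$var_hat[l], unname(vcov(fq)[2, 2]), tolerance = 1e-10)
  }
})
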