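#' Count allele transmissions from heterozygous parents
#'
#' For each variant, counts how often heterozygous parents transmitted the
#' minor allele (`b`) versus the major allele (`c_`) to the affected child of
#' each trio. Homozygous parents transmit a known allele and contribute
#' nothing. When both parents are heterozygous and the child is heterozygous,
#' one minor and one major transmission occurred, so both counts increase by
#' one. Trios with a missing genotype at a variant are skipped at that
#' variant, as are Mendelian-inconsistent trios; both are tallied.
#'
#' @param gm A [genotype_matrix()], oriented so scores count the minor allele
#'   (re-orientation is applied internally).
#' @param trios A [trio_set()] whose ids index rows of `gm`.
#' @return A tibble with one row per variant: `variant_id`, `maf`, `b`, `c_`
#'   (major-allele transmissions), `n_informative = b + c_`, `n_missing`
#'   (trios skipped for missingness) and `n_mendel` (trios skipped for
#'   Mendelian inconsistency).
#' @export
count_transmissions <- function(gm, trios) {
  gm <- orient_minor(gm)
  ids <- gm$samples$sample_id
  fi <- match(trios$father, ids)
  mi <- match(trios$mother, ids)
  ci <- match(trios$child, ids)
  assert_that(!anyNA(c(fi, mi, ci)), "trio ids not found in genotype matrix")

  gf <- gm$geno[fi, , drop = FALSE]
  gmo <- gm$geno[mi, , drop = FALSE]
  gc <- gm$geno[ci, , drop = FALSE]

  miss <- is.na(gf) | is.na(gmo) | is.na(gc)
  # minor copies the child received from heterozygous parents; homozygous-2
  # parents each transmit exactly one minor copy, homozygous-0 none.
  m_het <- gc - (gf == 2L) - (gmo == 2L)
  n_het <- (gf == 1L) + (gmo == 1L)
  valid <- !miss & m_het >= 0L & m_het <= n_het
  mendel <- !miss & !valid

  m_het[!valid] <- 0L
  n_het[!valid] <- 0L

  tibble(
    variant_id = gm$variants$variant_id,
    maf = gm$variants$maf,
    b = as.integer(colSums(m_het)),
    c_ = as.integer(colSums(n_het - m_het)),
    n_missing = as.integer(colSums(miss)),
    n_mendel = as.integer(colSums(mendel))
  ) %>%
    mutate(n_informative = b + c_)
}

#' Per-variant TDT effect summaries from transmission counts
#'
#' Converts transmission counts to the per-variant effect scale used by the
#' Bayes-factor machinery: `beta_hat = log(b/c)` (log odds ratio of the minor
#' allele), `var_hat = (b + c)/(b c)`, and the TDT chi-square
#' `(b - c)^2 / (b + c)` with its 1-df upper-tail p-value. A zero cell
#' (`b = 0` or `c = 0`) makes the log odds ratio infinite; the default rule
#' adds 0.5 to both cells (Haldane-Anscombe continuity correction) and flags
#' the variant `"corrected"`; `zero_cell = "drop"` drops it instead.
#' Uninformative variants (`b + c = 0`) are always flagged `"dropped"`.
#'
#' @param counts Output of [count_transmissions()] (columns `b`, `c_`).
#' @param zero_cell `"correct"` (default) or `"drop"`.
#' @return A tibble with `variant_id`, `maf`, `b`, `c_`, `beta_hat`,
#'   `var_hat`, `or` (`exp(beta_hat)`), `statistic`, `p_value`, `flag`
#'   (`"ok"`, `"corrected"` or `"dropped"`).
#' @export
tdt_effect <- function(counts, zero_cell = c("correct", "drop")) {
  zero_cell <- match.arg(zero_cell)
  counts <- as_tibble(counts)
  assert_that(all(c("b", "c_") %in% names(counts)),
              "`counts` needs columns b and c_")
  b0 <- as.numeric(counts$b)
  c0 <- as.numeric(counts$c_)
  uninf <- (b0 + c0) == 0
  zero <- !uninf & (b0 == 0 | c0 == 0)

  b <- b0
  cc <- c0
  flag <- rep("ok", length(b0))
  flag[uninf] <- "dropped"
  if (zero_cell == "correct") {
    b[zero] <- b0[zero] + 0.5
    cc[zero] <- c0[zero] + 0.5
    flag[zero] <- "corrected"
  } else {
    flag[zero] <- "dropped"
  }
  use <- flag != "dropped"

  beta_hat <- var_hat <- statistic <- p_value <- rep(NA_real_, length(b0))
  beta_hat[use] <- log(b[use] / cc[use])
  var_hat[use] <- (b[use] + cc[use]) / (b[use] * cc[use])
  statistic[use] <- (b[use] - cc[use])^2 / (b[use] + cc[use])
  p_value[use] <- chisq1_p(statistic[use])

  out <- counts %>%
    mutate(beta_hat = beta_hat, var_hat = var_hat, or = exp(beta_hat),
           statistic = statistic, p_value = p_value, flag = flag)
  if (!"maf" %in% names(out)) out$maf <- NA_real_
  out
}

#' Per-variant regression effect summaries for unrelated subjects
#'
#' Fits, for each requested variant, the single-locus model
#' `outcome ~ genotype + covariates` (logistic for binary traits, linear for
#' quantitative traits) on complete cases and returns the genotype
#' coefficient, its sampling variance, the Wald chi-square
#' `beta_hat^2 / var_hat` and its 1-df p-value. Logistic fits that fail to
#' converge or separate fall back to a Firth penalized fit and are flagged
#' `"corrected"`. Variants monomorphic among the analysed subjects are
#' flagged `"dropped"`.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotypes Data frame with `sample_id`, an outcome column, and any
#'   covariate columns.
#' @param trait `"binary"` (outcome in 0/1) or `"quantitative"`.
#' @param outcome Name of the outcome column (default `"y"`).
#' @param covariates Character vector of covariate column names (default
#'   none).
#' @param variants Optional character vector restricting the fit to a subset
#'   of variant ids.
#' @param check_scale For quantitative traits, warn when the outcome standard
#'   deviation deviates from 1 by more than 10% (the Bayes-factor prior
#'   shipped here is calibrated for standardized traits). Default `TRUE`.
#' @return A tibble with `variant_id`, `maf`, `beta_hat`, `var_hat`,
#'   `statistic`, `p_value`, `n_used`, `flag`.
#' @export
regression_effect <- function(gm, phenotypes, trait = c("binary", "quantitative"),
                              outcome = "y", covariates = character(),
                              variants = NULL, check_scale = TRUE) {
  trait <- match.arg(trait)
  gm <- orient_minor(gm)
  phenotypes <- as_tibble(phenotypes)
  assert_that(outcome %in% names(phenotypes), "outcome column not found")
  assert_that(all(covariates %in% names(phenotypes)), "covariate column not found")
  idx <- match(phenotypes$sample_id, gm$samples$sample_id)
  assert_that(!anyNA(idx), "phenotype sample ids not found in genotype matrix")

  y <- phenotypes[[outcome]]
  assert_that(!anyNA(y), "outcome must be non-missing for analysed subjects")
  if (trait == "binary") {
    assert_that(all(y %in% c(0, 1)), "binary outcome must be coded 0/1")
  } else if (check_scale && abs(stats::sd(y) - 1) > 0.1) {
    warning("quantitative outcome sd deviates from 1 by more than 10%; ",
            "the default Bayes-factor prior assumes a standardized trait",
            call. = FALSE)
  }

  vids <- variants %||% gm$variants$variant_id
  vpos <- match(vids, gm$variants$variant_id)
  assert_that(!anyNA(vpos), "unknown variant id requested")

  covmat <- if (length(covariates)) {
    as.matrix(phenotypes[, covariates, drop = FALSE])
  } else {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  }

  rows <- purrr::map(vpos, function(j) {
    g <- gm$geno[idx, j]
    keep <- !is.na(g) & stats::complete.cases(covmat)
    gk <- g[keep]
    yk <- y[keep]
    ck <- covmat[keep, , drop = FALSE]
    vid <- gm$variants$variant_id[j]
    maf_j <- gm$variants$maf[j]
    if (length(unique(gk)) < 2) {
      return(tibble(variant_id = vid, maf = maf_j, beta_hat = NA_real_,
                    var_hat = NA_real_, statistic = NA_real_,
                    p_value = NA_real_, n_used = sum(keep), flag = "dropped"))
    }
    X <- cbind(`(Intercept)` = 1, g = gk, ck)
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient design for variant ", vid,
           " (genotype collinear with covariates)", call. = FALSE)
    }
    fit_one_variant(X, yk, trait, vid, maf_j)
  })
  bind_rows(rows)
}

# Single-variant ML fit with Firth fallback for separated logistic models.
fit_one_variant <- function(X, y, trait, vid, maf_j) {
  flag <- "ok"
  if (trait == "quantitative") {
    fit <- stats::lm.fit(X, y)
    res <- fit$residuals
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    beta <- fit$coefficients["g"]
    v <- sigma2 * XtXinv[2, 2]
  } else {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = stats::binomial()),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    )
    beta <- fit$coefficients["g"]
    se_big <- FALSE
    if (!sep && fit$converged) {
      info <- crossprod(X * sqrt(fit$weights))
      vc <- chol2inv(chol(info))
      v <- vc[2, 2]
      se_big <- !is.finite(v) || v > 1e4
    }
    if (sep || !fit$converged || se_big) {
      ff <- firth_logistic(X, y)
      beta <- ff$beta[2]
      v <- ff$var[2]
      flag <- "corrected"
    }
  }
  beta <- unname(beta)
  stat <- beta^2 / v
  tibble(variant_id = vid, maf = maf_j, beta_hat = beta, var_hat = v,
         statistic = stat, p_value = chisq1_p(stat),
         n_used = length(y), flag = flag)
}

# Firth penalized logistic regression (Jeffreys-prior score correction):
# score_j* = sum_i (y_i - p_i + h_i (1/2 - p_i)) x_ij, with h the hat values.
# Deterministic Newton iteration; variance from the inverse Fisher information
# at the penalized estimate. Keeps Wald summaries finite under separation.
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  p_dim <- ncol(X)
  beta <- rep(0, p_dim)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    info_inv <- tryCatch(chol2inv(chol(info)), error = function(e) MASS_ginv(info))
    h <- rowSums((XW %*% info_inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(info_inv %*% score)
    # damp very large steps for stability on near-degenerate designs
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  w <- stats::plogis(eta) * (1 - stats::plogis(eta))
  info <- crossprod(X * sqrt(w))
  list(beta = beta, var = diag(tryCatch(chol2inv(chol(info)),
                                        error = function(e) MASS_ginv(info))))
}

# Firth penalized single-locus logistic fit expressed on genotype-class
# sufficient statistics (class sizes n_g and case counts s_g for g = 0,1,2),
# vectorized over variants. Within a genotype class every subject shares the
# same hat value h_g = w_g (I22 - 2 g I12 + g^2 I11)/det(I), so the
# penalized score and the Newton step are O(1) per variant per iteration.
# Numerically identical to firth_logistic() on the expanded design.
firth_batch_classes <- function(n0, n1, n2, s0, s1, s2, a_start = 0,
                                max_iter = 100, tol = 1e-8) {
  L <- length(n0)
  a <- rep(a_start, L)
  bb <- rep(0, L)
  for (it in seq_len(max_iter)) {
    p0 <- stats::plogis(a)
    p1 <- stats::plogis(a + bb)
    p2 <- stats::plogis(a + 2 * bb)
    w0 <- p0 * (1 - p0)
    w1 <- p1 * (1 - p1)
    w2 <- p2 * (1 - p2)
    i11 <- n0 * w0 + n1 * w1 + n2 * w2
    i12 <- n1 * w1 + 2 * n2 * w2
    i22 <- n1 * w1 + 4 * n2 * w2
    det <- i11 * i22 - i12^2
    h0 <- w0 * i22 / det
    h1 <- w1 * (i22 - 2 * i12 + i11) / det
    h2 <- w2 * (i22 - 4 * i12 + 4 * i11) / det
    t0 <- s0 - n0 * p0 + n0 * h0 * (0.5 - p0)
    t1 <- s1 - n1 * p1 + n1 * h1 * (0.5 - p1)
    t2 <- s2 - n2 * p2 + n2 * h2 * (0.5 - p2)
    u1 <- t0 + t1 + t2
    u2 <- t1 + 2 * t2
    da <- (i22 * u1 - i12 * u2) / det
    db <- (i11 * u2 - i12 * u1) / det
    bad <- !is.finite(da) | !is.finite(db)
    da[bad] <- 0
    db[bad] <- 0
    da <- pmax(pmin(da, 5), -5)
    db <- pmax(pmin(db, 5), -5)
    a <- a + da
    bb <- bb + db
    if (max(pmax(abs(da), abs(db))) < tol) break
  }
  p0 <- stats::plogis(a)
  p1 <- stats::plogis(a + bb)
  p2 <- stats::plogis(a + 2 * bb)
  w0 <- p0 * (1 - p0)
  w1 <- p1 * (1 - p1)
  w2 <- p2 * (1 - p2)
  i11 <- n0 * w0 + n1 * w1 + n2 * w2
  i12 <- n1 * w1 + 2 * n2 * w2
  i22 <- n1 * w1 + 4 * n2 * w2
  list(beta_hat = bb, var_hat = i11 / (i11 * i22 - i12^2))
}

# Minimal Moore-Penrose pseudoinverse (SVD); last-resort for singular
# information matrices inside the Firth fallback.
MASS_ginv <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Vectorized per-variant Wald summaries with no covariates, used by the
# simulation harnesses where thousands of regions are fitted. Binary traits:
# the single-locus logistic likelihood depends on the data only through the
# per-genotype-class counts and case counts (scores are 0/1/2), so after one
# pass over the genotype matrix the two-parameter Newton iteration is O(L)
# per step and exact; quantitative traits: closed-form simple OLS.
# Agreement with stats::glm / stats::lm is covered by tests.
batch_wald <- function(G, y, trait, max_iter = 50, tol = 1e-10) {
  n <- length(y)
  if (trait == "quantitative") {
    gbar <- colMeans(G)
    Gc <- sweep(G, 2, gbar)
    sxx <- colSums(Gc^2)
    yc <- y - mean(y)
    beta <- colSums(Gc * yc) / sxx
    rss <- sum(yc^2) - beta^2 * sxx
    sigma2 <- rss / (n - 2)
    v <- sigma2 / sxx
    return(list(beta_hat = beta, var_hat = v))
  }
  L <- ncol(G)
  het <- G == 1L
  hom <- G == 2L
  n1 <- colSums(het)
  n2 <- colSums(hom)
  n0 <- n - n1 - n2
  s1 <- drop(crossprod(y, het))    # cases among heterozygotes, per variant
  s2 <- drop(crossprod(y, hom))
  s0 <- sum(y) - s1 - s2

  a <- rep(stats::qlogis(mean(y)), L)
  bb <- rep(0, L)
  step <- rep(Inf, L)
  for (it in seq_len(max_iter)) {
    p0 <- stats::plogis(a)
    p1 <- stats::plogis(a + bb)
    p2 <- stats::plogis(a + 2 * bb)
    r0 <- s0 - n0 * p0
    r1 <- s1 - n1 * p1
    r2 <- s2 - n2 * p2
    u1 <- r0 + r1 + r2
    u2 <- r1 + 2 * r2
    w0 <- n0 * p0 * (1 - p0)
    w1 <- n1 * p1 * (1 - p1)
    w2 <- n2 * p2 * (1 - p2)
    i11 <- w0 + w1 + w2
    i12 <- w1 + 2 * w2
    i22 <- w1 + 4 * w2
    det <- i11 * i22 - i12^2
    da <- (i22 * u1 - i12 * u2) / det
    db <- (i11 * u2 - i12 * u1) / det
    # freeze columns whose information degenerated (separation drives the
    # fitted probabilities to 0/1); they get a Firth refit below
    bad <- !is.finite(da) | !is.finite(db)
    da[bad] <- 0
    db[bad] <- 0
    # damp the occasional wild step for near-separated rare variants
    da <- pmax(pmin(da, 5), -5)
    db <- pmax(pmin(db, 5), -5)
    a <- a + da
    bb <- bb + db
    step <- pmax(abs(da), abs(db))
    if (max(step) < tol) break
  }
  p0 <- stats::plogis(a)
  p1 <- stats::plogis(a + bb)
  p2 <- stats::plogis(a + 2 * bb)
  w0 <- n0 * p0 * (1 - p0)
  w1 <- n1 * p1 * (1 - p1)
  w2 <- n2 * p2 * (1 - p2)
  i11 <- w0 + w1 + w2
  i12 <- w1 + 2 * w2
  i22 <- w1 + 4 * w2
  v <- i11 / (i11 * i22 - i12^2)

  # separated or non-converged variants: Firth penalized refit keeps the
  # Wald summary finite (mirrors the regression_effect fallback)
  refit <- which(step > 1e-6 | !is.finite(bb) | !is.finite(v) | v <= 0)
  if (length(refit)) {
    ff <- firth_batch_classes(n0[refit], n1[refit], n2[refit],
                              s0[refit], s1[refit], s2[refit],
                              a_start = stats::qlogis(mean(y)))
    bb[refit] <- ff$beta_hat
    v[refit] <- ff$var_hat
  }
  list(beta_hat = bb, var_hat = v, corrected = refit)
}
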