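#' Genotype correlation matrix of a region
#'
#' Pairwise Pearson correlation of genotype scores, used to approximate the
#' correlation among the per-variant association statistics when drawing
#' correlated null effect estimates. For trio data only founder genotypes
#' contribute. Pairwise-complete correlations need not be positive
#' semidefinite, so negative eigenvalues are clipped to 1e-10 and the matrix
#' is rescaled back to unit diagonal.
#'
#' @param gm A [genotype_matrix()].
#' @param founders_only Use founders only (default `TRUE` when founders are
#'   present).
#' @param variants Optional character vector of variant ids.
#' @return A symmetric positive-semidefinite correlation matrix with unit
#'   diagonal, dimnames set to the variant ids.
#' @export
genotype_correlation <- function(gm, founders_only = TRUE, variants = NULL) {
  rows <- if (founders_only && any(gm$samples$role == "founder")) {
    which(gm$samples$role == "founder")
  } else {
    seq_len(nrow(gm$geno))
  }
  vids <- variants %||% gm$variants$variant_id
  j <- match(vids, gm$variants$variant_id)
  assert_that(!anyNA(j), "unknown variant id requested")
  g <- gm$geno[rows, j, drop = FALSE]
  assert_that(ncol(g) >= 2, "need at least two variants")
  assert_that(nrow(g) >= 3, "need at least three contributing individuals")
  sds <- apply(g, 2, stats::sd, na.rm = TRUE)
  if (any(is.na(sds) | sds == 0)) {
    stop("monomorphic variant(s) in correlation input: ",
         paste(vids[is.na(sds) | sds == 0], collapse = ", "),
         " (filter with drop_monomorphic() first)", call. = FALSE)
  }
  R <- if (anyNA(g)) {
    stats::cor(g, use = "pairwise.complete.obs")
  } else {
    # complete data: one BLAS crossprod instead of the pairwise path
    gs <- scale(g)
    crossprod(gs) / (nrow(g) - 1)
  }
  R[is.na(R)] <- 0
  diag(R) <- 1
  R <- make_psd(R)
  dimnames(R) <- list(vids, vids)
  R
}

# Eigenvalue clipping to positive semidefiniteness, then renormalization to a
# unit-diagonal correlation matrix.
make_psd <- function(R, floor = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= floor) return(R)
  vals <- pmax(e$values, floor)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

#' Adaptive top-k summary-score curve
#'
#' Orders per-variant scores (log Bayes factors for the BF-combination test,
#' `-log p` for the p-value-combination test) and forms, for every
#' `k = 1..L`, the summary score `S_k` = sum of the `k` largest scores. Ties
#' are broken by ascending variant index, so the selection order is
#' deterministic. `S_k` need not be monotone in `k`: variants with negative
#' log Bayes factors (evidence for the null) reduce the running sum.
#'
#' @param scores Finite numeric vector of per-variant scores.
#' @param variant_ids Optional ids (defaults to `names(scores)` or `v1..vL`).
#' @return A tibble with `k`, `variant_id` (the k-th selected variant) and
#'   `s_k`.
#' @export
summary_scores <- function(scores, variant_ids = NULL) {
  assert_that(length(scores) >= 1, "need at least one score")
  if (any(!is.finite(scores))) stop("scores must all be finite", call. = FALSE)
  ids <- variant_ids %||% names(scores) %||% paste0("v", seq_along(scores))
  ord <- order(-scores, seq_along(scores))
  tibble(k = seq_along(scores), variant_id = ids[ord], s_k = cumsum(scores[ord]))
}

#' Draw correlated null effect estimates
#'
#' Draws `B` independent vectors of per-variant effect estimates under the
#' global null from `N(0, V)` with `V[i, j] = R[i, j] sqrt(v_i v_j)`, where
#' `v` holds the observed per-variant sampling variances and `R` the genotype
#' correlation matrix. Uses a Cholesky factor of `R`, falling back to an
#' eigendecomposition square root after positive-semidefinite repair when `R`
#' is singular.
#'
#' @param var_hats Per-variant sampling variances, all `> 0`.
#' @param R Correlation matrix from [genotype_correlation()] (or the identity
#'   for independent variants).
#' @param B Number of null draws.
#' @param seed Integer seed; the draw is reproducible.
#' @return A `B x L` matrix of null effect estimates.
#' @export
resample_null <- function(var_hats, R, B, seed = 1L) {
  assert_that(all(var_hats > 0), "var_hats must all be > 0")
  L <- length(var_hats)
  assert_that(nrow(R) == L && ncol(R) == L, "R dimension mismatch")
  assert_that(B >= 1, "B must be >= 1")
  C <- chol_or_sqrt(R)
  set.seed(seed)
  Z <- matrix(stats::rnorm(B * L), nrow = B)
  sweep(Z %*% C, 2, sqrt(var_hats), `*`)
}

# Upper-triangular-ish square root of a correlation matrix: Cholesky when
# possible, else symmetric eigen square root after PSD repair.
chol_or_sqrt <- function(R) {
  out <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(out)) return(out)
  R <- make_psd(R)
  e <- eigen(R, symmetric = TRUE)
  t(e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors)))
}

# Score transform applied to effect estimates at fixed per-variant variances.
# adabf: log Wakefield BF; ada: -log of the 1-df Wald p-value.
score_transform <- function(beta, var_hat, transform, W) {
  if (transform == "adabf") {
    if (is.matrix(beta)) {
      0.5 * rep(log(var_hat / (var_hat + W)), each = nrow(beta)) +
        beta^2 * rep(W / (2 * var_hat * (var_hat + W)), each = nrow(beta))
    } else {
      wakefield_log_bf(beta, var_hat, W)
    }
  } else {
    stat <- if (is.matrix(beta)) {
      beta^2 / rep(var_hat, each = nrow(beta))
    } else {
      beta^2 / var_hat
    }
    -stats::pchisq(stat, df = 1, lower.tail = FALSE, log.p = TRUE)
  }
}

# Min-P counting given the observed summary-score curve and the ensemble's
# B x L summary-score matrix. Per-k p-values use >= comparisons divided by B;
# each resample is ranked against the full ensemble with itself included (so
# per-resample per-k p-values are bounded below by 1/B); the adjusted
# p-value uses <= on MinP. Zero exceedances are floored at 1/B.
artp_counting <- function(obs_S, S) {
  B <- nrow(S)
  L <- ncol(S)
  p_k <- numeric(L)
  minp_b <- rep(1, B)
  for (kk in seq_len(L)) {
    col <- S[, kk]
    p_k[kk] <- sum(col >= obs_S[kk]) / B
    # #(col >= col[b]) = B - #(col < col[b]) = B - (min-rank - 1)
    pb <- (B - rank(col, ties.method = "min") + 1) / B
    minp_b <- pmin(minp_b, pb)
  }
  minp <- min(p_k)
  exceed <- sum(minp_b <= minp)
  floor_flag <- exceed == 0
  list(p_k = p_k, minp = minp, minp_b = minp_b,
       adjusted_p = if (floor_flag) 1 / B else exceed / B,
       floor = floor_flag, selected_k = which.min(p_k))
}

# Row-wise descending sort followed by cumulative sums: S matrix of the
# ensemble. Single order() call instead of B per-row sorts.
rowwise_topk_cumsum <- function(X) {
  B <- nrow(X)
  L <- ncol(X)
  Xs <- matrix(X[order(row(X), -X)], nrow = B, byrow = TRUE)
  for (k in seq_len(L)[-1]) Xs[, k] <- Xs[, k] + Xs[, k - 1]
  Xs
}

#' Region p-value at a fixed resample count
#'
#' The core of the adaptive combination test. Per-variant scores are computed
#' from the observed effect estimates, and for each of `B` null resamples
#' from the resampled estimates with the same per-variant variances. For
#' every `k` the observed summary score `S_k` is compared with its null
#' distribution to give a per-k p-value; the region statistic is `MinP`, the
#' minimum over `k`. Each resample's own `MinP` is computed by ranking it
#' against the full ensemble (self included), and the adjusted p-value is the
#' fraction of resamples whose `MinP` is at most the observed `MinP`. Zero
#' exceedances are reported as `1/B` with `floor = TRUE`.
#'
#' @param effects Per-variant effect table with `beta_hat`, `var_hat` and
#'   (for the `"ada"` transform) `p_value`; typically filtered of dropped
#'   variants.
#' @param R Genotype correlation matrix matching `effects` (identity allowed).
#' @param B Number of null resamples.
#' @param transform `"adabf"` (combine log Bayes factors) or `"ada"` (combine
#'   `-log p`).
#' @param prior_sd Prior standard deviation for the Bayes-factor transform.
#' @param seed Integer seed for the ensemble.
#' @param chunk Resamples are generated in chunks of this many rows to bound
#'   memory (the `B x L` summary-score matrix is the only full-size object).
#' @return An object of class `adabf_test`; see [adabf_test_region()].
#' @export
artp_pvalue <- function(effects, R, B = 100, transform = c("adabf", "ada"),
                        prior_sd = 0.2, seed = 1L, chunk = 1e5L) {
  transform <- match.arg(transform)
  effects <- as_tibble(effects)
  assert_that(B >= 1, "B must be >= 1")
  keep <- is.finite(effects$beta_hat) & is.finite(effects$var_hat) &
    effects$var_hat > 0
  effects <- effects[keep, , drop = FALSE]
  L <- nrow(effects)
  assert_that(L >= 1, "no usable variants in region")
  if (L > 1) {
    assert_that(all(dim(R) == L), "R dimension must match usable variants")
  }
  W <- prior_sd^2
  v <- effects$var_hat
  ids <- effects$variant_id %||% paste0("v", seq_len(L))

  obs_scores <- score_transform(effects$beta_hat, v, transform, W)
  curve <- summary_scores(obs_scores, ids)
  obs_S <- curve$s_k

  Cfac <- if (L > 1) chol_or_sqrt(R) else matrix(1, 1, 1)
  S <- matrix(NA_real_, nrow = B, ncol = L)
  set.seed(seed)
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Z <- matrix(stats::rnorm(nb * L), nrow = nb)
    beta0 <- sweep(Z %*% Cfac, 2, sqrt(v), `*`)
    sc <- score_transform(beta0, v, transform, W)
    S[(done + 1L):(done + nb), ] <- if (L > 1) rowwise_topk_cumsum(sc) else sc
    done <- done + nb
  }

  cnt <- artp_counting(obs_S, S)
  p_k <- cnt$p_k
  minp <- cnt$minp
  floor_flag <- cnt$floor
  adj <- cnt$adjusted_p
  sel_k <- cnt$selected_k
  structure(list(
    method = if (transform == "ada") "ADA" else if (abs(W - 0.01) < 1e-12) "ADABF1" else "ADABF",
    transform = transform,
    prior_w = W,
    L = L,
    variant_ids = ids,
    score_curve = curve %>% mutate(p_k = p_k),
    minp = minp,
    adjusted_p = adj,
    B = B,
    selected_k = sel_k,
    selected_variants = curve$variant_id[seq_len(sel_k)],
    floor = floor_flag,
    seed = seed
  ), class = "adabf_test")
}

#' Region test with sequential resampling escalation
#'
#' Runs [artp_pvalue()] at `B_min` resamples and, while the adjusted p-value
#' is at most `10 / B`, draws a fresh independent ensemble ten times larger
#' and recomputes, up to `B_max`. Small p-values are thereby estimated with
#' relative precision while null regions stop after `B_min` draws. Stage
#' seeds are derived deterministically from `seed`, so identical calls give
#' identical results.
#'
#' @inheritParams artp_pvalue
#' @param method `"adabf"` (prior sd 0.2), `"adabf1"` (prior sd 0.1) or
#'   `"ada"`. `prior_sd` overrides the method preset when supplied.
#' @param B_min,B_max Minimum and maximum resample counts (defaults 100 and
#'   1e7). Memory for a stage is roughly `8 * B * L` bytes.
#' @param escalate Multiplier between stages (default 10).
#' @return An `adabf_test` object: a list with `method`, `L`, `minp`,
#'   `adjusted_p`, `B`, `selected_k`, `selected_variants`, `floor` and the
#'   per-k `score_curve`. Use [generics::tidy()] for the per-k curve and
#'   [generics::glance()] for a one-row summary.
#' @export
adabf_test_region <- function(effects, R, method = c("adabf", "adabf1", "ada"),
                              prior_sd = NULL, B_min = 100, B_max = 1e7,
                              escalate = 10, seed = 1L, chunk = 1e5L) {
  method <- match.arg(method)
  transform <- if (method == "ada") "ada" else "adabf"
  prior_sd <- prior_sd %||% switch(method, adabf = 0.2, adabf1 = 0.1, ada = 0.2)
  B <- B_min
  stage <- 1L
  repeat {
    res <- artp_pvalue(effects, R, B = B, transform = transform,
                       prior_sd = prior_sd, seed = derive_seed(seed, stage),
                       chunk = chunk)
    if (res$adjusted_p > 10 / B || B >= B_max) break
    B <- min(B * escalate, B_max)
    stage <- stage + 1L
  }
  if (method == "adabf1") res$method <- "ADABF1"
  if (method == "adabf") res$method <- "ADABF"
  res
}

#' @export
print.adabf_test <- function(x, ...) {
  cat(sprintf("<adabf_test> %s: L = %d, MinP = %.4g, adjusted p = %.4g (B = %g%s), k* = %d\n",
              x$method, x$L, x$minp, x$adjusted_p, x$B,
              if (x$floor) ", floored at 1/B" else "", x$selected_k))
  cat("  selected:", paste(utils::head(x$selected_variants, 8), collapse = ", "),
      if (length(x$selected_variants) > 8) "..." else "", "\n")
  invisible(x)
}
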