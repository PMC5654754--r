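# Shared fixture builders; everything is generated in code.

# Genotype matrix from a plain matrix, with auto-generated metadata.
fix_gm <- function(geno, roles = NULL, chrom = "1", pos = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno)
  L <- ncol(geno)
  roles <- roles %||% rep("unrelated", n)
  genotype_matrix(
    geno,
    variants = tibble::tibble(
      variant_id = paste0("v", seq_len(L)),
      chrom = chrom,
      pos = pos %||% seq_len(L) * 100L,
      allele_minor = "A", allele_major = "G"
    ),
    samples = tibble::tibble(sample_id = paste0("s", seq_len(n)), role = roles)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-trio genotype matrix: rows father, mother, child.
fix_trio_gm <- function(gf, gm_, gc) {
  g <- rbind(gf, gm_, gc)
  fix_gm(g, roles = c("founder", "founder", "offspring"))
}

fix_one_trio <- function() {
  trio_set(father = "s1", mother = "s2", child = "s3")
}

# Random trio dataset for brute-force comparisons: returns the genotype
# matrix, the trio set and the raw parent/child genotype arrays.
fix_random_trios <- function(n_trios, L, maf = NULL, miss_rate = 0, seed = 1) {
  set.seed(seed)
  maf <- maf %||% runif(L, 0.05, 0.5)
  draw <- function() {
    g <- sapply(maf, function(f) rbinom(n_trios, 2, f))
    matrix(as.integer(g), nrow = n_trios)
  }
  gf <- draw()
  gmo <- draw()
  # child genotypes built by actual transmission, so trios are
  # Mendelian-consistent before any missingness is injected
  transmit <- function(g) ifelse(g == 1L, rbinom(length(g), 1, 0.5), g / 2L)
  gc <- transmit(gf) + transmit(gmo)
  if (miss_rate > 0) {
    gf[runif(length(gf)) < miss_rate] <- NA_integer_
    gc[runif(length(gc)) < miss_rate] <- NA_integer_
  }
  geno <- rbind(gf, gmo, gc)
  n <- n_trios
  roles <- rep(c("founder", "founder", "offspring"), each = n)
  gm <- fix_gm(geno, roles = roles)
  trios <- trio_set(father = paste0("s", 1:n), mother = paste0("s", n + 1:n),
                    child = paste0("s", 2 * n + 1:n))
  list(gm = gm, trios = trios, gf = gf, gmo = gmo, gc = gc)
}

# Independent brute-force TDT transmission counter: per trio, per variant,
# enumerates the transmissions implied by the genotype triple.
oracle_count <- function(gf, gmo, gc) {
  L <- ncol(gf)
  b <- c_ <- mend <- miss <- integer(L)
  for (l in seq_len(L)) {
    for (i in seq_len(nrow(gf))) {
      f <- gf[i, l]; m <- gmo[i, l]; k <- gc[i, l]
      if (is.na(f) || is.na(m) || is.na(k)) { miss[l] <- miss[l] + 1L; next }
      minor_from_het <- k - (f == 2) - (m == 2)
      n_het <- (f == 1) + (m == 1)
      if (minor_from_het < 0 || minor_from_het > n_het) {
        mend[l] <- mend[l] + 1L
      } else {
        b[l] <- b[l] + minor_from_het
        c_[l] <- c_[l] + (n_het - minor_from_het)
      }
    }
  }
  list(b = b, c_ = c_, mendel = mend, missing = miss)
}

# Naive min-P counting oracle: double loops, no ranking tricks.
oracle_artp <- function(obs_S, S) {
  B <- nrow(S); L <- ncol(S)
  p_k <- sapply(seq_len(L), function(k) sum(S[, k] >= obs_S[k]) / B)
  minp <- min(p_k)
  minp_b <- sapply(seq_len(B), function(b) {
    min(sapply(seq_len(L), function(k) sum(S[, k] >= S[b, k]) / B))
  })
  cnt <- sum(minp_b <= minp)
  list(p_k = p_k, minp = minp, adjusted_p = if (cnt == 0) 1 / B else cnt / B)
}

# Observed top-k curve / ensemble top-k matrix, via the package's own
# primitives (used where only counting behaviour is under test).
sort_curve <- function(x) summary_scores(x)$s_k
topk_matrix <- function(S) adabf:::rowwise_topk_cumsum(S)

# Tiny effect table for region tests.
fix_effects <- function(beta, v, ids = NULL) {
  tibble::tibble(variant_id = ids %||% paste0("v", seq_along(beta)),
                 beta_hat = beta, var_hat = v,
                 statistic = beta^2 / v,
                 p_value = pchisq(beta^2 / v, 1, lower.tail = FALSE),
                 flag = "ok")
}
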