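#' Genotype matrix container
#'
#' A light container tying an individuals-by-variants matrix of minor-allele
#' counts (0, 1, 2 or `NA`) to a variant table and a sample table. All
#' region-level tests in the package consume this object; [read_genotypes()]
#' and the simulators in [simulate_trios()] / [simulate_case_control()]
#' produce it.
#'
#' @param geno Integer matrix, individuals in rows, variants in columns.
#'   Entries must be 0, 1, 2 or `NA`. Row names are sample ids, column names
#'   variant ids.
#' @param variants Data frame with one row per column of `geno`:
#'   `variant_id`, `chrom`, `pos`, `allele_minor`, `allele_major`. A `maf`
#'   column is (re)computed by [orient_minor()].
#' @param samples Data frame with one row per row of `geno`: `sample_id` and
#'   `role`, one of `"founder"`, `"offspring"`, `"unrelated"`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants, samples) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  assert_that(nrow(variants) == ncol(geno),
              "`variants` must have one row per genotype column")
  assert_that(nrow(samples) == nrow(geno),
              "`samples` must have one row per genotype row")
  assert_that(!anyDuplicated(variants$variant_id),
              "duplicate variant ids")
  assert_that(all(samples$role %in% c("founder", "offspring", "unrelated")),
              "sample roles must be founder, offspring or unrelated")
  bad <- geno[!is.na(geno)]
  assert_that(all(bad %in% 0:2), "genotype scores must be 0, 1, 2 or NA")
  rownames(geno) <- samples$sample_id
  colnames(geno) <- variants$variant_id
  structure(list(geno = geno, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants (%d founders, %d offspring, %d unrelated)\n",
              nrow(x$geno), ncol(x$geno),
              sum(x$samples$role == "founder"),
              sum(x$samples$role == "offspring"),
              sum(x$samples$role == "unrelated")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

# Rows over which allele frequencies are computed: founders when any pedigree
# structure is present, everyone otherwise.
freq_rows <- function(gm) {
  if (any(gm$samples$role == "founder")) {
    which(gm$samples$role == "founder")
  } else {
    seq_len(nrow(gm$geno))
  }
}

#' Orient genotype scores to the minor allele
#'
#' Ensures every variant counts copies of its minor allele: columns whose
#' scored-allele frequency exceeds 0.5 are flipped (`2 - g`) and the allele
#' labels swapped. Frequencies are computed on founders for trio data and on
#' all subjects otherwise. A tie at frequency 0.5 keeps the lexicographically
#' smaller allele label as the minor allele, so orientation is deterministic.
#'
#' @param gm A [genotype_matrix()].
#' @return The oriented `genotype_matrix`, with an up-to-date `maf` column in
#'   `$variants`.
#' @export
orient_minor <- function(gm) {
  rows <- freq_rows(gm)
  g <- gm$geno[rows, , drop = FALSE]
  freq <- colMeans(g, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0
  flip <- freq > 0.5
  tie <- abs(freq - 0.5) < 1e-12
  if (any(tie)) {
    # deterministic tie-break on allele names
    swap <- gm$variants$allele_minor > gm$variants$allele_major
    flip[tie] <- swap[tie]
  }
  if (any(flip)) {
    gm$geno[, flip] <- 2L - gm$geno[, flip, drop = FALSE]
    tmp <- gm$variants$allele_minor[flip]
    gm$variants$allele_minor[flip] <- gm$variants$allele_major[flip]
    gm$variants$allele_major[flip] <- tmp
    freq[flip] <- 1 - freq[flip]
  }
  gm$variants$maf <- freq
  gm
}

#' Minor allele frequencies of a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @return A tibble with `variant_id` and `maf` (computed on founders for trio
#'   data, on all subjects otherwise).
#' @export
variant_maf <- function(gm) {
  gm <- orient_minor(gm)
  gm$variants %>% select(variant_id, maf)
}

#' Drop variants that are monomorphic among the frequency-reference subjects
#'
#' @param gm A [genotype_matrix()].
#' @return A `genotype_matrix` restricted to polymorphic variants.
#' @export
drop_monomorphic <- function(gm) {
  gm <- orient_minor(gm)
  keep <- gm$variants$maf > 0
  subset_variants(gm, which(keep))
}

# Column subset that keeps the container consistent.
subset_variants <- function(gm, idx) {
  gm$geno <- gm$geno[, idx, drop = FALSE]
  gm$variants <- gm$variants[idx, , drop = FALSE]
  gm
}

#' Case-parent trio index set
#'
#' @param father,mother,child Character vectors of sample ids (parallel).
#' @param family_id Optional family labels.
#' @return A tibble with columns `family_id`, `father`, `mother`, `child`.
#' @export
trio_set <- function(father, mother, child, family_id = NULL) {
  assert_that(length(father) == length(mother) && length(mother) == length(child),
              "father, mother and child must have equal length")
  ok <- father != mother & father != child & mother != child
  assert_that(all(ok), "indices within a trio must be distinct")
  tibble(family_id = family_id %||% paste0("fam", seq_along(child)),
         father = father, mother = mother, child = child)
}
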