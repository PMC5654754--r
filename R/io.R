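#' Read genotypes from VCF or PLINK-style text
#'
#' Builds a [genotype_matrix()] (and, when pedigree information is present, a
#' [trio_set()]) from either a VCF with GT fields or a PLINK text `.ped`
#' file with its `.map` companion. Only biallelic records are used;
#' multi-allelic VCF records are skipped with a warning. Genotype scores are
#' oriented to the minor allele after reading.
#'
#' @param path Path to the `.vcf` (or `.vcf.gz`) or `.ped` file. For
#'   `format = "ped"` a `.map` file with the same stem must sit next to it.
#' @param format `"vcf"` or `"ped"`; guessed from the extension by default.
#' @param pedigree Optional path to a PLINK `.fam`-style file (`FID IID PAT
#'   MAT SEX PHENO`) supplying pedigree structure for a VCF. `.ped` input
#'   carries its own pedigree columns.
#' @return A list with `gm` (the oriented [genotype_matrix()]) and `trios`
#'   (a [trio_set()], or `NULL` when no complete trio is present).
#' @export
read_genotypes <- function(path, format = NULL, pedigree = NULL) {
  format <- format %||%
    if (grepl("\\.ped$", path, ignore.case = TRUE)) "ped" else "vcf"
  assert_that(format %in% c("vcf", "ped"), "format must be vcf or ped")
  if (format == "vcf") read_genotypes_vcf(path, pedigree)
  else read_genotypes_ped(path)
}

read_genotypes_vcf <- function(path, pedigree = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
  }
  keep <- !multi
  vids_all <- ifelse(is.na(fix$ID) | fix$ID == ".",
                     paste0(fix$CHROM, ":", fix$POS), fix$ID)
  if (anyDuplicated(vids_all)) {
    stop("duplicate variant ids in VCF: ",
         paste(unique(vids_all[duplicated(vids_all)]), collapse = ", "),
         call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  vids <- vids_all[keep]

  score <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    bad <- !is.na(x) & !(x %in% c("0/0", "0/1", "1/0", "1/1", "./."))
    if (any(bad)) stop("unparseable GT value(s): ",
                       paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    out
  }
  geno <- apply(gt, 2, score)             # variants x samples
  if (is.null(dim(geno))) geno <- matrix(geno, ncol = ncol(gt))
  geno <- t(geno)                          # samples x variants
  sample_ids <- colnames(gt)

  variants <- tibble(variant_id = vids,
                     chrom = normalize_chrom(fix$CHROM),
                     pos = as.integer(fix$POS),
                     allele_minor = fix$ALT, allele_major = fix$REF)

  ped <- if (!is.null(pedigree)) read_fam(pedigree) else NULL
  build_gm(geno, variants, sample_ids, ped)
}

read_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(fam) >= 4, "pedigree file needs at least FID IID PAT MAT")
  names(fam)[1:4] <- c("fid", "iid", "pat", "mat")
  fam
}

read_genotypes_ped <- function(path) {
  map_path <- sub("\\.ped$", ".map", path, ignore.case = TRUE)
  assert_that(file.exists(map_path), paste("missing .map companion:", map_path))
  mp <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE)
  names(mp)[1:4] <- c("chrom", "variant_id", "cm", "pos")
  if (anyDuplicated(mp$variant_id)) stop("duplicate variant ids in .map", call. = FALSE)
  L <- nrow(mp)

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nfield <- 6 + 2 * L
  badlen <- which(lengths(toks) != nfield)
  if (length(badlen)) {
    stop("malformed .ped record at line ", badlen[1], ": expected ",
         nfield, " fields, got ", lengths(toks)[badlen[1]], call. = FALSE)
  }
  tok <- do.call(rbind, toks)
  fam <- data.frame(fid = tok[, 1], iid = tok[, 2], pat = tok[, 3],
                    mat = tok[, 4], stringsAsFactors = FALSE)

  a1 <- tok[, 6 + 2 * seq_len(L) - 1, drop = FALSE]
  a2 <- tok[, 6 + 2 * seq_len(L), drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(tok), ncol = L)
  minor <- major <- character(L)
  for (l in seq_len(L)) {
    al <- c(a1[, l], a2[, l])
    obs <- sort(unique(al[al != "0"]))
    if (length(obs) > 2) {
      stop("variant ", mp$variant_id[l], " is not biallelic", call. = FALSE)
    }
    if (length(obs) == 0) obs <- c("A", "G")
    if (length(obs) == 1) obs <- c(obs, setdiff(c("A", "C", "G", "T"), obs)[1])
    minor[l] <- obs[1]
    major[l] <- obs[2]
    miss <- a1[, l] == "0" | a2[, l] == "0"
    g <- (a1[, l] == obs[1]) + (a2[, l] == obs[1])
    g[miss] <- NA_integer_
    geno[, l] <- g
  }
  variants <- tibble(variant_id = mp$variant_id,
                     chrom = normalize_chrom(mp$chrom),
                     pos = as.integer(mp$pos),
                     allele_minor = minor, allele_major = major)
  build_gm(geno, variants, fam$iid, fam)
}

# Assemble the container: flag founders/offspring from the pedigree and
# collect complete trios (child with both parents genotyped).
build_gm <- function(geno, variants, sample_ids, ped) {
  roles <- rep("unrelated", length(sample_ids))
  trios <- NULL
  if (!is.null(ped)) {
    ped <- ped[match(sample_ids, ped$iid), , drop = FALSE]
    has_parents <- !is.na(ped$iid) & ped$pat != "0" & ped$mat != "0" &
      ped$pat %in% sample_ids & ped$mat %in% sample_ids
    roles[has_parents] <- "offspring"
    parent_ids <- unique(c(ped$pat[has_parents], ped$mat[has_parents]))
    roles[sample_ids %in% parent_ids] <- "founder"
    if (any(has_parents)) {
      trios <- trio_set(father = ped$pat[has_parents],
                        mother = ped$mat[has_parents],
                        child = sample_ids[has_parents],
                        family_id = ped$fid[has_parents])
    }
  }
  samples <- tibble(sample_id = sample_ids, role = roles)
  gm <- orient_minor(genotype_matrix(geno, variants, samples))
  list(gm = gm, trios = trios)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotype fields (REF = major allele,
#' ALT = minor allele, so scores round-trip through [read_genotypes()]).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  v <- gm$variants
  gt <- c("0/0", "0/1", "1/1")[gm$geno + 1L]
  gt[is.na(gt)] <- "./."
  gt <- matrix(gt, nrow = nrow(gm$geno))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$samples$sample_id), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$allele_major, v$allele_minor,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a pedigree file (PLINK .fam layout)
#'
#' @param gm A [genotype_matrix()].
#' @param trios A [trio_set()] (parents of listed children are written with
#'   unknown parents themselves).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fam <- function(gm, trios, path) {
  ids <- gm$samples$sample_id
  fid <- rep("0", length(ids))
  pat <- mat <- rep("0", length(ids))
  for (i in seq_len(nrow(trios))) {
    members <- c(trios$father[i], trios$mother[i], trios$child[i])
    fid[ids %in% members] <- trios$family_id[i]
    j <- match(trios$child[i], ids)
    pat[j] <- trios$father[i]
    mat[j] <- trios$mother[i]
  }
  pheno <- ifelse(gm$samples$role == "offspring", 2L, 1L)
  writeLines(paste(fid, ids, pat, mat, 0L, pheno, sep = "\t"), path)
  invisible(path)
}

#' Read region definitions from BED
#'
#' BED intervals are 0-based half-open; internally regions are held 1-based
#' inclusive, so `start = bed_start + 1` and `end = bed_end`.
#'
#' @param path BED file with at least chrom/start/end, optionally a name
#'   column.
#' @return Tibble: `region`, `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_regions <- function(path) {
  bed <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           sep = "\t")
  assert_that(ncol(bed) >= 3, "BED needs at least 3 columns")
  nm <- if (ncol(bed) >= 4) as.character(bed[[4]]) else
    paste0("region", seq_len(nrow(bed)))
  out <- tibble(region = nm, chrom = normalize_chrom(bed[[1]]),
                start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]))
  assert_that(all(out$start <= out$end), "BED interval with start > end")
  out
}

#' Map variants to regions with flanking
#'
#' A variant belongs to a region when its position lies in the closed
#' interval `[start - flank, end + flank]` on the same chromosome (labels
#' normalized across the `chr` prefix, with a warning when conventions
#' differ). Variants may belong to several regions.
#'
#' @param variants Tibble with `variant_id`, `chrom`, `pos` (e.g.
#'   `gm$variants`).
#' @param regions Output of [read_regions()].
#' @param flank Flank size in base pairs added to both sides (default 30000,
#'   covering nearby regulatory sequence).
#' @return `regions` with list-column `variant_ids` and `n_variants` added.
#' @export
map_variants_to_regions <- function(variants, regions, flank = 30000) {
  variants <- as_tibble(variants)
  vchrom <- normalize_chrom(variants$chrom)
  rchrom <- normalize_chrom(regions$chrom)
  if (!identical(as.character(variants$chrom), vchrom) ||
      !identical(as.character(regions$chrom), rchrom)) {
    if (!identical(unique(grepl("^chr", variants$chrom)),
                   unique(grepl("^chr", regions$chrom)))) {
      warning("chromosome naming conventions differ; normalized 'chr' prefix",
              call. = FALSE)
    }
  }
  members <- purrr::map(seq_len(nrow(regions)), function(i) {
    hit <- vchrom == rchrom[i] &
      variants$pos >= regions$start[i] - flank &
      variants$pos <= regions$end[i] + flank
    variants$variant_id[hit]
  })
  regions %>%
    mutate(variant_ids = members, n_variants = lengths(members),
           flank = flank)
}

#' Read a phenotype/covariate table
#'
#' @param path TSV with a `sample_id` column, an outcome column and optional
#'   covariates.
#' @return A tibble.
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
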