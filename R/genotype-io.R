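#' Read genotypes from a VCF file
#'
#' Parses a VCF (v4.2, GT required) into a [genotype_matrix()]. Records
#' are restricted to the biallelic autosomal SNVs the downstream
#' analyses are defined on: multi-allelic records, non-SNV alleles and
#' sex-chromosome records are skipped, with counts reported via the
#' `"skipped"` attribute and a message. Missing genotypes are kept
#' missing. Per-site depth is taken from INFO/DP when present, else
#' the sum of FORMAT/DP, else 0.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param breed_map optional named vector sample -> breed; every name
#'   must be a sample in the file.
#' @param quiet suppress the skip-count message.
#' @return a [genotype_matrix()]; attribute `"skipped"` holds counts of
#'   multiallelic, non-SNV and sex-chromosome records.
#' @export
read_vcf_genotypes <- function(path, breed_map = NULL, quiet = FALSE) {
  if (!file.exists(path))
    stop("read_vcf_genotypes: no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    stop("read_vcf_genotypes: no records in ", path, call. = FALSE)

  sex <- fix$CHROM %in% c("X", "Y", "chrX", "chrY", "MT", "chrM")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  nonsnv <- !multi & (nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L |
                        is.na(fix$ALT))
  keep <- !(sex | multi | nonsnv)
  skipped <- c(sex_chrom = sum(sex), multiallelic = sum(multi & !sex),
               non_snv = sum(nonsnv & !sex))
  if (!quiet && sum(skipped) > 0)
    message("read_vcf_genotypes: skipped ", sum(skipped), " records (",
            paste(names(skipped), skipped, sep = "=", collapse = ", "), ")")
  if (!any(keep))
    stop("read_vcf_genotypes: no biallelic autosomal SNVs in ", path,
         call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  code <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  geno <- t(matrix(code(gt), nrow = nrow(gt), dimnames = dimnames(gt)))

  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))[keep]
  if (all(is.na(dp))) {
    fdp <- tryCatch(vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE),
                    error = function(e) NULL)
    dp <- if (!is.null(fdp)) as.integer(rowSums(fdp[keep, , drop = FALSE],
                                                na.rm = TRUE))
          else rep(0L, sum(keep))
  }
  dp[is.na(dp)] <- 0L

  breed <- NULL
  if (!is.null(breed_map)) {
    unknown <- setdiff(names(breed_map), colnames(gt))
    if (length(unknown))
      stop("read_vcf_genotypes: breed_map samples not in VCF: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    breed <- breed_map
  }
  loci <- data.frame(chrom = fix$CHROM[keep],
                     pos = as.integer(fix$POS[keep]),
                     ref = fix$REF[keep], alt = fix$ALT[keep],
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(loci, geno, dp, breed = breed)
  attr(out, "skipped") <- skipped
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Emits GT per sample and total site depth as INFO/DP; phased
#' genotypes can be written by [write_phased_vcf()].
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  body <- apply(x$geno, 1, function(g)
    ifelse(is.na(g), "./.", gt_str[g + 1L]))
  body <- matrix(body, ncol = length(x$samples))  # loci x samples
  header <- c("##fileformat=VCFv4.2",
              "##source=crossase",
              paste0("##contig=<ID=", unique(x$loci$chrom), ">"),
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples), collapse = "\t"))
  lines <- paste(x$loci$chrom, x$loci$pos, ".", x$loci$ref, x$loci$alt,
                 ".", "PASS", paste0("DP=", x$depth), "GT",
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Remove loci in the depth-distribution tails
#'
#' Extreme site depth flags collapsed repeats (high tail) and poorly
#' covered, unreliable calls (low tail); dropping about 2% of loci at
#' the depth extremes is the conventional cleanup after hard filtering.
#' Loci strictly below the `tail_fraction` empirical quantile or
#' strictly above the `1 - tail_fraction` quantile are removed.
#'
#' @param x a [genotype_matrix()].
#' @param tail_fraction fraction removed per tail (default 0.01, so
#'   roughly 2% total); must be < 0.5.
#' @return the filtered [genotype_matrix()]; attribute `"depth_filter"`
#'   records the bounds and the number of loci removed.
#' @export
depth_tail_filter <- function(x, tail_fraction = 0.01) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (tail_fraction >= 0.5)
    stop("depth_tail_filter: tail_fraction must be < 0.5", call. = FALSE)
  if (tail_fraction < 0)
    stop("depth_tail_filter: tail_fraction must be >= 0", call. = FALSE)
  q <- quantile(x$depth, c(tail_fraction, 1 - tail_fraction), names = FALSE)
  keep <- x$depth >= q[1] & x$depth <= q[2]
  out <- genotype_matrix(x$loci[keep, , drop = FALSE],
                         x$geno[, keep, drop = FALSE],
                         x$depth[keep], breed = x$breed)
  attr(out, "depth_filter") <- list(lower = q[1], upper = q[2],
                                    n_removed = sum(!keep),
                                    n_kept = sum(keep))
  out
}

#' Per-breed genotype frequencies
#'
#' For each locus and breed, the frequencies of the three genotype
#' classes (hom-ref, het, hom-alt) over non-missing calls, and the
#' transmitted (reference) allele frequency f = p_homref + p_het / 2 —
#' the probability that a random individual of the breed passes the
#' reference allele to an offspring. Loci with no called genotype in a
#' breed get NA frequencies and are flagged.
#'
#' @param x a [genotype_matrix()].
#' @param breeds named vector sample -> breed; defaults to the breed
#'   labels stored in `x`.
#' @return a `genotype_freqs` data frame (see
#'   [simulate_breed_frequencies()] for columns) with `n_called` filled.
#' @export
genotype_frequencies <- function(x, breeds = x$breed) {
  stopifnot(inherits(x, "genotype_matrix"))
  if (is.null(breeds))
    stop("genotype_frequencies: breed assignment required", call. = FALSE)
  miss <- setdiff(x$samples, names(breeds))
  if (length(miss))
    stop("genotype_frequencies: samples without breed: ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(unique(breeds[x$samples]), function(b) {
    g <- x$geno[x$samples[breeds[x$samples] == b], , drop = FALSE]
    n0 <- colSums(g == 0L, na.rm = TRUE)
    n1 <- colSums(g == 1L, na.rm = TRUE)
    n2 <- colSums(g == 2L, na.rm = TRUE)
    n <- n0 + n1 + n2
    data.frame(x$loci, breed = b,
               p_homref = n0 / n, p_het = n1 / n, p_homalt = n2 / n,
               n_called = as.integer(n), f = (2 * n0 + n1) / (2 * n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("genotype_freqs", "data.frame")
  out
}

#' Per-individual heterozygosity
#'
#' Count and fraction of heterozygous calls per sample (fraction over
#' that sample's non-missing loci). Crossbred offspring of divergent
#' parental lines carry more heterozygous SNPs than purebreds, so these
#' counts separate the generations of a cross.
#'
#' @param x a [genotype_matrix()].
#' @return data frame: sample, n_het, n_called, het_fraction.
#' @export
per_individual_heterozygosity <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  n_het <- rowSums(x$geno == 1L, na.rm = TRUE)
  n_called <- rowSums(!is.na(x$geno))
  data.frame(sample = x$samples, n_het = as.integer(n_het),
             n_called = as.integer(n_called),
             het_fraction = n_het / n_called,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trio Mendelian consistency
#'
#' A locus is inconsistent when the offspring genotype cannot be formed
#' by one allele from each parent: a het offspring of two identical
#' homozygotes, a hom-ref offspring of a hom-alt parent, or a hom-alt
#' offspring of a hom-ref parent. The error rate is computed over loci
#' where all three genotypes are called.
#'
#' @param sire,dam,offspring aligned genotype code vectors (0/1/2/NA).
#' @return list: `flag` (logical per locus, NA when incomplete),
#'   `n_complete`, `n_inconsistent`, `rate`.
#' @export
mendelian_consistency <- function(sire, dam, offspring) {
  n <- length(offspring)
  if (length(sire) != n || length(dam) != n)
    stop("mendelian_consistency: genotype vectors differ in length",
         call. = FALSE)
  complete <- !(is.na(sire) | is.na(dam) | is.na(offspring))
  bad <- (offspring == 1L & ((sire == 0L & dam == 0L) |
                               (sire == 2L & dam == 2L))) |
         (offspring == 0L & (sire == 2L | dam == 2L)) |
         (offspring == 2L & (sire == 0L | dam == 0L))
  bad[!complete] <- NA
  list(flag = bad,
       n_complete = sum(complete),
       n_inconsistent = sum(bad, na.rm = TRUE),
       rate = if (sum(complete)) sum(bad, na.rm = TRUE) / sum(complete)
              else NA_real_)
}
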