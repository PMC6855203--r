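#' Trio configuration classes
#'
#' The mutually exclusive labels a (sire, dam, offspring) genotype
#' triple can take. Of the nine ordered parental pairs compatible with
#' a heterozygous offspring, seven are Mendelian-consistent: two with
#' both parents homozygous for opposite alleles and four with exactly
#' one heterozygous parent can be phased; the het x het pair cannot.
#'
#' @format character vector of the six class labels.
#' @export
TRIO_CLASSES <- c("NOT_HET_OFFSPRING", "PHASABLE_BOTH_HOM",
                  "PHASABLE_ONE_HET", "UNPHASABLE_BOTH_HET",
                  "MENDELIAN_ERROR", "INCOMPLETE")

#' Classify trio genotype configurations for phasing
#'
#' Deterministically labels each locus of a sire/dam/offspring trio
#' (see [TRIO_CLASSES]) and, where the configuration is phasable,
#' resolves the parental origin of the heterozygous offspring's two
#' alleles: a homozygous parent can only have transmitted its own
#' allele, which pins the other allele on the other parent.
#'
#' @param g_sire,g_dam,g_offspring genotype code vectors (0 hom-ref,
#'   1 het, 2 hom-alt, NA missing), equal length.
#' @return data frame: `class` (factor over [TRIO_CLASSES]),
#'   `pat_allele`, `mat_allele` ("ref"/"alt", NA when not phased).
#' @export
classify_trio_configuration <- function(g_sire, g_dam, g_offspring) {
  n <- length(g_offspring)
  if (length(g_sire) != n || length(g_dam) != n)
    stop("classify_trio_configuration: vectors differ in length",
         call. = FALSE)
  cls <- rep("INCOMPLETE", n)
  pat <- mat <- rep(NA_character_, n)
  ok <- !(is.na(g_sire) | is.na(g_dam) | is.na(g_offspring))

  mend <- mendelian_consistency(g_sire, g_dam, g_offspring)$flag
  err <- ok & mend
  nothet <- ok & !mend & g_offspring != 1L
  het <- ok & !mend & g_offspring == 1L

  both_hom <- het & g_sire != 1L & g_dam != 1L  # consistency forces opposite
  one_het <- het & xor(g_sire == 1L, g_dam == 1L)
  both_het <- het & g_sire == 1L & g_dam == 1L

  cls[err] <- "MENDELIAN_ERROR"
  cls[nothet] <- "NOT_HET_OFFSPRING"
  cls[both_hom] <- "PHASABLE_BOTH_HOM"
  cls[one_het] <- "PHASABLE_ONE_HET"
  cls[both_het] <- "UNPHASABLE_BOTH_HET"

  phasable <- both_hom | one_het
  # the homozygous sire fixes the paternal allele; otherwise the
  # homozygous dam fixes the maternal allele and the sire gets the rest
  sire_hom <- phasable & g_sire != 1L
  pat[sire_hom] <- ifelse(g_sire[sire_hom] == 0L, "ref", "alt")
  mat[sire_hom] <- ifelse(g_sire[sire_hom] == 0L, "alt", "ref")
  dam_fix <- phasable & g_sire == 1L  # then the dam must be homozygous
  mat[dam_fix] <- ifelse(g_dam[dam_fix] == 0L, "ref", "alt")
  pat[dam_fix] <- ifelse(g_dam[dam_fix] == 0L, "alt", "ref")

  data.frame(class = factor(cls, levels = TRIO_CLASSES),
             pat_allele = pat, mat_allele = mat,
             stringsAsFactors = FALSE)
}

#' Phase a family's heterozygous SNPs by trio genotypes
#'
#' Applies [classify_trio_configuration()] to every individual whose
#' sire and dam are both genotyped, phasing each phasable heterozygous
#' locus to a paternal|maternal allele pair. Mendelian-error and
#' het x het loci are left unphased. Phased fractions are reported both
#' over all heterozygous loci and with Mendelian-error loci removed
#' from the denominator.
#'
#' @param genotypes a [genotype_matrix()] over the family.
#' @param pedigree data frame with columns id, sire, dam (NA for
#'   founders); every non-founder's parents must be genotyped.
#' @return an object of class `phased_family`: `$phase` — per offspring
#'   id, the per-locus classification/origin data frame; `$summary` —
#'   per offspring: n_het, n_phased, n_mendelian_error, phased_fraction,
#'   phased_fraction_excl_err; `$loci`.
#' @export
phase_family <- function(genotypes, pedigree) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            all(c("id", "sire", "dam") %in% names(pedigree)))
  kids <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), ]
  if (nrow(kids) == 0L)
    stop("phase_family: pedigree contains no individual with both parents",
         call. = FALSE)
  missing_members <- setdiff(unique(c(kids$id, kids$sire, kids$dam)),
                             genotypes$samples)
  if (length(missing_members))
    stop("phase_family: ungenotyped family members: ",
         paste(missing_members, collapse = ", "), call. = FALSE)

  phase <- lapply(seq_len(nrow(kids)), function(i) {
    classify_trio_configuration(genotypes$geno[kids$sire[i], ],
                                genotypes$geno[kids$dam[i], ],
                                genotypes$geno[kids$id[i], ])
  })
  names(phase) <- kids$id

  summary <- do.call(rbind, lapply(kids$id, function(id) {
    cl <- phase[[id]]$class
    n_het <- sum(cl %in% c("PHASABLE_BOTH_HOM", "PHASABLE_ONE_HET",
                           "UNPHASABLE_BOTH_HET", "MENDELIAN_ERROR"))
    n_phased <- sum(cl %in% c("PHASABLE_BOTH_HOM", "PHASABLE_ONE_HET"))
    n_err <- sum(cl == "MENDELIAN_ERROR")
    data.frame(id = id, n_het = n_het, n_phased = n_phased,
               n_mendelian_error = n_err,
               phased_fraction = if (n_het) n_phased / n_het else NA_real_,
               phased_fraction_excl_err =
                 if (n_het > n_err) n_phased / (n_het - n_err) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  structure(list(phase = phase, summary = summary, loci = genotypes$loci),
            class = "phased_family")
}

#' @export
print.phased_family <- function(x, ...) {
  cat("phased_family:", length(x$phase), "phased individuals,",
      nrow(x$loci), "loci\n")
  print(x$summary)
  invisible(x)
}

#' Write phased family genotypes as VCF
#'
#' Phased heterozygous loci are written with the phased separator in
#' paternal|maternal order; everything else keeps the unphased
#' separator. A per-sample FORMAT field `TC` carries the trio class.
#'
#' @param family a [genotype_matrix()] over the family.
#' @param phased a `phased_family` from [phase_family()].
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(family, phased, path) {
  stopifnot(inherits(family, "genotype_matrix"),
            inherits(phased, "phased_family"))
  gt_str <- c("0/0", "0/1", "1/1")
  cols <- lapply(family$samples, function(s) {
    g <- family$geno[s, ]
    gt <- ifelse(is.na(g), "./.", gt_str[g + 1L])
    tc <- rep(".", length(g))
    if (s %in% names(phased$phase)) {
      ph <- phased$phase[[s]]
      tc <- as.character(ph$class)
      done <- !is.na(ph$pat_allele)
      gt[done] <- paste0(ifelse(ph$pat_allele[done] == "ref", "0", "1"), "|",
                         ifelse(ph$mat_allele[done] == "ref", "0", "1"))
    }
    paste(gt, tc, sep = ":")
  })
  header <- c("##fileformat=VCFv4.2",
              "##source=crossase trio phasing (GT is paternal|maternal when phased)",
              paste0("##contig=<ID=", unique(family$loci$chrom), ">"),
              '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=TC,Number=1,Type=String,Description="Trio phasing class">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", family$samples), collapse = "\t"))
  lines <- paste(family$loci$chrom, family$loci$pos, ".", family$loci$ref,
                 family$loci$alt, ".", "PASS", paste0("DP=", family$depth),
                 "GT:TC", do.call(paste, c(cols, sep = "\t")), sep = "\t")
  writeLines(c(header, lines), path)
  invisible(path)
}
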