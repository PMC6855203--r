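#' Construct a genotype matrix
#'
#' Container for biallelic autosomal SNV genotypes: samples x loci codes
#' in \{0 hom-ref, 1 het, 2 hom-alt, NA missing\} plus per-site total
#' read depth. All genotype consumers in the package validate through
#' this constructor.
#'
#' @param loci data frame with columns chrom, pos (1-based), ref, alt;
#'   unique and sorted by (chrom, pos).
#' @param geno integer matrix, samples in rows, loci in columns.
#' @param depth per-locus total depth (non-negative integers).
#' @param breed optional named character vector, sample -> breed label.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(loci, geno, depth, breed = NULL) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(loci))
    stop("genotype_matrix: geno columns must match loci rows", call. = FALSE)
  if (length(depth) != nrow(loci))
    stop("genotype_matrix: depth length must match loci rows", call. = FALSE)
  if (anyDuplicated(paste(loci$chrom, loci$pos)))
    stop("genotype_matrix: duplicate locus keys", call. = FALSE)
  if (any(depth < 0, na.rm = TRUE))
    stop("genotype_matrix: negative depth", call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotype_matrix: genotype codes must be 0/1/2/NA",
                     call. = FALSE)
  ord <- order(suppressWarnings(as.numeric(loci$chrom)), loci$chrom, loci$pos,
               na.last = TRUE)
  samples <- rownames(geno) %||% paste0("S", seq_len(nrow(geno)))
  geno <- geno[, ord, drop = FALSE]
  rownames(geno) <- samples
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, geno = geno,
                 depth = as.integer(depth)[ord],
                 samples = samples, breed = breed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$loci), "loci\n")
  if (!is.null(x$breed))
    print(table(x$breed[x$samples]))
  invisible(x)
}

#' Simulate purebred genotype panels under Hardy–Weinberg equilibrium
#'
#' Draws genotypes for each breed from its per-locus transmitted-allele
#' frequency (alt-allele dosage ~ Binomial(2, 1 - f)) and a per-site
#' total depth from a negative binomial, emulating a resequenced
#' purebred reference panel.
#'
#' @param freqs a `genotype_freqs` table (see
#'   [simulate_breed_frequencies()]).
#' @param n_per_breed named integer vector of panel sizes, e.g.
#'   `c(D = 11, L = 9, Y = 10)`; breeds with 0 are simply absent.
#' @param seed integer seed.
#' @param depth_mean mean per-sample coverage; site depth is drawn
#'   NB(mu = depth_mean * n_samples, size = depth_size).
#' @param depth_size negative-binomial size (inverse dispersion).
#' @return a [genotype_matrix()] with breed labels.
#' @export
simulate_purebred_genotypes <- function(freqs,
                                        n_per_breed = c(D = 11L, L = 9L, Y = 10L),
                                        seed = 1L,
                                        depth_mean = 15, depth_size = 10) {
  set.seed(as.integer(seed))
  fm <- freq_matrix(freqs)
  loci <- attr(fm, "loci")
  n_loci <- nrow(loci)
  breeds <- names(n_per_breed)[n_per_breed > 0]
  geno <- NULL; lab <- character(0)
  for (b in breeds) {
    if (!b %in% colnames(fm))
      stop("simulate_purebred_genotypes: no frequencies for breed ", b,
           call. = FALSE)
    nb <- n_per_breed[[b]]
    g <- matrix(rbinom(nb * n_loci, 2L, rep(1 - fm[, b], each = nb)),
                nrow = nb)
    rownames(g) <- sprintf("%s%02d", b, seq_len(nb))
    geno <- rbind(geno, g)
    lab <- c(lab, rep(b, nb))
  }
  if (is.null(geno)) {
    geno <- matrix(integer(0), nrow = 0, ncol = n_loci)
    lab <- character(0)
  }
  n_samples <- max(nrow(geno), 1L)
  depth <- rnbinom(n_loci, mu = depth_mean * n_samples, size = depth_size)
  genotype_matrix(loci, geno, depth,
                  breed = setNames(lab, rownames(geno)))
}
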