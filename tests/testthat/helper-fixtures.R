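# shared in-code fixtures

# genotype_freqs table from theoretical per-breed reference-allele
# frequencies (HWE expansion); each argument is recycled to n loci
make_freqs <- function(f_D, f_L, f_Y, n = NULL) {
  n <- n %||% max(length(f_D), length(f_L), length(f_Y))
  fs <- list(D = rep_len(f_D, n), L = rep_len(f_L, n), Y = rep_len(f_Y, n))
  loci <- data.frame(chrom = "1", pos = 1000L * seq_len(n),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(names(fs), function(b) {
    f <- fs[[b]]
    data.frame(loci, breed = b, p_homref = f^2, p_het = 2 * f * (1 - f),
               p_homalt = (1 - f)^2, n_called = NA_integer_, f = f,
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("genotype_freqs", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small genotype matrix from a samples x loci code matrix
make_gm <- function(codes, depth = NULL, breed = NULL) {
  codes <- as.matrix(codes)
  loci <- data.frame(chrom = "1", pos = 1000L * seq_len(ncol(codes)),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(loci, codes, depth %||% rep(30L, ncol(codes)),
                  breed = breed)
}

# minimal phased_family carrying explicit paternal alleles per sample
make_phase <- function(loci, pat_alleles) {
  phase <- lapply(pat_alleles, function(p)
    data.frame(class = factor(ifelse(is.na(p), "UNPHASABLE_BOTH_HET",
                                     "PHASABLE_ONE_HET"),
                              levels = TRIO_CLASSES),
               pat_allele = p,
               mat_allele = ifelse(p == "ref", "alt", "ref"),
               stringsAsFactors = FALSE))
  structure(list(phase = phase, summary = NULL, loci = loci),
            class = "phased_family")
}

# all 27 complete trio genotype combinations
trio_cube <- expand.grid(sire = 0:2, dam = 0:2, offspring = 0:2)
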