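#' Simulate a three-way cross family with tracked allele origins
#'
#' Builds the fixed DLY design: a Landrace grandsire and Yorkshire
#' granddam produce an F1 (LY) dam; a Duroc sire mated to the LY dam
#' produces the offspring. Founders are drawn under Hardy–Weinberg
#' equilibrium from their breed's allele frequencies; every gamete is
#' sampled allele-by-allele and recorded, so each offspring carries a
#' ground-truth paternal/maternal allele origin at every locus. Loci are
#' unlinked (the PHS computation is per-locus, so no recombination map
#' is needed).
#'
#' @param freqs a `genotype_freqs` table covering breeds D, L, Y.
#' @param n_offspring number of crossbred offspring (the study design
#'   uses six).
#' @param seed integer seed.
#' @param depth_mean,depth_size per-site depth model as in
#'   [simulate_purebred_genotypes()].
#' @return an object of class `family_truth`: a [genotype_matrix()] over
#'   the family (`$genotypes`), a pedigree data frame (`$pedigree`: id,
#'   sire, dam, sex, generation), and `$origin` — per offspring, integer
#'   matrices `pat` and `mat` of transmitted alleles (0 = ref, 1 = alt)
#'   per locus.
#' @export
simulate_dly_family <- function(freqs, n_offspring = 6L, seed = 1L,
                                depth_mean = 38.5, depth_size = 10) {
  stopifnot(n_offspring >= 1L)
  set.seed(as.integer(seed))
  fm <- freq_matrix(freqs)
  for (b in c("D", "L", "Y"))
    if (!b %in% colnames(fm))
      stop("simulate_dly_family: breed ", b, " missing from frequencies",
           call. = FALSE)
  loci <- attr(fm, "loci")
  n <- nrow(loci)

  # founders as ordered allele pairs (0 = ref, 1 = alt), HWE per breed
  draw_pair <- function(f) cbind(a1 = rbinom(n, 1L, 1 - f),
                                 a2 = rbinom(n, 1L, 1 - f))
  gs <- draw_pair(fm[, "L"])   # L grandsire
  gd <- draw_pair(fm[, "Y"])   # Y granddam
  sire <- draw_pair(fm[, "D"]) # D terminal sire

  gamete <- function(pair) {
    pick <- rbinom(n, 1L, 0.5) + 1L
    pair[cbind(seq_len(n), pick)]
  }
  # F1 dam: one gamete from each grandparent (paternal = grandsire)
  dam <- cbind(a1 = gamete(gs), a2 = gamete(gd))

  ids_off <- sprintf("O%02d", seq_len(n_offspring))
  origin <- lapply(seq_len(n_offspring), function(i)
    list(pat = gamete(sire), mat = gamete(dam)))
  names(origin) <- ids_off

  geno <- rbind(
    L_grandsire = gs[, 1] + gs[, 2],
    Y_granddam  = gd[, 1] + gd[, 2],
    D_sire      = sire[, 1] + sire[, 2],
    LY_dam      = dam[, 1] + dam[, 2],
    do.call(rbind, lapply(origin, function(o) o$pat + o$mat)))
  rownames(geno) <- c("L_grandsire", "Y_granddam", "D_sire", "LY_dam", ids_off)

  pedigree <- data.frame(
    id = rownames(geno),
    sire = c(NA, NA, NA, "L_grandsire", rep("D_sire", n_offspring)),
    dam = c(NA, NA, NA, "Y_granddam", rep("LY_dam", n_offspring)),
    sex = c("M", "F", "M", "F",
            rep(c("M", "F"), length.out = n_offspring)),
    generation = c(0L, 0L, 1L, 1L, rep(2L, n_offspring)),
    stringsAsFactors = FALSE)

  depth <- rnbinom(n, mu = depth_mean * nrow(geno), size = depth_size)
  gm <- genotype_matrix(loci, geno, depth,
                        breed = setNames(c("L", "Y", "D", "LY",
                                           rep("DLY", n_offspring)),
                                         rownames(geno)))
  # genotype_matrix may reorder loci; keep origins aligned
  ord <- match(paste(gm$loci$chrom, gm$loci$pos), paste(loci$chrom, loci$pos))
  origin <- lapply(origin, function(o)
    list(pat = o$pat[ord], mat = o$mat[ord]))
  structure(list(genotypes = gm, pedigree = pedigree, origin = origin),
            class = "family_truth")
}

#' @export
print.family_truth <- function(x, ...) {
  cat("family_truth:", nrow(x$pedigree), "individuals,",
      nrow(x$genotypes$loci), "loci,",
      length(x$origin), "offspring with tracked origins\n")
  invisible(x)
}
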