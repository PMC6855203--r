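#' Hierarchical breed divergence model
#'
#' Parameters of a Balding–Nichols-style model for allele frequencies of
#' three pig breeds: Duroc (D) diverges directly from a global ancestor,
#' while Landrace (L) and Yorkshire (Y) diverge from a shared
#' intermediate ancestor, which makes L and Y mutually closer than
#' either is to D — the structure seen in principal-component analyses
#' of commercial pig breeds. Given an ancestral reference-allele
#' frequency p and a divergence parameter F, a descendant frequency is
#' drawn from Beta(p(1-F)/F, (1-p)(1-F)/F), whose mean is p and whose
#' variance is F p (1-p).
#'
#' @param n_loci number of biallelic SNP loci to simulate.
#' @param ancestral_freq_range range (min, max) of the Uniform draw of
#'   ancestral reference-allele frequencies; bounded away from 0 and 1
#'   so loci segregate somewhere.
#' @param fst_duroc divergence of Duroc from the global ancestor.
#' @param fst_ly_split divergence of Landrace and of Yorkshire from
#'   their shared ancestor.
#' @param fst_ly_ancestor divergence of the Landrace/Yorkshire shared
#'   ancestor from the global ancestor.
#' @param n_chrom number of autosomes loci are spread over.
#' @param seed integer seed making the frequency draw reproducible.
#' @return an object of class `breed_model` (a validated list).
#' @export
breed_model <- function(n_loci = 100000L,
                        ancestral_freq_range = c(0.05, 0.95),
                        fst_duroc = 0.30,
                        fst_ly_split = 0.05,
                        fst_ly_ancestor = 0.10,
                        n_chrom = 18L,
                        seed = 1L) {
  m <- list(n_loci = as.integer(n_loci),
            ancestral_freq_range = as.numeric(ancestral_freq_range),
            fst_duroc = fst_duroc, fst_ly_split = fst_ly_split,
            fst_ly_ancestor = fst_ly_ancestor,
            n_chrom = as.integer(n_chrom), seed = as.integer(seed))
  if (m$n_loci < 1L)
    stop("breed_model: n_loci must be >= 1", call. = FALSE)
  r <- m$ancestral_freq_range
  if (length(r) != 2L || r[1] >= r[2] || r[1] <= 0 || r[2] >= 1)
    stop("breed_model: ancestral_freq_range must be ordered within (0,1)",
         call. = FALSE)
  for (f in c(m$fst_duroc, m$fst_ly_split, m$fst_ly_ancestor))
    if (!is.finite(f) || f < 0 || f >= 1)
      stop("breed_model: F parameters must lie in [0,1)", call. = FALSE)
  class(m) <- "breed_model"
  m
}

# Balding-Nichols draw: descendant frequency around p at divergence fst.
# fst = 0 is the no-drift limit (frequency unchanged).
bn_draw <- function(p, fst) {
  if (fst == 0) return(p)
  f <- rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  # rbeta can round to exactly 0/1 at small shapes; fixed loci are legal
  pmin(pmax(f, 0), 1)
}

# deterministic locus map: loci spread evenly over autosomes, 1 kb apart
make_loci <- function(n_loci, n_chrom) {
  chrom <- rep(as.character(seq_len(n_chrom)), length.out = n_loci)
  chrom <- sort(factor(chrom, levels = as.character(seq_len(n_chrom))))
  pos <- unlist(lapply(table(chrom), function(k) 1000L * seq_len(k)),
                use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- bases[((seq_len(n_loci) - 1L) %% 4L) + 1L]
  alt <- bases[(seq_len(n_loci) %% 4L) + 1L]
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Simulate per-breed genotype frequencies
#'
#' Draws per-locus reference-allele frequencies for Duroc, Landrace and
#' Yorkshire under the hierarchical divergence model and expands each
#' into Hardy–Weinberg genotype frequencies. The output has the same
#' shape as [genotype_frequencies()] computed from an observed panel, so
#' either can feed the PHS machinery.
#'
#' @param model a [breed_model()].
#' @return a `genotype_freqs` data frame: one row per locus per breed
#'   with columns chrom, pos, ref, alt, breed, p_homref, p_het,
#'   p_homalt, n_called (NA for model-derived rows) and f, the
#'   transmitted (reference) allele frequency.
#' @export
simulate_breed_frequencies <- function(model) {
  stopifnot(inherits(model, "breed_model"))
  set.seed(model$seed)
  loci <- make_loci(model$n_loci, model$n_chrom)
  p_anc <- runif(model$n_loci, model$ancestral_freq_range[1],
                 model$ancestral_freq_range[2])
  p_lyanc <- bn_draw(p_anc, model$fst_ly_ancestor)
  f <- cbind(D = bn_draw(p_anc, model$fst_duroc),
             L = bn_draw(p_lyanc, model$fst_ly_split),
             Y = bn_draw(p_lyanc, model$fst_ly_split))
  out <- do.call(rbind, lapply(colnames(f), function(b) {
    fb <- f[, b]
    data.frame(loci, breed = b,
               p_homref = fb^2, p_het = 2 * fb * (1 - fb),
               p_homalt = (1 - fb)^2, n_called = NA_integer_, f = fb,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("genotype_freqs", "data.frame")
  out
}

# wide loci x breed matrix of transmitted-allele frequencies; rows follow
# the unique (chrom, pos) order of the table
freq_matrix <- function(freqs) {
  stopifnot(inherits(freqs, "genotype_freqs") || is.data.frame(freqs))
  key <- paste(freqs$chrom, freqs$pos)
  loci <- !duplicated(key)
  breeds <- unique(freqs$breed)
  m <- vapply(breeds, function(b) {
    fb <- freqs[freqs$breed == b, ]
    fb$f[match(key[loci], paste(fb$chrom, fb$pos))]
  }, numeric(sum(loci)))
  m <- matrix(m, ncol = length(breeds), dimnames = list(NULL, breeds))
  li <- freqs[loci, c("chrom", "pos", "ref", "alt")]
  class(li) <- "data.frame"
  rownames(li) <- NULL
  attr(m, "loci") <- li
  m
}
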