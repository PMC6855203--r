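#' Define a crossbreeding scheme
#'
#' A scheme is a binary tree whose leaves are breeds and whose internal
#' nodes are matings (sire side first). A compact string spells the
#' terminal cross: `"DLY"` means D x (L x Y) — a Duroc terminal sire on
#' a Landrace x Yorkshire F1 dam; `"LY"` means the two-way cross L x Y.
#' Nested lists allow arbitrary trees, e.g.
#' `cross_scheme(list("D", list("L", "Y")))`.
#'
#' @param x a scheme string (2 or 3 single-letter breed codes) or a
#'   nested two-element list of breed codes / sub-lists.
#' @param name optional scheme name; defaults to the concatenated
#'   leaves.
#' @return an object of class `cross_scheme`.
#' @export
cross_scheme <- function(x, name = NULL) {
  build <- function(node) {
    if (is.character(node) && length(node) == 1L)
      return(list(type = "leaf", breed = node))
    if (is.list(node) && length(node) == 2L)
      return(list(type = "cross", sire = build(node[[1]]),
                  dam = build(node[[2]])))
    stop("cross_scheme: nodes must be breed codes or two-element lists",
         call. = FALSE)
  }
  if (is.character(x) && length(x) == 1L && !grepl("[^A-Za-z]", x)) {
    b <- strsplit(x, "")[[1]]
    tree <- switch(as.character(length(b)),
                   "2" = list(b[1], b[2]),
                   "3" = list(b[1], list(b[2], b[3])),
                   stop("cross_scheme: scheme strings use 2 or 3 breed codes",
                        call. = FALSE))
    name <- name %||% x
  } else tree <- x
  root <- build(tree)
  leaves <- scheme_leaves(root)
  name <- name %||% paste(leaves, collapse = "")
  structure(list(root = root, name = name, leaves = leaves),
            class = "cross_scheme")
}

scheme_leaves <- function(node) {
  if (node$type == "leaf") return(node$breed)
  c(scheme_leaves(node$sire), scheme_leaves(node$dam))
}

#' @export
print.cross_scheme <- function(x, ...) {
  fmt <- function(n) if (n$type == "leaf") n$breed else
    paste0("(", fmt(n$sire), " x ", fmt(n$dam), ")")
  cat("cross_scheme ", x$name, ": ", fmt(x$root), "\n", sep = "")
  invisible(x)
}

#' Transmitted-allele frequency of a scheme node
#'
#' The probability that a random individual of the node's population
#' transmits the reference allele: for a breed leaf, f = p_homref +
#' p_het / 2 from the breed's genotype frequencies; for a cross, the
#' mean of the sire-side and dam-side frequencies, since each parent
#' contributes one gamete.
#'
#' @param node a `cross_scheme` or a node of one.
#' @param freqs a `genotype_freqs` table (or a precomputed frequency
#'   matrix from it).
#' @return numeric vector of per-locus transmitted reference-allele
#'   frequencies, in the locus order of `freqs`.
#' @export
transmitted_allele_frequency <- function(node, freqs) {
  fm <- if (is.matrix(freqs)) freqs else freq_matrix(freqs)
  if (inherits(node, "cross_scheme")) node <- node$root
  rec <- function(n) {
    if (n$type == "leaf") {
      if (!n$breed %in% colnames(fm))
        stop("transmitted_allele_frequency: unknown breed ", n$breed,
             call. = FALSE)
      return(fm[, n$breed])
    }
    (rec(n$sire) + rec(n$dam)) / 2
  }
  rec(node)
}

#' Per-locus PHS for a crossbreeding scheme
#'
#' The probability of a heterozygous SNP (PHS) in a simulated offspring
#' of the scheme's terminal cross. With sire-side and dam-side
#' transmitted reference-allele frequencies f_s and f_d, the offspring
#' genotype distribution is pRR = f_s f_d, pHet = f_s (1 - f_d) +
#' (1 - f_s) f_d, pAA = (1 - f_s)(1 - f_d), and PHS = pHet. The closed
#' form is exact because, under random mating, a side's gamete depends
#' on its genotype distribution only through the transmitted frequency;
#' [phs_enumerate()] provides the full genotype-frequency propagation
#' as an independent check.
#'
#' @param scheme a [cross_scheme()] whose root is a cross (a leaf-only
#'   scheme has no mating to simulate).
#' @param freqs a `genotype_freqs` table covering the scheme's breeds.
#' @return a `phs_table` data frame: chrom, pos, ref, alt, scheme, pRR,
#'   pHet, pAA, phs. Loci with no called frequency in any leaf breed
#'   are excluded; the count is in attribute `"n_excluded"`.
#' @export
phs_for_scheme <- function(scheme, freqs) {
  stopifnot(inherits(scheme, "cross_scheme"))
  if (scheme$root$type != "cross")
    stop("phs_for_scheme: scheme must contain a cross", call. = FALSE)
  fm <- freq_matrix(freqs)
  f_s <- transmitted_allele_frequency(scheme$root$sire, fm)
  f_d <- transmitted_allele_frequency(scheme$root$dam, fm)
  loci <- attr(fm, "loci")
  ok <- is.finite(f_s) & is.finite(f_d)
  out <- data.frame(loci[ok, , drop = FALSE], scheme = scheme$name,
                    pRR = (f_s * f_d)[ok],
                    pHet = (f_s * (1 - f_d) + (1 - f_s) * f_d)[ok],
                    pAA = ((1 - f_s) * (1 - f_d))[ok],
                    stringsAsFactors = FALSE)
  out$phs <- out$pHet
  rownames(out) <- NULL
  class(out) <- c("phs_table", "data.frame")
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Brute-force PHS by genotype-frequency propagation
#'
#' Independent enumeration oracle for [phs_for_scheme()]: the genotype
#' distribution of each node is computed recursively — a leaf takes its
#' breed's observed three-genotype frequencies; a cross enumerates all
#' 3 x 3 parental genotype pairs and, per pair, all gamete
#' transmissions (a homozygote transmits its allele, a heterozygote
#' transmits each with probability 1/2). PHS is the heterozygote mass
#' of the root distribution. O(9^depth) per locus; intended for tests
#' and spot checks, not production runs.
#'
#' @param scheme a [cross_scheme()].
#' @param freqs a `genotype_freqs` table.
#' @return data frame chrom, pos, pRR, pHet, pAA, phs over loci with
#'   complete leaf frequencies.
#' @export
phs_enumerate <- function(scheme, freqs) {
  stopifnot(inherits(scheme, "cross_scheme"))
  key <- paste(freqs$chrom, freqs$pos)
  loci <- freqs[!duplicated(key), c("chrom", "pos")]
  dist_of <- function(node) {
    if (node$type == "leaf") {
      fb <- freqs[freqs$breed == node$breed, ]
      if (nrow(fb) == 0L)
        stop("phs_enumerate: unknown breed ", node$breed, call. = FALSE)
      fb <- fb[match(key[!duplicated(key)], paste(fb$chrom, fb$pos)), ]
      return(cbind(p0 = fb$p_homref, p1 = fb$p_het, p2 = fb$p_homalt))
    }
    ds <- dist_of(node$sire); dd <- dist_of(node$dam)
    gref <- c(1, 0.5, 0)  # P(transmit ref | genotype 0/1/2)
    out <- matrix(0, nrow = nrow(ds), ncol = 3,
                  dimnames = list(NULL, c("p0", "p1", "p2")))
    for (gs in 0:2) for (gd in 0:2) {
      w <- ds[, gs + 1L] * dd[, gd + 1L]
      rs <- gref[gs + 1L]; rd <- gref[gd + 1L]
      out[, 1] <- out[, 1] + w * rs * rd
      out[, 2] <- out[, 2] + w * (rs * (1 - rd) + (1 - rs) * rd)
      out[, 3] <- out[, 3] + w * (1 - rs) * (1 - rd)
    }
    out
  }
  d <- dist_of(scheme$root)
  ok <- rowSums(is.finite(d)) == 3L
  data.frame(loci[ok, , drop = FALSE],
             pRR = d[ok, 1], pHet = d[ok, 2], pAA = d[ok, 3],
             phs = d[ok, 2], row.names = NULL, stringsAsFactors = FALSE)
}

#' Bin PHS values into 20 equal intervals
#'
#' Bins `[k * 0.05, (k + 1) * 0.05)` for k = 0..19, the last bin closed
#' at 1, i.e. bin index min(floor(phs / 0.05), 19).
#'
#' @param table a `phs_table` from [phs_for_scheme()].
#' @return a `phs_bins` data frame: bin (0-based), lower, upper, n,
#'   mean_phs (NA for empty bins); bin counts sum to the locus count.
#' @export
bin_phs_counts <- function(table) {
  stopifnot(is.data.frame(table), "phs" %in% names(table))
  if (nrow(table) == 0L)
    stop("bin_phs_counts: empty PHS table", call. = FALSE)
  idx <- pmin(floor(table$phs / 0.05), 19)
  n <- tabulate(idx + 1L, nbins = 20L)
  means <- rep(NA_real_, 20L)
  agg <- tapply(table$phs, idx, mean)
  means[as.integer(names(agg)) + 1L] <- agg
  structure(data.frame(bin = 0:19, lower = 0:19 * 0.05,
                       upper = 1:20 * 0.05, n = n, mean_phs = means),
            class = c("phs_bins", "data.frame"),
            scheme = if ("scheme" %in% names(table)) table$scheme[1] else NA)
}

#' Pairwise correlation of scheme PHS distributions
#'
#' Pearson correlation between each pair of schemes' 20-bin SNP counts.
#' Strongly negative correlations mean the schemes pile their SNPs at
#' opposite ends of the PHS range. The mean of the first scheme's
#' correlations against the others is reported, since the first scheme
#' is conventionally the one under evaluation.
#'
#' @param binnings named list of `phs_bins` (equal bin counts).
#' @param log_counts correlate log10(n + 1) instead of raw counts.
#' @return list: `r` and `p` matrices, and `mean_r_vs_first`.
#'   Zero-variance count vectors give NA with a warning.
#' @export
scheme_pairwise_correlation <- function(binnings, log_counts = FALSE) {
  stopifnot(is.list(binnings), length(binnings) >= 2L)
  counts <- vapply(binnings, function(b) as.numeric(b$n),
                   numeric(nrow(binnings[[1]])))
  if (log_counts) counts <- log10(counts + 1)
  k <- ncol(counts)
  nm <- names(binnings) %||% paste0("scheme", seq_len(k))
  r <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(counts[, i]) == 0 || stats::sd(counts[, j]) == 0) {
      warning("scheme_pairwise_correlation: zero-variance bin counts")
      next
    }
    ct <- cor.test(counts[, i], counts[, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, mean_r_vs_first = mean(r[1, -1]))
}

#' Expected heterozygosity by PHS bin
#'
#' Mean PHS within each bin of a scheme's table — the model's expected
#' heterozygous fraction for loci falling in that bin.
#'
#' @param table a `phs_table`.
#' @return data frame bin, n, expected_het (NA where the bin is empty).
#' @export
expected_het_by_bin <- function(table) {
  b <- bin_phs_counts(table)
  data.frame(bin = b$bin, n = b$n, expected_het = b$mean_phs)
}

#' Observed heterozygosity of an individual by PHS bin
#'
#' Fraction of heterozygous genotypes among an individual's non-missing
#' loci within each PHS bin, and its Pearson correlation with the
#' model's expected curve over bins where both are defined. Individuals
#' drawn from the scheme's terminal cross track the expected curve;
#' purebreds and other crosses do not.
#'
#' @param genotypes genotype codes for one individual, aligned to
#'   `table`'s loci (same length and order, or a named vector keyed
#'   "chrom:pos").
#' @param table a `phs_table`.
#' @return list: `bins` (bin, n_called, n_het, observed_het,
#'   expected_het), `r`, `p`.
#' @export
observed_het_by_bin <- function(genotypes, table) {
  stopifnot(is.data.frame(table), "phs" %in% names(table))
  if (!is.null(names(genotypes)))
    genotypes <- genotypes[paste(table$chrom, table$pos, sep = ":")]
  if (length(genotypes) != nrow(table))
    stop("observed_het_by_bin: genotypes not aligned to PHS table",
         call. = FALSE)
  idx <- pmin(floor(table$phs / 0.05), 19)
  called <- !is.na(genotypes)
  n_called <- tabulate(idx[called] + 1L, nbins = 20L)
  n_het <- tabulate(idx[called & genotypes == 1L] + 1L, nbins = 20L)
  obs <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  exp_curve <- expected_het_by_bin(table)$expected_het
  use <- is.finite(obs) & is.finite(exp_curve)
  ct <- if (sum(use) >= 3) cor.test(obs[use], exp_curve[use]) else NULL
  list(bins = data.frame(bin = 0:19, n_called = n_called, n_het = n_het,
                         observed_het = obs, expected_het = exp_curve),
       r = if (is.null(ct)) NA_real_ else unname(ct$estimate),
       p = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' High-PHS marker set
#'
#' Loci whose PHS strictly exceeds a threshold — the stably inherited
#' heterozygous markers a terminal cross is expected to carry.
#'
#' @param table a `phs_table`.
#' @param threshold PHS threshold (default 0.9).
#' @return the qualifying rows of `table`, sorted by (chrom, pos).
#' @export
high_phs_markers <- function(table, threshold = 0.9) {
  stopifnot(is.data.frame(table), "phs" %in% names(table))
  out <- table[table$phs > threshold, , drop = FALSE]
  out[order(suppressWarnings(as.numeric(out$chrom)), out$chrom, out$pos), ,
      drop = FALSE]
}
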