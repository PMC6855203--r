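#' Build a synthetic gene model over simulated loci
#'
#' Tiles genes along the simulated loci: each gene is one exon (BED
#' 0-based half-open) covering a contiguous run of `snps_per_gene`
#' loci, with untranscribed gaps between genes so some SNPs stay
#' intergenic.
#'
#' @param loci data frame with chrom, pos.
#' @param n_genes number of genes to place.
#' @param snps_per_gene loci covered per gene.
#' @param gap_snps loci skipped between consecutive genes.
#' @return data frame: gene_id, chrom, start (0-based), end.
#' @export
make_gene_model <- function(loci, n_genes = 200L, snps_per_gene = 3L,
                            gap_snps = 2L) {
  stopifnot(n_genes >= 1L, snps_per_gene >= 1L, gap_snps >= 0L)
  per <- snps_per_gene + gap_snps
  # tile genes within chromosomes so no gene spans a boundary
  idx <- unlist(lapply(split(seq_len(nrow(loci)), loci$chrom), function(i) {
    k <- length(i) %/% per
    if (k == 0L) return(integer(0))
    i[(rep((seq_len(k) - 1L) * per, each = snps_per_gene) +
         seq_len(snps_per_gene))]
  }), use.names = FALSE)
  capacity <- length(idx) %/% snps_per_gene
  if (n_genes > capacity)
    stop("make_gene_model: not enough loci for ", n_genes, " genes",
         call. = FALSE)
  idx <- idx[seq_len(n_genes * snps_per_gene)]
  first <- idx[(seq_len(n_genes) - 1L) * snps_per_gene + 1L]
  last <- idx[seq_len(n_genes) * snps_per_gene]
  data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
             chrom = loci$chrom[first],
             start = loci$pos[first] - 1L,   # include first SNP
             end = loci$pos[last],           # half-open: includes last SNP
             stringsAsFactors = FALSE)
}

#' Plant allele-specific expression effects
#'
#' Assigns each gene a true paternal-allele expression fraction per
#' tissue: null genes are exactly 0.5 everywhere; ASE genes carry
#' `ase_ratio` in one randomly assigned tissue (ASE in real tissues is
#' predominantly tissue-specific) and 0.5 elsewhere, unless
#' `shared_fraction` of them are made ASE in all tissues.
#'
#' @param gene_model data frame from [make_gene_model()].
#' @param tissues character vector of tissue names.
#' @param frac_ase fraction of genes with a planted effect.
#' @param ase_ratio true paternal fraction of effect genes (default
#'   0.8, in the range of reported allelic ratios).
#' @param shared_fraction fraction of effect genes expressed with the
#'   effect in every tissue.
#' @param seed integer seed.
#' @return data frame: gene_id, tissue, true_ratio (paternal
#'   fraction), is_ase.
#' @export
ase_truth_spec <- function(gene_model,
                           tissues = c("adipose", "heart", "liver", "muscle"),
                           frac_ase = 0.2, ase_ratio = 0.8,
                           shared_fraction = 0, seed = 1L) {
  stopifnot(frac_ase >= 0, frac_ase <= 1,
            ase_ratio >= 0, ase_ratio <= 1)
  set.seed(as.integer(seed))
  genes <- gene_model$gene_id
  n_ase <- round(frac_ase * length(genes))
  ase_genes <- if (n_ase) sample(genes, n_ase) else character(0)
  n_shared <- round(shared_fraction * n_ase)
  shared <- if (n_shared) ase_genes[seq_len(n_shared)] else character(0)
  home <- setNames(sample(tissues, n_ase, replace = TRUE), ase_genes)
  out <- expand.grid(gene_id = genes, tissue = tissues,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$true_ratio <- 0.5
  hit <- out$gene_id %in% shared |
    (out$gene_id %in% ase_genes & home[out$gene_id] == out$tissue)
  out$true_ratio[hit] <- ase_ratio
  out$is_ase <- out$true_ratio != 0.5
  out[order(out$tissue, out$gene_id), ]
}

#' Simulate allelic RNA read counts for a family's offspring
#'
#' For each offspring, tissue and gene: the gene's total read count is
#' drawn from a negative binomial NB(mu = depth_mean, size =
#' dispersion); the paternal share is Binomial(total, rho) with rho
#' the gene x tissue true paternal fraction; paternal and maternal
#' reads are then split multinomially (equal weights) across the
#' gene's exonic SNPs at which that offspring is heterozygous, and
#' reoriented to ref/alt counts with the ground-truth phase. Samples
#' with no heterozygous exonic SNP in a gene emit no counts there.
#'
#' @param family a `family_truth` from [simulate_dly_family()].
#' @param gene_model data frame from [make_gene_model()].
#' @param truth data frame from [ase_truth_spec()].
#' @param depth_mean mean reads per gene per sample (default 100).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param seed integer seed.
#' @return list: `counts` (sample, tissue, chrom, pos, ref, alt,
#'   gene_id, ref_count, alt_count), `truth`, `skipped_genes` (genes
#'   with no exonic SNP).
#' @export
simulate_allelic_counts <- function(family, gene_model, truth,
                                    depth_mean = 100, dispersion = 10,
                                    seed = 1L) {
  stopifnot(inherits(family, "family_truth"), depth_mean > 0,
            dispersion > 0)
  set.seed(as.integer(seed))
  loci <- family$genotypes$loci
  snp_map <- map_snps_to_gene_exons(loci, gene_model)
  skipped <- setdiff(gene_model$gene_id, snp_map$gene_id)
  lockey <- paste(loci$chrom, loci$pos)
  snp_idx <- split(match(paste(snp_map$chrom, snp_map$pos), lockey),
                   snp_map$gene_id)
  tissues <- unique(truth$tissue)
  rho <- setNames(truth$true_ratio, paste(truth$gene_id, truth$tissue))

  rows <- list(); k <- 0L
  for (off in names(family$origin)) {
    org <- family$origin[[off]]
    het <- org$pat != org$mat
    for (g in names(snp_idx)) {
      idx <- snp_idx[[g]][het[snp_idx[[g]]]]
      if (length(idx) == 0L) next
      for (ts in tissues) {
        total <- rnbinom(1L, mu = depth_mean, size = dispersion)
        r <- rho[[paste(g, ts)]]
        pat_total <- rbinom(1L, total, r)
        mat_total <- total - pat_total
        w <- rep(1 / length(idx), length(idx))
        pat_i <- as.integer(rmultinom(1L, pat_total, w))
        mat_i <- as.integer(rmultinom(1L, mat_total, w))
        pat_is_ref <- org$pat[idx] == 0L
        k <- k + 1L
        rows[[k]] <- data.frame(
          sample = off, tissue = ts,
          chrom = loci$chrom[idx], pos = loci$pos[idx],
          ref = loci$ref[idx], alt = loci$alt[idx], gene_id = g,
          ref_count = ifelse(pat_is_ref, pat_i, mat_i),
          alt_count = ifelse(pat_is_ref, mat_i, pat_i),
          stringsAsFactors = FALSE)
      }
    }
  }
  counts <- if (k) do.call(rbind, rows)
            else data.frame(sample = character(), tissue = character(),
                            chrom = character(), pos = integer(),
                            ref = character(), alt = character(),
                            gene_id = character(), ref_count = integer(),
                            alt_count = integer())
  rownames(counts) <- NULL
  if (length(skipped))
    message("simulate_allelic_counts: ", length(skipped),
            " genes with no exonic SNP skipped")
  list(counts = counts, truth = truth, skipped_genes = skipped)
}
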