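#' Map SNPs to gene exons
#'
#' Assigns each 1-based SNP position to every gene with an exon
#' covering it (BED-style exons are 0-based half-open, so a SNP at
#' 1-based position p falls in [start, end) iff start < p <= end).
#' SNPs outside all exons are dropped; SNPs inside exons of more than
#' one gene are kept for each gene and flagged ambiguous.
#'
#' @param loci data frame with chrom, pos (1-based).
#' @param exons data frame with chrom, start (0-based), end, gene_id.
#' @param drop_ambiguous drop SNPs hitting multiple genes instead of
#'   flagging them.
#' @return data frame: chrom, pos, gene_id, ambiguous; attribute
#'   `"n_non_exonic"` counts dropped SNPs.
#' @export
map_snps_to_gene_exons <- function(loci, exons, drop_ambiguous = FALSE) {
  stopifnot(all(c("chrom", "pos") %in% names(loci)),
            all(c("chrom", "start", "end", "gene_id") %in% names(exons)))
  if (any(exons$end <= exons$start) || any(exons$start < 0))
    stop("map_snps_to_gene_exons: malformed exon interval", call. = FALSE)
  snp_gr <- GenomicRanges::GRanges(loci$chrom,
                                   IRanges::IRanges(loci$pos, loci$pos))
  # BED half-open [start, end) covers 1-based positions start+1 .. end
  ex_gr <- GenomicRanges::GRanges(exons$chrom,
                                  IRanges::IRanges(exons$start + 1L,
                                                   exons$end))
  hits <- GenomicRanges::findOverlaps(snp_gr, ex_gr)
  qh <- S4Vectors::queryHits(hits)
  out <- data.frame(chrom = loci$chrom[qh], pos = loci$pos[qh],
                    gene_id = exons$gene_id[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  out <- unique(out)  # multiple exons of one gene count once
  n_genes <- stats::ave(seq_len(nrow(out)), paste(out$chrom, out$pos),
                        FUN = length)
  out$ambiguous <- n_genes > 1L
  if (drop_ambiguous) out <- out[!out$ambiguous, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_non_exonic") <- nrow(loci) - length(unique(qh))
  out
}

#' Collapse multi-SNP reads to one count each
#'
#' A read overlapping several heterozygous SNPs must contribute a
#' single count or the per-gene binomial test would treat one molecule
#' as several observations. Each read is kept at the lowest-coordinate
#' SNP it covers; reads whose base matches neither the reference nor
#' the alternate allele there are discarded and counted.
#'
#' @param read_level data frame: read_id, sample, tissue, chrom, pos,
#'   allele (the observed base).
#' @param loci data frame with chrom, pos, ref, alt.
#' @return aggregated data frame (sample, tissue, chrom, pos, ref, alt,
#'   ref_count, alt_count); attributes `"n_retained"` and
#'   `"n_discarded"`.
#' @export
resolve_multi_snp_reads <- function(read_level, loci) {
  stopifnot(all(c("read_id", "sample", "tissue", "chrom", "pos", "allele")
                %in% names(read_level)))
  x <- merge(read_level, loci[, c("chrom", "pos", "ref", "alt")],
             by = c("chrom", "pos"))
  x <- x[order(suppressWarnings(as.numeric(x$chrom)), x$chrom, x$pos), ]
  # one row per read: first SNP in coordinate order
  first <- !duplicated(x[, c("sample", "tissue", "read_id")])
  x <- x[first, , drop = FALSE]
  valid <- x$allele == x$ref | x$allele == x$alt
  n_discarded <- sum(!valid)
  x <- x[valid, , drop = FALSE]
  x$is_ref <- x$allele == x$ref
  agg <- stats::aggregate(cbind(ref_count = x$is_ref,
                                alt_count = !x$is_ref),
                          by = x[, c("sample", "tissue", "chrom", "pos",
                                     "ref", "alt")],
                          FUN = sum)
  agg$ref_count <- as.integer(agg$ref_count)
  agg$alt_count <- as.integer(agg$alt_count)
  attr(agg, "n_retained") <- sum(valid)
  attr(agg, "n_discarded") <- n_discarded
  agg
}

#' Haplotype-resolved gene counts
#'
#' Reorients per-SNP ref/alt read counts to paternal/maternal using the
#' trio phase, then sums over each gene's phased exonic heterozygous
#' SNPs per sample and tissue. Counts at SNPs that are not phased
#' heterozygous sites for that sample are dropped and counted.
#'
#' @param counts aggregated allelic counts (sample, tissue, chrom, pos,
#'   ref_count, alt_count).
#' @param phased a `phased_family` from [phase_family()].
#' @param snp_map SNP-to-gene map from [map_snps_to_gene_exons()].
#' @return data frame per gene x sample x tissue: gene_id, sample,
#'   tissue, pat_count, mat_count, n_snps; attribute `"n_dropped"`
#'   counts unphased rows. Gene/sample pairs with no phased exonic het
#'   SNP carry no row here; [classify_genes()] labels them NO_HET_SNP.
#' @export
gene_allelic_counts <- function(counts, phased, snp_map) {
  stopifnot(inherits(phased, "phased_family"))
  # the SNP->gene map is authoritative; drop any gene annotation the
  # count table already carries
  counts <- counts[, setdiff(names(counts), "gene_id"), drop = FALSE]
  x <- merge(counts, snp_map, by = c("chrom", "pos"))
  lockey <- paste(phased$loci$chrom, phased$loci$pos)
  idx <- match(paste(x$chrom, x$pos), lockey)
  pat_allele <- rep(NA_character_, nrow(x))
  for (s in unique(x$sample)) {
    if (!s %in% names(phased$phase)) next
    rows <- x$sample == s
    pat_allele[rows] <- phased$phase[[s]]$pat_allele[idx[rows]]
  }
  phased_ok <- !is.na(pat_allele)
  n_dropped <- sum(!phased_ok)
  x <- x[phased_ok, , drop = FALSE]
  pat_allele <- pat_allele[phased_ok]
  x$pat_count <- ifelse(pat_allele == "ref", x$ref_count, x$alt_count)
  x$mat_count <- ifelse(pat_allele == "ref", x$alt_count, x$ref_count)
  if (nrow(x) == 0L) {
    out <- data.frame(gene_id = character(), sample = character(),
                      tissue = character(), pat_count = integer(),
                      mat_count = integer(), n_snps = integer())
  } else {
    out <- stats::aggregate(cbind(pat_count = x$pat_count,
                                  mat_count = x$mat_count,
                                  n_snps = rep(1L, nrow(x))),
                            by = x[, c("gene_id", "sample", "tissue")],
                            FUN = sum)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Exact binomial test for allelic imbalance
#'
#' Two-sided exact binomial test of paternal vs maternal read counts
#' against the 1:1 expectation: with n = pat + mat and m = min(pat,
#' mat), p = P(X <= m) + P(X >= n - m) for X ~ Binomial(n, 1/2)
#' (capped at 1 when the counts are balanced). Genes with fewer than
#' `min_total` reads are not tested (NA), since the test has no power
#' there.
#'
#' @param pat,mat non-negative integer count vectors.
#' @param min_total minimum pat + mat required to test (default 10).
#' @return p-value vector; NA marks not-tested entries.
#' @export
binomial_ase_test <- function(pat, mat, min_total = 10L) {
  stopifnot(length(pat) == length(mat))
  if (any(pat < 0 | mat < 0, na.rm = TRUE))
    stop("binomial_ase_test: negative counts", call. = FALSE)
  n <- pat + mat
  m <- pmin(pat, mat)
  p <- pmin(1, pbinom(m, n, 0.5) + pbinom(n - m - 1, n, 0.5,
                                          lower.tail = FALSE))
  p[n < min_total] <- NA_real_
  p
}

#' Bonferroni adjustment
#'
#' Family-wise error control: adjusted p = min(1, m p) with m the
#' number of tested (non-NA) p-values in the family.
#'
#' @param p p-value vector; NA entries (not tested) are passed through.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("bonferroni_adjust: p-values outside [0,1]", call. = FALSE)
  m <- sum(!is.na(p))
  pmin(1, m * p)
}

#' Classify genes for allele-specific expression
#'
#' Per gene x sample x tissue: ASE when the Bonferroni-adjusted
#' binomial p falls strictly below `alpha`; NA when the gene has a
#' phased exonic het SNP but is not significant (including genes below
#' the count threshold, which are untestable rather than balanced);
#' NO_HET_SNP when the sample has no phased exonic het SNP in the
#' gene. The allelic ratio is the higher-expressed allele's fraction,
#' max(pat, mat) / (pat + mat).
#'
#' @param gene_counts output of [gene_allelic_counts()].
#' @param gene_universe optional data frame (gene_id, sample, tissue)
#'   of all gene/sample/tissue combinations that should receive a
#'   classification; combinations with no phased het SNP are
#'   NO_HET_SNP.
#' @param eligible optional data frame (gene_id, sample, tissue) of
#'   combinations that do have a phased exonic het SNP; such
#'   combinations missing from `gene_counts` (zero reads) are NA
#'   rather than NO_HET_SNP. Defaults to the combinations present in
#'   `gene_counts`.
#' @param alpha significance level on adjusted p (default 0.05).
#' @param min_total minimum read count to test (default 10).
#' @param family scope of the Bonferroni family: `"sample_tissue"`
#'   (default; all tested genes of one sample x tissue) or `"global"`.
#' @return a `gene_ase` data frame: gene_id, sample, tissue, pat_count,
#'   mat_count, n_snps, allelic_ratio, p_value, adjusted_p,
#'   classification.
#' @export
classify_genes <- function(gene_counts, gene_universe = NULL,
                           eligible = NULL,
                           alpha = 0.05, min_total = 10L,
                           family = c("sample_tissue", "global")) {
  family <- match.arg(family)
  if (alpha <= 0 || alpha >= 1)
    stop("classify_genes: alpha must be in (0,1)", call. = FALSE)
  x <- gene_counts
  x$allelic_ratio <- ifelse(x$pat_count + x$mat_count > 0,
                            pmax(x$pat_count, x$mat_count) /
                              (x$pat_count + x$mat_count), NA_real_)
  x$p_value <- binomial_ase_test(x$pat_count, x$mat_count, min_total)
  fam <- if (family == "global") rep("all", nrow(x))
         else paste(x$sample, x$tissue)
  x$adjusted_p <- NA_real_
  for (f in unique(fam))
    x$adjusted_p[fam == f] <- bonferroni_adjust(x$p_value[fam == f])
  x$classification <- ifelse(!is.na(x$adjusted_p) & x$adjusted_p < alpha,
                             "ASE", "NA")
  key <- paste(x$gene_id, x$sample, x$tissue)
  ekey <- if (is.null(eligible)) key
          else paste(eligible$gene_id, eligible$sample, eligible$tissue)
  pad <- function(df, cls) {
    if (nrow(df) == 0L) return(NULL)
    data.frame(df[, c("gene_id", "sample", "tissue")],
               pat_count = 0L, mat_count = 0L, n_snps = 0L,
               allelic_ratio = NA_real_, p_value = NA_real_,
               adjusted_p = NA_real_, classification = cls,
               stringsAsFactors = FALSE)
  }
  if (!is.null(eligible))
    x <- rbind(x, pad(eligible[!(ekey %in% key), , drop = FALSE], "NA"))
  if (!is.null(gene_universe)) {
    ukey <- paste(gene_universe$gene_id, gene_universe$sample,
                  gene_universe$tissue)
    x <- rbind(x, pad(gene_universe[!(ukey %in% c(key, ekey)), ,
                                    drop = FALSE], "NO_HET_SNP"))
  }
  x <- x[order(x$tissue, x$sample, x$gene_id), ]
  rownames(x) <- NULL
  class(x) <- c("gene_ase", "data.frame")
  x
}

#' High-confidence ASE genes per tissue
#'
#' A gene is called high-confidence in a tissue when it is classified
#' ASE in at least `min_ase_samples` of the tissue's samples; the
#' supporting-sample count and the median allelic ratio over the ASE
#' samples are reported.
#'
#' @param records a `gene_ase` table from [classify_genes()].
#' @param min_ase_samples minimum ASE-classified samples (default 2).
#' @return named list (one element per tissue) of data frames:
#'   gene_id, n_ase_samples, median_allelic_ratio; each carries the
#'   tissue-level median ratio as attribute `"median_ratio"`.
#' @export
call_high_confidence_ase <- function(records, min_ase_samples = 2L) {
  stopifnot(is.data.frame(records),
            all(c("gene_id", "sample", "tissue", "classification")
                %in% names(records)))
  out <- lapply(split(records, records$tissue), function(rt) {
    ase <- rt[rt$classification == "ASE", , drop = FALSE]
    if (nrow(ase) == 0L) {
      hc <- data.frame(gene_id = character(), n_ase_samples = integer(),
                       median_allelic_ratio = numeric())
    } else {
      n_ase <- tapply(ase$sample, ase$gene_id, function(s) length(unique(s)))
      med <- tapply(ase$allelic_ratio, ase$gene_id, median)
      hc <- data.frame(gene_id = names(n_ase),
                       n_ase_samples = as.integer(n_ase),
                       median_allelic_ratio = as.numeric(med),
                       row.names = NULL, stringsAsFactors = FALSE)
      hc <- hc[hc$n_ase_samples >= min_ase_samples, , drop = FALSE]
      hc <- hc[order(hc$gene_id), , drop = FALSE]
      rownames(hc) <- NULL
    }
    attr(hc, "median_ratio") <-
      if (nrow(hc)) median(hc$median_allelic_ratio) else NA_real_
    hc
  })
  out
}

#' Tissue specificity of ASE calls
#'
#' Overlap structure of per-tissue high-confidence gene sets: how many
#' genes are found in exactly one tissue, and the full
#' tissue-combination (Venn-style) breakdown.
#'
#' @param callsets named list of per-tissue data frames (or character
#'   vectors) of gene ids, e.g. from [call_high_confidence_ase()].
#' @return list: `n_union`, `n_specific`, `fraction_specific`,
#'   `by_gene` (gene_id, n_tissues, tissues), `combinations` (counts
#'   per tissue combination).
#' @export
tissue_specificity <- function(callsets) {
  stopifnot(is.list(callsets), length(callsets) >= 2L)
  sets <- lapply(callsets, function(x)
    if (is.data.frame(x)) x$gene_id else as.character(x))
  genes <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) genes %in% s, logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(genes, names(callsets)))
  n_tis <- rowSums(member)
  combo <- apply(member, 1, function(r)
    paste(colnames(member)[r], collapse = "+"))
  by_gene <- data.frame(gene_id = genes, n_tissues = as.integer(n_tis),
                        tissues = combo, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(n_union = length(genes),
       n_specific = sum(n_tis == 1L),
       fraction_specific = if (length(genes)) mean(n_tis == 1L) else NA_real_,
       by_gene = by_gene,
       combinations = if (length(genes)) table(combo) else table(character()))
}
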