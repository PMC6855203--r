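#' Pipeline configuration
#'
#' Validated bundle of every knob the end-to-end run uses. Defaults
#' reproduce the study design at desk scale: a 100k-locus map, panels
#' of 11 Duroc / 9 Landrace / 10 Yorkshire, a six-offspring three-way
#' family, four tissues, and the standard thresholds (1% depth tail
#' per side, PHS > 0.9 markers, minimum count 10, adjusted p < 0.05,
#' ASE support in at least 2 of 6 offspring).
#'
#' @param out_dir output directory.
#' @param seed master seed (mandatory; every stage stream derives from
#'   it).
#' @param n_loci simulated SNP loci.
#' @param schemes cross scheme strings; the first is the scheme under
#'   evaluation (default DLY, then its two rotations).
#' @param n_per_breed,n_offspring,tissues study design.
#' @param fst_duroc,fst_ly_split,fst_ly_ancestor breed divergence, see
#'   [breed_model()].
#' @param tail_fraction depth-tail filter per side.
#' @param phs_threshold high-PHS marker threshold.
#' @param min_count,alpha,min_ase_samples ASE calling thresholds.
#' @param n_genes,snps_per_gene,frac_ase,ase_ratio,rna_depth_mean,rna_dispersion
#'   synthetic gene/expression model.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("crossase_run_"),
                            seed = NULL,
                            n_loci = 100000L,
                            schemes = c("DLY", "LYD", "YDL"),
                            n_per_breed = c(D = 11L, L = 9L, Y = 10L),
                            n_offspring = 6L,
                            tissues = c("adipose", "heart", "liver",
                                        "muscle"),
                            fst_duroc = 0.30, fst_ly_split = 0.05,
                            fst_ly_ancestor = 0.10,
                            tail_fraction = 0.01,
                            phs_threshold = 0.9,
                            min_count = 10L, alpha = 0.05,
                            min_ase_samples = 2L,
                            n_genes = 200L, snps_per_gene = 3L,
                            frac_ase = 0.2, ase_ratio = 0.8,
                            rna_depth_mean = 100,
                            rna_dispersion = 10) {
  if (is.null(seed))
    stop("pipeline_config: a seed is mandatory in simulate mode",
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("pipeline_config: alpha must be in (0,1)", call. = FALSE)
  if (tail_fraction < 0 || tail_fraction >= 0.5)
    stop("pipeline_config: tail_fraction must be in [0, 0.5)",
         call. = FALSE)
  if (phs_threshold < 0 || phs_threshold > 1)
    stop("pipeline_config: phs_threshold must be in [0,1]", call. = FALSE)
  if (min_count < 0 || min_ase_samples < 1)
    stop("pipeline_config: invalid count thresholds", call. = FALSE)
  if (length(schemes) < 2L)
    stop("pipeline_config: need at least two schemes to compare",
         call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full breed-of-origin pipeline
#'
#' Chains simulate -> genotype frequencies -> PHS -> trio phasing ->
#' ASE calling. Inputs are written as their on-disk formats and read
#' back through the parsers, so a run also exercises the I/O layer.
#' All stage outputs are written under `config$out_dir` as TSV/VCF and
#' a structured report is returned. Identical config and seed give
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list of class `pipeline_report`; see the `summary` element
#'   for headline numbers.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[crossase] ", ...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  say("simulating study (", config$n_loci, " loci, seed ", config$seed, ")")
  study <- simulate_study(
    model = breed_model(n_loci = config$n_loci,
                        fst_duroc = config$fst_duroc,
                        fst_ly_split = config$fst_ly_split,
                        fst_ly_ancestor = config$fst_ly_ancestor),
    n_per_breed = config$n_per_breed, n_offspring = config$n_offspring,
    n_genes = config$n_genes, snps_per_gene = config$snps_per_gene,
    tissues = config$tissues, frac_ase = config$frac_ase,
    ase_ratio = config$ase_ratio,
    rna_depth_mean = config$rna_depth_mean,
    rna_dispersion = config$rna_dispersion, seed = config$seed)
  paths <- write_study(study, file.path(config$out_dir, "input"))

  say("reading genotypes back from VCF")
  breeds_tbl <- read.table(paths["breeds"], header = TRUE,
                           stringsAsFactors = FALSE)
  breed_map <- setNames(breeds_tbl$breed, breeds_tbl$sample)
  purebreds <- read_vcf_genotypes(paths["purebreds"], breed_map,
                                  quiet = quiet)
  family <- read_vcf_genotypes(paths["family"], quiet = quiet)
  pedigree <- read_pedigree(paths["pedigree"])

  say("depth-tail filter and per-breed genotype frequencies")
  purebreds <- depth_tail_filter(purebreds, config$tail_fraction)
  filt <- attr(purebreds, "depth_filter")
  freqs <- genotype_frequencies(purebreds)

  say("PHS for schemes ", paste(config$schemes, collapse = ", "))
  tables <- lapply(config$schemes, function(s)
    phs_for_scheme(cross_scheme(s), freqs))
  names(tables) <- config$schemes
  bins <- lapply(tables, bin_phs_counts)
  corr <- scheme_pairwise_correlation(bins)
  markers <- lapply(tables, high_phs_markers,
                    threshold = config$phs_threshold)
  n_high <- vapply(markers, nrow, integer(1))

  say("observed-vs-expected heterozygosity by PHS bin")
  ref_table <- tables[[1]]
  obs_r <- vapply(family$samples, function(s) {
    g <- setNames(family$geno[s, ],
                  paste(family$loci$chrom, family$loci$pos, sep = ":"))
    observed_het_by_bin(g, ref_table)$r
  }, numeric(1))

  say("trio phasing and Mendelian checks")
  phased <- phase_family(family, pedigree)
  het_tbl <- per_individual_heterozygosity(family)
  kids <- pedigree[!is.na(pedigree$sire) & !is.na(pedigree$dam), ]
  mend_rate <- vapply(seq_len(nrow(kids)), function(i)
    mendelian_consistency(family$geno[kids$sire[i], ],
                          family$geno[kids$dam[i], ],
                          family$geno[kids$id[i], ])$rate, numeric(1))
  names(mend_rate) <- kids$id
  write_phased_vcf(family, phased, file.path(config$out_dir, "phased.vcf"))

  say("ASE calling")
  exons <- read_exons_bed(paths["exons"])
  counts <- read_allelic_counts(paths["counts"])
  snp_map <- map_snps_to_gene_exons(family$loci, exons)
  gcounts <- gene_allelic_counts(counts, phased, snp_map)
  offspring <- intersect(names(phased$phase), unique(counts$sample))
  eligible <- ase_eligibility(phased, snp_map, offspring, config$tissues)
  universe <- expand.grid(gene_id = exons$gene_id, sample = offspring,
                          tissue = config$tissues,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  records <- classify_genes(gcounts, gene_universe = universe,
                            eligible = eligible, alpha = config$alpha,
                            min_total = config$min_count)
  hc <- call_high_confidence_ase(records, config$min_ase_samples)
  spec <- tissue_specificity(hc)
  truth <- study$ase$truth
  recov <- ase_recovery(hc, truth)

  say("writing outputs")
  w <- function(x, f) write.table(x, file.path(config$out_dir, f),
                                  sep = "\t", quote = FALSE,
                                  row.names = FALSE)
  w(do.call(rbind, lapply(names(bins), function(s)
    data.frame(scheme = s, bins[[s]]))), "phs_bins.tsv")
  w(do.call(rbind, tables), "phs.tsv")
  w(do.call(rbind, markers), "phs_markers.tsv")
  w(het_tbl, "het_by_individual.tsv")
  w(phased$summary, "phased_summary.tsv")
  w(records, "gene_ase.tsv")
  w(do.call(rbind, lapply(names(hc), function(t)
    if (nrow(hc[[t]])) data.frame(tissue = t, hc[[t]]) else NULL)),
    "high_confidence.tsv")
  w(spec$by_gene, "tissue_overlap.tsv")

  summary <- list(
    n_loci_simulated = config$n_loci,
    n_loci_after_depth_filter = filt$n_kept,
    depth_filter_removed_fraction = filt$n_removed /
      (filt$n_removed + filt$n_kept),
    n_high_phs = n_high,
    mean_r_vs_first = corr$mean_r_vs_first,
    mean_obs_r_offspring = mean(obs_r[kids$id[kids$sire == "D_sire"]]),
    mean_obs_r_nonoffspring =
      mean(obs_r[setdiff(family$samples, kids$id[kids$sire == "D_sire"])]),
    phased_fraction = setNames(phased$summary$phased_fraction,
                               phased$summary$id),
    mendelian_error_rate = mend_rate,
    n_high_confidence = vapply(hc, nrow, integer(1)),
    fraction_tissue_specific = spec$fraction_specific,
    ase_recall = recov$recall,
    ase_precision = recov$precision,
    median_allelic_ratio = recov$median_ratio)

  structure(list(config = config, paths = paths, study = study,
                 freqs = freqs, phs = tables, bins = bins,
                 correlations = corr, markers = markers, obs_r = obs_r,
                 phased = phased, het = het_tbl,
                 mendelian_error_rate = mend_rate, records = records,
                 high_confidence = hc, tissue_specificity = spec,
                 recovery = recov, summary = summary),
            class = "pipeline_report")
}

#' Gene/sample/tissue combinations with a phased exonic het SNP
#'
#' The ASE classifier distinguishes genes that could not be tested in
#' a sample because no read reached them (NA) from genes the sample
#' has no informative SNP in at all (NO_HET_SNP); this helper computes
#' the combinations with at least one phased exonic heterozygous SNP.
#'
#' @param phased a `phased_family` from [phase_family()].
#' @param snp_map SNP-to-gene map from [map_snps_to_gene_exons()].
#' @param samples samples to evaluate (must be phased offspring).
#' @param tissues tissue names to expand over.
#' @return data frame: gene_id, sample, tissue.
#' @export
ase_eligibility <- function(phased, snp_map, samples, tissues) {
  lockey <- paste(phased$loci$chrom, phased$loci$pos)
  idx <- match(paste(snp_map$chrom, snp_map$pos), lockey)
  combos <- do.call(rbind, lapply(samples, function(s) {
    ok <- !is.na(phased$phase[[s]]$pat_allele[idx])
    if (!any(ok)) return(NULL)
    data.frame(gene_id = unique(snp_map$gene_id[ok]), sample = s,
               stringsAsFactors = FALSE)
  }))
  if (is.null(combos)) return(NULL)
  merge(combos, data.frame(tissue = tissues), by = NULL)
}

# recall/precision of high-confidence calls against planted truth
ase_recovery <- function(hc, truth) {
  per_tissue <- lapply(names(hc), function(t) {
    true_genes <- truth$gene_id[truth$tissue == t & truth$is_ase]
    called <- hc[[t]]$gene_id
    list(recall = if (length(true_genes))
           mean(true_genes %in% called) else NA_real_,
         precision = if (length(called))
           mean(called %in% true_genes) else NA_real_)
  })
  names(per_tissue) <- names(hc)
  ratios <- unlist(lapply(hc, function(x) x$median_allelic_ratio))
  list(recall = vapply(per_tissue, `[[`, numeric(1), "recall"),
       precision = vapply(per_tissue, `[[`, numeric(1), "precision"),
       median_ratio = if (length(ratios)) median(ratios) else NA_real_)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("crossase pipeline report (seed ", x$config$seed, ")\n", sep = "")
  cat("  loci: ", s$n_loci_simulated, " simulated, ",
      s$n_loci_after_depth_filter, " after depth filter (",
      sprintf("%.2f%%", 100 * s$depth_filter_removed_fraction),
      " removed)\n", sep = "")
  cat("  high-PHS markers (>", x$config$phs_threshold, "): ",
      paste(names(s$n_high_phs), s$n_high_phs, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  mean Pearson r, ", names(x$phs)[1], " bins vs others: ",
      sprintf("%.3f", s$mean_r_vs_first), "\n", sep = "")
  cat("  observed-vs-expected het r: offspring ",
      sprintf("%.3f", s$mean_obs_r_offspring), ", non-offspring ",
      sprintf("%.3f", s$mean_obs_r_nonoffspring), "\n", sep = "")
  cat("  phased fraction: ",
      sprintf("%.2f%%-%.2f%%", 100 * min(s$phased_fraction),
              100 * max(s$phased_fraction)), "\n", sep = "")
  cat("  high-confidence ASE genes: ",
      paste(names(s$n_high_confidence), s$n_high_confidence, sep = "=",
            collapse = ", "), " (", sprintf("%.1f%%",
      100 * s$fraction_tissue_specific), " tissue-specific)\n", sep = "")
  cat("  planted-effect recovery: recall ",
      paste(sprintf("%.2f", s$ase_recall), collapse = "/"),
      ", median allelic ratio ",
      sprintf("%.3f", s$median_allelic_ratio), "\n", sep = "")
  invisible(x)
}
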