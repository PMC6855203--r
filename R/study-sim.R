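#' Simulate a complete breed-of-origin study
#'
#' One call producing every input the pipeline consumes, with ground
#' truth: purebred panels of three breeds, the three-way family with
#' tracked allele origins, a gene model, and allelic RNA counts with
#' planted ASE effects. Stage seeds are derived from the master seed
#' so stages have independent random streams.
#'
#' @param model a [breed_model()]; its `seed` is overridden by the
#'   derived stage seed when `seed` is given.
#' @param n_per_breed purebred panel sizes (default `c(D = 11, L = 9,
#'   Y = 10)`, a typical small resequencing panel).
#' @param n_offspring crossbred offspring in the family (default 6).
#' @param n_genes,snps_per_gene,gap_snps gene-model layout, see
#'   [make_gene_model()].
#' @param tissues tissue panel (default four: adipose, heart, liver,
#'   muscle).
#' @param frac_ase,ase_ratio,shared_fraction planted-effect structure,
#'   see [ase_truth_spec()].
#' @param rna_depth_mean,rna_dispersion gene-level RNA count model.
#' @param seed master seed.
#' @return list of class `study`: `freqs`, `purebreds`
#'   ([genotype_matrix()]), `family` (`family_truth`), `gene_model`,
#'   `ase` (counts + truth), `seed`.
#' @export
simulate_study <- function(model = breed_model(),
                           n_per_breed = c(D = 11L, L = 9L, Y = 10L),
                           n_offspring = 6L,
                           n_genes = 200L, snps_per_gene = 3L,
                           gap_snps = 2L,
                           tissues = c("adipose", "heart", "liver", "muscle"),
                           frac_ase = 0.2, ase_ratio = 0.8,
                           shared_fraction = 0,
                           rna_depth_mean = 100, rna_dispersion = 10,
                           seed = 1L) {
  seeds <- derive_seeds(seed, 5L)
  model$seed <- seeds[1]
  freqs <- simulate_breed_frequencies(model)
  purebreds <- simulate_purebred_genotypes(freqs, n_per_breed,
                                           seed = seeds[2])
  family <- simulate_dly_family(freqs, n_offspring, seed = seeds[3])
  gene_model <- make_gene_model(family$genotypes$loci, n_genes,
                                snps_per_gene, gap_snps)
  truth <- ase_truth_spec(gene_model, tissues, frac_ase, ase_ratio,
                          shared_fraction, seed = seeds[4])
  ase <- simulate_allelic_counts(family, gene_model, truth,
                                 depth_mean = rna_depth_mean,
                                 dispersion = rna_dispersion,
                                 seed = seeds[5])
  structure(list(freqs = freqs, purebreds = purebreds, family = family,
                 gene_model = gene_model, ase = ase, seed = seed),
            class = "study")
}

#' Write a simulated study to disk
#'
#' Emits the plain-text fixture bundle the pipeline reads back:
#' purebreds.vcf + breeds.tsv, family.vcf + pedigree.tsv, exons.bed
#' (0-based half-open, gene id in the name column), counts.tsv and
#' truth.tsv.
#'
#' @param study a `study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(purebreds = file.path(dir, "purebreds.vcf"),
             breeds = file.path(dir, "breeds.tsv"),
             family = file.path(dir, "family.vcf"),
             pedigree = file.path(dir, "pedigree.tsv"),
             exons = file.path(dir, "exons.bed"),
             counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_genotype_vcf(study$purebreds, paths["purebreds"])
  write.table(data.frame(sample = names(study$purebreds$breed),
                         breed = unname(study$purebreds$breed)),
              paths["breeds"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_genotype_vcf(study$family$genotypes, paths["family"])
  write.table(study$family$pedigree, paths["pedigree"], sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  bed <- study$gene_model
  write.table(data.frame(bed$chrom, bed$start, bed$end, bed$gene_id),
              paths["exons"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(study$ase$counts, paths["counts"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$ase$truth, paths["truth"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a BED exon file with gene ids
#'
#' @param path BED file: chrom, start (0-based), end, name = gene id.
#' @return data frame: gene_id, chrom, start, end.
#' @export
read_exons_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "gene_id"),
                  colClasses = c("character", "integer", "integer",
                                 "character"))
  if (any(x$end <= x$start))
    stop("read_exons_bed: malformed interval in ", path, call. = FALSE)
  x[, c("gene_id", "chrom", "start", "end")]
}

#' Read an allelic count table
#'
#' @param path TSV with columns sample, tissue, chrom, pos, ref, alt,
#'   gene_id, ref_count, alt_count.
#' @return validated data frame.
#' @export
read_allelic_counts <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE,
                  colClasses = c(chrom = "character"),
                  stringsAsFactors = FALSE)
  need <- c("sample", "tissue", "chrom", "pos", "ref", "alt", "gene_id",
            "ref_count", "alt_count")
  if (!all(need %in% names(x)))
    stop("read_allelic_counts: missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "), call. = FALSE)
  if (any(x$ref_count < 0 | x$alt_count < 0))
    stop("read_allelic_counts: negative counts", call. = FALSE)
  x
}

#' Read a pedigree table
#'
#' @param path TSV with columns id, sire, dam (empty for founders) and
#'   optionally sex, generation.
#' @return data frame with NA for unknown parents.
#' @export
read_pedigree <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, na.strings = c("", "NA"),
                  stringsAsFactors = FALSE)
  if (!all(c("id", "sire", "dam") %in% names(x)))
    stop("read_pedigree: need columns id, sire, dam", call. = FALSE)
  x
}
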