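#!/usr/bin/env Rscript
# Stage 4: gene-level allele-specific expression.
#
# Maps SNPs to exons, reorients allelic read counts to
# paternal/maternal with the trio phase, sums per gene, tests each
# gene x offspring x tissue against the 1:1 expectation with the exact
# binomial test (minimum 10 reads), Bonferroni-adjusts within each
# sample x tissue, classifies genes ASE / NA / NO_HET_SNP, calls
# high-confidence ASE genes (ASE in >= 2 of 6 offspring) per tissue,
# and checks the calls against the planted truth.

suppressPackageStartupMessages(library(crossase))
dir.create("results/ase", recursive = TRUE, showWarnings = FALSE)

fam <- read_vcf_genotypes("results/data/family.vcf")
ped <- read_pedigree("results/data/pedigree.tsv")
ph <- phase_family(fam, ped)
exons <- read_exons_bed("results/data/exons.bed")
counts <- read_allelic_counts("results/data/counts.tsv")
truth <- read.table("results/data/truth.tsv", header = TRUE)

snp_map <- map_snps_to_gene_exons(fam$loci, exons)
gc <- gene_allelic_counts(counts, ph, snp_map)
offspring <- sort(unique(counts$sample))
tissues <- sort(unique(counts$tissue))
rec <- classify_genes(
  gc, alpha = 0.05, min_total = 10L,
  eligible = ase_eligibility(ph, snp_map, offspring, tissues),
  gene_universe = expand.grid(gene_id = exons$gene_id, sample = offspring,
                              tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE))
cat("Gene x sample x tissue classifications:\n")
print(table(rec$classification))

hc <- call_high_confidence_ase(rec, min_ase_samples = 2L)
n_hc <- vapply(hc, nrow, integer(1))
cat("\nHigh-confidence ASE genes per tissue:\n")
print(n_hc)
spec <- tissue_specificity(hc)
cat(sprintf("%.1f%% of the %d high-confidence genes are single-tissue\n",
            100 * spec$fraction_specific, spec$n_union))

for (t in names(hc)) {
  true_t <- truth$gene_id[truth$tissue == t & truth$is_ase]
  called <- hc[[t]]$gene_id
  cat(sprintf("  %-8s recall %.2f, precision %.2f, median ratio %.3f\n",
              t, mean(true_t %in% called),
              if (length(called)) mean(called %in% true_t) else NA,
              if (length(called)) median(hc[[t]]$median_allelic_ratio)
              else NA))
}
cat("-> planted effects (paternal fraction 0.8) are recovered with the\n",
    "   planted ratio; misses are genes with shallow coverage or without\n",
    "   a phasable exonic het SNP in enough offspring.\n")

write.table(rec, "results/ase/gene_ase.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, lapply(names(hc), function(t)
  if (nrow(hc[[t]])) data.frame(tissue = t, hc[[t]]) else NULL)),
  "results/ase/high_confidence.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
write.table(spec$by_gene, "results/ase/tissue_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
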