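# direct pmf-summation oracle for the two-sided equal-probability
# binomial test
binom_oracle <- function(k1, k2) {
  n <- k1 + k2
  x <- 0:n
  d <- dbinom(x, n, 0.5)
  m <- min(k1, k2)
  min(1, sum(d[x <= m]) + sum(d[x >= n - m]))
}

test_that("SNP-to-exon mapping converts coordinates correctly", {
  loci <- data.frame(chrom = "1", pos = c(100L, 150L, 200L, 205L))
  exons <- data.frame(chrom = "1",
                      start = c(99L, 180L, 199L),
                      end = c(100L, 195L, 210L),
                      gene_id = c("A", "B", "B"))
  m <- map_snps_to_gene_exons(loci, exons)
  # BED [99,100) covers exactly 1-based position 100
  expect_equal(m$gene_id[m$pos == 100L], "A")
  # SNP at 150 sits between exons -> dropped
  expect_false(150L %in% m$pos)
  expect_equal(attr(m, "n_non_exonic"), 1L)
  expect_true(all(c(200L, 205L) %in% m$pos))
  expect_error(map_snps_to_gene_exons(loci,
               data.frame(chrom = "1", start = 10L, end = 10L,
                          gene_id = "Z")), "malformed")
})

test_that("SNPs in overlapping genes are flagged or dropped", {
  loci <- data.frame(chrom = "1", pos = 120L)
  exons <- data.frame(chrom = "1", start = c(100L, 110L),
                      end = c(130L, 140L), gene_id = c("A", "B"))
  m <- map_snps_to_gene_exons(loci, exons)
  expect_equal(sort(m$gene_id), c("A", "B"))
  expect_true(all(m$ambiguous))
  expect_equal(nrow(map_snps_to_gene_exons(loci, exons,
                                           drop_ambiguous = TRUE)), 0L)
})

test_that("multi-SNP reads contribute exactly one count", {
  loci <- data.frame(chrom = "1", pos = c(10L, 20L), ref = c("A", "C"),
                     alt = c("G", "T"))
  reads <- data.frame(
    read_id = c("r1", "r1", "r2", "r3", "r4"),
    sample = "S", tissue = "T",
    chrom = "1", pos = c(10L, 20L, 10L, 10L, 20L),
    allele = c("A", "T", "G", "C", "T"))
  agg <- resolve_multi_snp_reads(reads, loci)
  # r1 covers both SNPs -> counted only at pos 10; r3 matches neither
  # allele -> discarded
  expect_equal(agg$ref_count[agg$pos == 10L], 1L)
  expect_equal(agg$alt_count[agg$pos == 10L], 1L)
  expect_equal(agg$alt_count[agg$pos == 20L], 1L)
  expect_equal(attr(agg, "n_discarded"), 1L)
  expect_equal(attr(agg, "n_retained"), 3L)
  # conservation: every retained read appears exactly once
  expect_equal(sum(agg$ref_count + agg$alt_count) +
                 attr(agg, "n_discarded"),
               length(unique(reads$read_id)))
})

test_that("gene counts are reoriented by phase before summation", {
  loci <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "G")
  ph <- make_phase(loci, list(S = c("ref", "alt")))
  counts <- data.frame(sample = "S", tissue = "T", chrom = "1",
                       pos = c(10L, 20L), ref_count = c(3L, 4L),
                       alt_count = c(7L, 6L))
  snp_map <- data.frame(chrom = "1", pos = c(10L, 20L), gene_id = "G1",
                        ambiguous = FALSE)
  gc <- gene_allelic_counts(counts, ph, snp_map)
  expect_equal(gc$pat_count, 9L)   # 3 (ref-paternal) + 6 (alt-paternal)
  expect_equal(gc$mat_count, 11L)
  expect_equal(gc$n_snps, 2L)
  # unphased rows are dropped and counted
  ph2 <- make_phase(loci, list(S = c("ref", NA)))
  gc2 <- gene_allelic_counts(counts, ph2, snp_map)
  expect_equal(gc2$pat_count, 3L)
  expect_equal(attr(gc2, "n_dropped"), 1L)
})

test_that("the exact binomial test matches hand-derived tail sums", {
  expect_equal(binomial_ase_test(5L, 5L), 1)
  expect_equal(binomial_ase_test(10L, 0L), 2 / 1024)
  expect_equal(binomial_ase_test(9L, 1L), 22 / 1024)
  expect_true(is.na(binomial_ase_test(5L, 4L)))  # total 9 < 10
  expect_equal(binomial_ase_test(5L, 4L, min_total = 5L),
               binom_oracle(5, 4))
  expect_error(binomial_ase_test(-1L, 5L), "negative")
})

test_that("the test p equals pmf summation and binom.test on random counts", {
  set.seed(99)
  n <- sample(10:400, 150, replace = TRUE)
  k <- rbinom(150, n, runif(150, 0.3, 0.9))
  p <- binomial_ase_test(k, n - k)
  oracle <- mapply(binom_oracle, k, n - k)
  expect_lt(max(abs(p - oracle)), 1e-12)
  bt <- mapply(function(k, n) binom.test(k, n, 0.5)$p.value, k, n)
  expect_lt(max(abs(p - bt)), 1e-9)
})

test_that("Bonferroni adjustment is min(1, m p) over tested entries", {
  expect_equal(bonferroni_adjust(rep(0.001, 50)), rep(0.05, 50))
  expect_equal(bonferroni_adjust(c(0.5, 0.5, 0.5)), rep(1, 3))
  expect_equal(bonferroni_adjust(0.3), 0.3)  # m = 1 is the identity
  p <- c(0.01, NA, 0.2)   # NA (not tested) does not enter m
  expect_equal(bonferroni_adjust(p), c(0.02, NA, 0.4))
  expect_equal(bonferroni_adjust(p)[c(1, 3)],
               unname(p.adjust(p[c(1, 3)], "bonferroni")))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), "outside")
})

test_that("classification respects the strict alpha boundary and partitions", {
  gc <- data.frame(gene_id = c("A", "B", "C"), sample = "S", tissue = "T",
                   pat_count = c(98L, 62L, 4L),
                   mat_count = c(30L, 38L, 3L), n_snps = 1L)
  rec <- classify_genes(gc, alpha = 0.05, family = "global")
  expect_equal(rec$classification[rec$gene_id == "A"], "ASE")
  # gene below the count threshold is NA, not NO_HET_SNP
  expect_equal(rec$classification[rec$gene_id == "C"], "NA")
  # boundary: adjusted p exactly at alpha is NA (strict inequality)
  one <- data.frame(gene_id = "X", sample = "S", tissue = "T",
                    pat_count = 0L, mat_count = 10L, n_snps = 1L)
  r1 <- classify_genes(one, alpha = 2 / 1024)
  expect_equal(r1$classification, "NA")
  r2 <- classify_genes(one, alpha = 2 / 1024 + 1e-9)
  expect_equal(r2$classification, "ASE")
  expect_error(classify_genes(gc, alpha = 1.5), "alpha")
  # universe/eligibility: zero-read eligible gene is NA; never-het gene
  # is NO_HET_SNP; every combination gets exactly one class
  uni <- expand.grid(gene_id = c("A", "B", "C", "D", "E"), sample = "S",
                     tissue = "T", stringsAsFactors = FALSE)
  eli <- data.frame(gene_id = "D", sample = "S", tissue = "T")
  rec2 <- classify_genes(gc, gene_universe = uni, eligible = eli,
                         family = "global")
  expect_equal(rec2$classification[rec2$gene_id == "D"], "NA")
  expect_equal(rec2$classification[rec2$gene_id == "E"], "NO_HET_SNP")
  expect_equal(nrow(rec2), 5L)
  expect_true(all(rec2$classification %in% c("ASE", "NA", "NO_HET_SNP")))
})

test_that("high-confidence calls need support in at least two samples", {
  rec <- data.frame(
    gene_id = c("g1", "g1", "g2", "g1", "g2"),
    sample = c("s1", "s4", "s2", "s5", "s2"),
    tissue = c("A", "A", "A", "B", "B"),
    classification = c("ASE", "ASE", "ASE", "ASE", "ASE"),
    allelic_ratio = c(0.8, 0.7, 0.9, 0.8, 0.66))
  hc <- call_high_confidence_ase(rec, min_ase_samples = 2)
  expect_equal(hc$A$gene_id, "g1")          # g2 has one sample only
  expect_equal(hc$A$n_ase_samples, 2L)
  expect_equal(hc$A$median_allelic_ratio, 0.75)
  expect_equal(nrow(hc$B), 0L)
})

test_that("tissue specificity computes overlap fractions", {
  out <- tissue_specificity(list(A = c("g1", "g2"), B = "g2"))
  expect_equal(out$n_union, 2L)
  expect_equal(out$fraction_specific, 0.5)
  expect_equal(tissue_specificity(list(A = "g1", B = "g2"))
               $fraction_specific, 1)
  expect_equal(tissue_specificity(list(A = c("g1", "g2"),
                                       B = c("g1", "g2")))
               $fraction_specific, 0)
})

test_that("planted effects are recovered through the full calling path", {
  fr <- simulate_breed_frequencies(breed_model(n_loci = 4000, seed = 50))
  fam <- simulate_dly_family(fr, n_offspring = 6, seed = 51)
  gmod <- make_gene_model(fam$genotypes$loci, n_genes = 150,
                          snps_per_gene = 4, gap_snps = 1)
  truth <- ase_truth_spec(gmod, tissues = "T1", frac_ase = 0.3,
                          ase_ratio = 0.8, seed = 52)
  sim <- simulate_allelic_counts(fam, gmod, truth, depth_mean = 150,
                                 dispersion = 10, seed = 53)
  ph <- phase_family(fam$genotypes, fam$pedigree)
  snp_map <- map_snps_to_gene_exons(fam$genotypes$loci, gmod)
  gc <- gene_allelic_counts(sim$counts, ph, snp_map)
  rec <- classify_genes(gc)
  hc <- call_high_confidence_ase(rec)
  called <- hc$T1$gene_id
  true_genes <- truth$gene_id[truth$is_ase]
  expect_gte(mean(true_genes %in% called), 0.9)
  expect_lt(abs(median(hc$T1$median_allelic_ratio) - 0.8), 0.03)
  # no null gene sneaks in (Bonferroni is conservative here)
  expect_lte(mean(!(called %in% true_genes)), 0.05)
})
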