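test_that("zero-divergence limit collapses all breeds onto the ancestor", {
  m <- breed_model(n_loci = 500, fst_duroc = 0, fst_ly_split = 0,
                   fst_ly_ancestor = 0, seed = 3)
  fr <- simulate_breed_frequencies(m)
  fm <- crossase:::freq_matrix(fr)
  expect_equal(fm[, "D"], fm[, "L"])
  expect_equal(fm[, "L"], fm[, "Y"])
  expect_true(all(fm >= 0.05 & fm <= 0.95))
})

test_that("breed model rejects invalid parameters", {
  expect_error(breed_model(n_loci = 0), "n_loci")
  expect_error(breed_model(ancestral_freq_range = c(0.9, 0.1)), "ordered")
  expect_error(breed_model(fst_duroc = 1.2), "F parameters")
})

test_that("frequency draws are deterministic given the seed", {
  m <- breed_model(n_loci = 1000, seed = 42)
  expect_identical(simulate_breed_frequencies(m),
                   simulate_breed_frequencies(m))
  m2 <- breed_model(n_loci = 1000, seed = 43)
  expect_false(identical(simulate_breed_frequencies(m),
                         simulate_breed_frequencies(m2)))
})

test_that("Landrace and Yorkshire stay mutually closer than either is to Duroc", {
  # divergence ordering must hold across seeds, not for one lucky draw
  for (seed in 1:5) {
    m <- breed_model(n_loci = 10000, fst_duroc = 0.15,
                     fst_ly_split = 0.03, fst_ly_ancestor = 0.03,
                     seed = seed)
    fm <- crossase:::freq_matrix(simulate_breed_frequencies(m))
    d_ly <- mean(abs(fm[, "L"] - fm[, "Y"]))
    expect_lt(d_ly, mean(abs(fm[, "D"] - fm[, "L"])))
    expect_lt(d_ly, mean(abs(fm[, "D"] - fm[, "Y"])))
  }
})

test_that("purebred genotypes follow HWE and respect fixed loci", {
  fr <- make_freqs(f_D = c(1, 0.5), f_L = 0.3, f_Y = 0.3)
  gm <- simulate_purebred_genotypes(fr, c(D = 10000L), seed = 5)
  g_fixed <- gm$geno[, gm$loci$pos == 1000L]
  expect_true(all(g_fixed == 0L))
  het <- mean(gm$geno[, gm$loci$pos == 2000L] == 1L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("an absent breed yields an empty sample block, not a failure", {
  fr <- make_freqs(0.5, 0.5, 0.5, n = 10)
  gm <- simulate_purebred_genotypes(fr, c(D = 0L, L = 3L, Y = 2L), seed = 1)
  expect_equal(length(gm$samples), 5L)
  expect_false(any(gm$breed == "D"))
})

test_that("family gametes reconstruct genotypes and forced crosses are het", {
  # fixed difference: D all-ref, L and Y all-alt -> every offspring het
  fr <- make_freqs(f_D = 1, f_L = 0, f_Y = 0, n = 200)
  fam <- simulate_dly_family(fr, n_offspring = 4, seed = 2)
  for (o in names(fam$origin)) {
    org <- fam$origin[[o]]
    expect_identical(org$pat + org$mat,
                     unname(fam$genotypes$geno[o, ]))
    expect_true(all(org$pat == 0L))  # paternal allele is always ref
    expect_true(all(fam$genotypes$geno[o, ] == 1L))
  }
  # L hom-ref x Y hom-alt grandparents force a het F1 dam
  fr2 <- make_freqs(f_D = 0.5, f_L = 1, f_Y = 0, n = 100)
  fam2 <- simulate_dly_family(fr2, n_offspring = 1, seed = 2)
  expect_true(all(fam2$genotypes$geno["LY_dam", ] == 1L))
})

test_that("gamete identity holds on a generic family", {
  fr <- simulate_breed_frequencies(breed_model(n_loci = 2000, seed = 9))
  fam <- simulate_dly_family(fr, n_offspring = 3, seed = 10)
  for (o in names(fam$origin))
    expect_identical(fam$origin[[o]]$pat + fam$origin[[o]]$mat,
                     unname(fam$genotypes$geno[o, ]))
})

test_that("allelic counts respect het-only emission and the planted ratio", {
  fr <- simulate_breed_frequencies(breed_model(n_loci = 3000, seed = 21))
  fam <- simulate_dly_family(fr, n_offspring = 6, seed = 22)
  gmod <- make_gene_model(fam$genotypes$loci, n_genes = 150,
                          snps_per_gene = 3, gap_snps = 1)
  truth <- ase_truth_spec(gmod, tissues = "T1", frac_ase = 1,
                          ase_ratio = 0.8, seed = 23)
  sim <- simulate_allelic_counts(fam, gmod, truth, depth_mean = 100,
                                 dispersion = 10, seed = 24)
  cnt <- sim$counts
  # counts appear only at loci where that sample is heterozygous
  for (o in unique(cnt$sample)) {
    rows <- cnt[cnt$sample == o, ]
    idx <- match(paste(rows$chrom, rows$pos),
                 paste(fam$genotypes$loci$chrom, fam$genotypes$loci$pos))
    expect_true(all(fam$genotypes$geno[o, idx] == 1L))
  }
  # paternal fraction over >= 100 effect genes ~ 0.8 within binomial error
  pat <- ifelse(unlist(lapply(seq_len(nrow(cnt)), function(i) {
    org <- fam$origin[[cnt$sample[i]]]
    idx <- match(paste(cnt$chrom[i], cnt$pos[i]),
                 paste(fam$genotypes$loci$chrom, fam$genotypes$loci$pos))
    org$pat[idx] == 0L
  })), cnt$ref_count, cnt$alt_count)
  total <- sum(cnt$ref_count + cnt$alt_count)
  se <- sqrt(0.8 * 0.2 / total)
  expect_lt(abs(sum(pat) / total - 0.8), 3 * se)
})

test_that("monoallelic and balanced limits behave", {
  fr <- make_freqs(1, 0, 0, n = 60)  # everyone het, paternal = ref
  fam <- simulate_dly_family(fr, n_offspring = 2, seed = 5)
  gmod <- make_gene_model(fam$genotypes$loci, n_genes = 20,
                          snps_per_gene = 3, gap_snps = 0)
  t1 <- ase_truth_spec(gmod, tissues = "T1", frac_ase = 1, ase_ratio = 1,
                       seed = 1)
  sim <- simulate_allelic_counts(fam, gmod, t1, depth_mean = 50, seed = 6)
  # paternal allele is ref everywhere, rho = 1 -> no alt (maternal) reads
  expect_true(all(sim$counts$alt_count == 0L))
  t0 <- ase_truth_spec(gmod, tissues = "T1", frac_ase = 0, seed = 1)
  sim0 <- simulate_allelic_counts(fam, gmod, t0, depth_mean = 200, seed = 7)
  frac <- sum(sim0$counts$ref_count) /
    sum(sim0$counts$ref_count + sim0$counts$alt_count)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("study bundles are byte-identical under one seed", {
  st1 <- simulate_study(breed_model(n_loci = 1500), n_genes = 30L,
                        seed = 77)
  st2 <- simulate_study(breed_model(n_loci = 1500), n_genes = 30L,
                        seed = 77)
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  p1 <- write_study(st1, d1); p2 <- write_study(st2, d2)
  for (k in names(p1))
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]),
                     info = paste("file", k))
})

test_that("generated inputs pass the consuming validators unmodified", {
  st <- simulate_study(breed_model(n_loci = 1200), n_genes = 25L, seed = 31)
  dir <- tempfile()
  paths <- write_study(st, dir)
  breeds <- read.table(paths[["breeds"]], header = TRUE)
  gm <- read_vcf_genotypes(paths[["purebreds"]],
                           setNames(breeds$breed, breeds$sample),
                           quiet = TRUE)
  expect_s3_class(gm, "genotype_matrix")
  fam <- read_vcf_genotypes(paths[["family"]], quiet = TRUE)
  ped <- read_pedigree(paths[["pedigree"]])
  expect_s3_class(phase_family(fam, ped), "phased_family")
  expect_silent(read_exons_bed(paths[["exons"]]))
  expect_silent(read_allelic_counts(paths[["counts"]]))
})
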