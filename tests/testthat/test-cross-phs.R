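# brute-force reference for a terminal two-sided cross, written against
# the genotype distributions directly (independent of the package's
# closed form and of phs_enumerate's recursion)
brute_phs <- function(p_sire, p_dam) {
  gref <- c(1, 0.5, 0)
  phs <- 0
  for (gs in 0:2) for (gd in 0:2) {
    w <- p_sire[gs + 1] * p_dam[gd + 1]
    rs <- gref[gs + 1]; rd <- gref[gd + 1]
    phs <- phs + w * (rs * (1 - rd) + (1 - rs) * rd)
  }
  phs
}
hwe <- function(f) c(f^2, 2 * f * (1 - f), (1 - f)^2)

test_that("scheme strings parse into the intended trees", {
  s <- cross_scheme("DLY")
  expect_equal(s$leaves, c("D", "L", "Y"))
  expect_equal(s$root$sire$breed, "D")
  expect_equal(s$root$dam$sire$breed, "L")
  two <- cross_scheme("LY")
  expect_equal(two$root$dam$breed, "Y")
  expect_error(cross_scheme("DLYX"), "2 or 3")
  expect_error(cross_scheme(list("D", "L", "Y")), "two-element")
})

test_that("transmitted-allele frequency recursion matches first principles", {
  fr <- make_freqs(f_D = c(1, 0.5, 1), f_L = c(0, 0.5, 0),
                   f_Y = c(0, 0.5, 0))
  expect_equal(transmitted_allele_frequency(cross_scheme("DLY")$root$sire,
                                            fr),
               c(1, 0.5, 1))
  # F1 of a fixed difference transmits each allele equally
  expect_equal(transmitted_allele_frequency(cross_scheme("DL"), fr)[1], 0.5)
  # leaf with genotype freqs (0.25, 0.5, 0.25) has f = 0.5
  expect_equal(transmitted_allele_frequency(cross_scheme("LY"), fr)[2], 0.5)
  bad <- cross_scheme(list("D", "Z"))
  expect_error(transmitted_allele_frequency(bad, fr), "unknown breed")
})

test_that("PHS closed form matches hand-derived values", {
  fr <- make_freqs(f_D = c(1, 0.5, 0.9), f_L = c(0, 0.5, 0.1),
                   f_Y = c(0, 0.5, 0.1))
  tab <- phs_for_scheme(cross_scheme("DLY"), fr)
  expect_equal(tab$phs[1], 1)    # sire side fixed ref, dam side fixed alt
  expect_equal(tab$phs[2], 0.5)  # symmetric f = 0.5 everywhere
  expect_equal(tab$phs[3], 0.9 * 0.9 + 0.1 * 0.1)  # 0.82
  expect_equal(tab$pRR + tab$pHet + tab$pAA, rep(1, 3))
  expect_error(phs_for_scheme(cross_scheme(list("D", "L"))$root$sire, fr))
})

test_that("closed form equals brute-force enumeration on random triples", {
  set.seed(123)
  n <- 400
  fr <- make_freqs(runif(n), runif(n), runif(n))
  for (s in c("DLY", "LYD", "YDL")) {
    sc <- cross_scheme(s)
    tab <- phs_for_scheme(sc, fr)
    enum <- phs_enumerate(sc, fr)
    expect_lt(max(abs(tab$phs - enum$phs)), 1e-12)
    expect_lt(max(abs(tab$pRR - enum$pRR)), 1e-12)
    # and against the flat 9-combination expansion at the root
    fm <- crossase:::freq_matrix(fr)
    b <- sc$leaves
    f_dam <- (fm[, b[2]] + fm[, b[3]]) / 2
    ref <- vapply(seq_len(n), function(i)
      brute_phs(hwe(fm[i, b[1]]), hwe(f_dam[i])), numeric(1))
    expect_lt(max(abs(tab$phs - ref)), 1e-12)
  }
})

test_that("PHS is symmetric in the dam-side breeds and in two-way crosses", {
  set.seed(7)
  fr <- make_freqs(runif(50), runif(50), runif(50))
  dly <- phs_for_scheme(cross_scheme(list("D", list("L", "Y"))), fr)
  dyl <- phs_for_scheme(cross_scheme(list("D", list("Y", "L"))), fr)
  expect_equal(dly$phs, dyl$phs)
  expect_equal(phs_for_scheme(cross_scheme("LY"), fr)$phs,
               phs_for_scheme(cross_scheme("YL"), fr)$phs)
})

test_that("PHS attains its bounds exactly at fixed leaves", {
  fr <- make_freqs(f_D = c(1, 0, 1), f_L = c(1, 0, 0), f_Y = c(1, 0, 0))
  tab <- phs_for_scheme(cross_scheme("DLY"), fr)
  expect_equal(tab$phs[1], 0)  # all fixed ref
  expect_equal(tab$phs[2], 0)  # all fixed alt
  expect_equal(tab$phs[3], 1)  # sire and dam sides fixed opposite
})

test_that("binning follows the 20-interval convention and conserves counts", {
  tab <- data.frame(chrom = "1", pos = 1:4, phs = c(0, 0.049, 0.05, 1))
  b <- bin_phs_counts(tab)
  expect_equal(b$n[b$bin == 0], 2L)
  expect_equal(b$n[b$bin == 1], 1L)
  expect_equal(b$n[b$bin == 19], 1L)
  expect_equal(sum(b$n), nrow(tab))
  all10 <- bin_phs_counts(data.frame(phs = rep(0.51, 7)))
  expect_equal(all10$n[all10$bin == 10], 7L)
  expect_error(bin_phs_counts(data.frame(phs = numeric(0))), "empty")
})

test_that("scheme correlations recover exact (anti)linearity", {
  b1 <- data.frame(n = c(1, 2, 3))
  expect_equal(scheme_pairwise_correlation(list(a = b1, b = b1))$r["a", "b"],
               1)
  rev <- data.frame(n = c(3, 2, 1))
  cc <- scheme_pairwise_correlation(list(a = b1, b = rev))
  expect_equal(cc$r["a", "b"], -1)
  expect_equal(cc$mean_r_vs_first, -1)
  flat <- data.frame(n = c(2, 2, 2))
  expect_warning(scheme_pairwise_correlation(list(a = b1, b = flat)),
                 "zero-variance")
})

test_that("bin means are the values' means and increase with bin index", {
  tab <- data.frame(phs = c(0.52, 0.54, 0.31, 0.9))
  e <- expected_het_by_bin(tab)
  expect_equal(e$expected_het[e$bin == 10], 0.53)
  expect_equal(e$expected_het[e$bin == 6], 0.31)
  set.seed(1)
  dense <- data.frame(phs = runif(5000))
  ed <- expected_het_by_bin(dense)
  expect_true(all(diff(ed$expected_het) > 0))
})

test_that("observed heterozygosity per bin and its correlation behave", {
  tab <- data.frame(chrom = "1", pos = 1:8,
                    phs = c(rep(0.12, 4), rep(0.87, 4)))
  g <- c(1L, 1L, 0L, 0L, 1L, 1L, 1L, 2L)
  ob <- observed_het_by_bin(g, tab)
  expect_equal(ob$bins$observed_het[ob$bins$bin == 2], 0.5)
  expect_equal(ob$bins$observed_het[ob$bins$bin == 17], 0.75)
  expect_error(observed_het_by_bin(g[1:3], tab), "aligned")
})

test_that("synthetic offspring track the expected curve; purebreds do not", {
  fr <- simulate_breed_frequencies(breed_model(n_loci = 100000, seed = 19))
  pure <- simulate_purebred_genotypes(fr, seed = 20)
  emp <- genotype_frequencies(pure)
  tab <- phs_for_scheme(cross_scheme("DLY"), emp)
  fam <- simulate_dly_family(fr, n_offspring = 2, seed = 21)
  gkey <- paste(fam$genotypes$loci$chrom, fam$genotypes$loci$pos, sep = ":")
  r_of <- function(s) {
    g <- setNames(fam$genotypes$geno[s, ], gkey)
    observed_het_by_bin(g, tab)$r
  }
  r_off <- r_of("O01")
  expect_gte(r_off, 0.9)
  expect_lt(r_of("D_sire"), r_off)
})

test_that("high-PHS marker extraction respects the strict threshold", {
  tab <- data.frame(chrom = "1", pos = c(30L, 10L, 20L),
                    phs = c(0.95, 0.8, 0.91))
  m <- high_phs_markers(tab, 0.9)
  expect_equal(nrow(m), 2L)
  expect_equal(m$pos, c(20L, 30L))  # sorted by position
  expect_equal(nrow(high_phs_markers(tab, 1.0)), 0L)
  expect_equal(nrow(high_phs_markers(tab, 0)), 3L)
})
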