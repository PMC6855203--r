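---
title: "Breed-of-origin analysis in three-way crosses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breed-of-origin analysis in three-way crosses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossase)
```

crossase implements a breed-of-origin analysis for terminal three-way
crossbreeding, the mating design behind most commercial pork production:
a Duroc (D) sire on a Landrace x Yorkshire (L x Y) F1 dam, giving DLY
offspring. The package answers three questions. Which SNPs will a
crossbred offspring reliably carry heterozygous, given only purebred
genotype panels? Which of an offspring's heterozygous alleles came from
its sire and which from its dam? And, per gene and tissue, do the two
parental alleles express unequally (allele-specific expression, ASE)?

Because these questions are usually asked of resequencing and RNA-seq
data that no desk-scale package can ship, crossase pairs each method
with a synthetic-data generator that reproduces the statistical
structure of such a study and carries ground-truth labels, so every
stage is validated by recovery tests rather than by assertion.

## Probability of a heterozygous SNP (PHS)

For one biallelic locus, a breed's genotype frequencies over called
individuals are (p_RR, p_RA, p_AA). The *transmitted-allele frequency*

  f = p_RR + p_RA / 2

is the probability that a random individual of that breed passes the
reference allele to an offspring. A crossbreeding scheme is a binary
tree of matings; the transmitted frequency of an internal node is the
mean of its two children's, because each parent contributes one gamete.
At the terminal cross with sire-side and dam-side frequencies f_s and
f_d, the offspring genotype distribution is

  pRR = f_s f_d,   pHet = f_s (1 - f_d) + (1 - f_s) f_d,
  pAA = (1 - f_s)(1 - f_d),

and PHS = pHet. This closed form is exact — not an approximation — under
random mating within each node: the offspring genotype depends on each
side's genotype distribution only through its transmitted frequency. The
package nonetheless keeps the full genotype-frequency propagation
(`phs_enumerate()`, which enumerates all 3 x 3 parental genotype pairs
and their gamete transmissions) as an independent oracle, and the test
suite requires agreement to 1e-12; this guards the algebraic reduction
rather than re-deriving it.

Two presentation conventions are fixed by the binning design: PHS values
are grouped into 20 intervals of width 0.05, half-open `[k/20, (k+1)/20)`
with the last bin closed, and marker sets use a *strict* threshold
(PHS > 0.9). Scheme distributions are compared by Pearson correlation of
the 20 bin counts (raw counts by default; a log10(n+1) option exists
because bin counts span orders of magnitude).

Validation against individuals inverts the model: loci are binned by
DLY PHS, and each genotyped individual's realized heterozygous fraction
per bin is correlated with the bin-mean PHS. We use bin-mean PHS as the
expected curve (rather than simulating a cohort and measuring it) since
the bin mean is exactly the model's conditional expectation; a sampled
cohort adds only Monte Carlo noise. In the packaged runs, simulated DLY
offspring reach r > 0.99 against this curve while their purebred
founders sit near zero — the qualitative signature that separates
crossbred from purebred genomes.

## Trio phasing

An offspring's heterozygous locus has ordered parental genotype pairs
(sire, dam) from a 3 x 3 cube; 7 of the 9 pairs are consistent with a
heterozygous offspring under Mendelian transmission. Two pairs (both
parents homozygous, for opposite alleles) and four pairs (exactly one
parent heterozygous) determine the origin of both alleles — a homozygous
parent can only have transmitted its own allele. The remaining
consistent pair, het x het, is unphasable from trio genotypes alone. The
classifier enumerates this cube explicitly (`classify_trio_configuration`),
and the 7 = 2 + 4 + 1 decomposition is asserted as an exact test.

Conventions: phased haplotypes are written paternal-first (`pat|mat`);
loci whose trio genotypes are Mendelian-impossible are excluded from
phasing and from downstream ASE (a conservative choice — such loci are
genotyping errors in real data); grandparental genotypes are *not* used
to rescue het x het trios, keeping the method a pure trio method. The
phased fraction is reported both over all heterozygous loci and with
Mendelian-error loci removed from the denominator, since published
phased fractions rarely state which denominator they use.

At loci where every breed sits at Hardy-Weinberg equilibrium with
f = 0.5, the phasable fraction has the closed value
1 - P(both parents het | offspring het) = 1 - (0.5^3)/0.5 = 3/4, which
the test suite checks within three binomial standard errors. Under the
default divergence model the simulated offspring phase at ~87%, close
to the high-80s fractions seen in real three-way families.

## ASE calling

Gene-level ASE is called from phased exonic SNP read counts:

1. SNPs are assigned to genes by exon overlap (BED intervals are
   0-based half-open; a 1-based SNP at position p lies in `[start, end)`
   iff start < p <= end). SNPs in exons of two genes count for both but
   are flagged; an exclusion mode exists.
2. A read covering several heterozygous SNPs is counted once, at its
   lowest-coordinate SNP — the tie-break is arbitrary but fixed, and
   read conservation (in = retained + discarded) is tested.
3. Per-SNP ref/alt counts are reoriented to paternal/maternal with the
   trio phase and summed within the gene.
4. Each gene x sample x tissue with pat + mat >= 10 reads is tested
   with the exact two-sided binomial test against 1:1:
   p = P(X <= m) + P(X >= n - m), m = min(pat, mat), X ~ Bin(n, 1/2).
   Below 10 reads the gene is not tested — the test has essentially no
   power there, and an untested gene is *not evidence of balance*.
5. p-values are Bonferroni-adjusted within one sample x tissue (the
   set of *tested* genes defines m; a genome-wide family option
   exists), and a gene is ASE iff adjusted p < 0.05, strictly.
6. Classes are ASE / NA / NO_HET_SNP: NA covers tested-not-significant
   *and* untestable-with-het-SNP genes (the three-class scheme leaves
   no other home for them); NO_HET_SNP means the sample has no phased
   exonic heterozygous SNP in the gene at all.
7. A *high-confidence* ASE gene in a tissue is one classified ASE in at
   least 2 of the 6 offspring; its allelic ratio is the median over its
   ASE samples of max(pat, mat)/(pat + mat). The ratio is defined on
   the higher-expressed allele (hence always >= 0.5) because published
   per-tissue medians are reported on that scale; a signed paternal
   fraction is available in the per-sample records.

The exact binomial p is computed from `pbinom` tails; tests compare it
against direct pmf summation for every n up to 500 (agreement to
1e-12) and against `binom.test`. Bonferroni is compared against
`p.adjust`. Operating characteristics are measured by simulation: with
200 all-null genes per sample the fraction of sample-level families
with any (Bonferroni-corrected) call stays near 0.03 — the discrete
test is conservative — and with a planted paternal fraction of 0.8 the
per-sample sensitivity among genes with >= 100 reads exceeds 0.95, with
the recovered median ratio within 0.01 of the planted value.

## The synthetic-data generator

The generator emulates the three data layers of a real study.

**Breed frequencies** follow a hierarchical Balding–Nichols model:
ancestral frequencies are Uniform(0.05, 0.95) (the analysis concerns
segregating SNPs, so monomorphic-everywhere loci are avoided); Duroc
diverges from the ancestor at `fst_duroc`; Landrace and Yorkshire
diverge at `fst_ly_split` from a shared intermediate that itself sits
`fst_ly_ancestor` from the ancestor. A descendant frequency at
divergence F is Beta(p(1-F)/F, (1-p)(1-F)/F) — mean p, variance
Fp(1-p). The defaults, `fst_duroc = 0.30`, `fst_ly_ancestor = 0.10`,
`fst_ly_split = 0.05`, were chosen once to match two features of real
commercial pig panels: Landrace and Yorkshire are mutually much closer
than either is to Duroc, and roughly one SNP per thousand attains
PHS > 0.9 in the DLY cross (resequencing studies report on the order
of 1.5e4 such loci among ~1.3e7 SNPs). Weaker divergence preserves the
ordering but starves the high-PHS tail that the marker analysis
exists for.

**Genotypes** are drawn under per-breed HWE for the purebred panels
(11 D, 9 L, 10 Y by default), with per-site depth from a negative
binomial. The family is built gamete by gamete — grandparents from L
and Y, the F1 dam from one tracked gamete of each, the D sire from D,
each offspring from one tracked sire gamete and one dam gamete — so
every offspring carries a known paternal/maternal allele at every
locus. Loci are unlinked: PHS and per-locus phasing are marginal
per-locus quantities, so linkage would change no expectation, only the
correlation structure of errors, and no method here pools across loci
except within genes.

**RNA counts**: per gene x offspring x tissue, a total from
NB(mu = 100, size = 10), a paternal share Binomial(total, rho), and a
multinomial split over the gene's heterozygous exonic SNPs, reoriented
to ref/alt by the true phase. Null genes have rho = 0.5 exactly;
planted genes have rho = 0.8 (within the 0.68–0.82 range of reported
per-tissue median allelic ratios) in one randomly assigned home tissue,
which also makes the planted truth predominantly tissue-specific, as
real ASE is. The NB-total/binomial-split pair is the simplest model
consistent with the binomial test's own assumption; it deliberately
omits mapping bias toward the reference allele, overdispersion of the
allelic split (e.g. beta-binomial), and shared-variance structure
across tissues.

What passing tests therefore show — and do not show: they validate the
combinatorics, the probability algebra, the estimators and the error
control under the stated generative model. They cannot certify
robustness to alignment artifacts, reference bias, genotyping error or
allelic overdispersion, which real studies must address upstream or
with a more dispersed null.

## Numerical and design choices

- **Depth-tail filter**: empirical quantiles (R type 7) at 1% per
  tail, removing loci *strictly* outside the bounds; on continuous-ish
  depth distributions this removes ~2% in total, the conventional
  cleanup fraction. Applied per input matrix (cohorts are filtered
  against their own depth distribution).
- **Missing genotypes** never enter denominators: frequencies use
  called individuals only, and a breed with no call at a locus makes
  the locus NA there and excluded (with a count) from any scheme using
  that breed.
- **Monomorphic loci are retained**: they carry PHS 0 (or 1 only in
  the fixed-opposite case) and simply populate the extreme bins.
- **Determinism**: every simulation takes a seed; multi-stage runs
  derive independent per-stage seeds from one master seed
  (`derive_seeds`), so a stage can be reproduced in isolation and
  identical configurations give byte-identical output files.
- **Degenerate inputs**: zero-sample breeds simulate to empty blocks;
  an all-equal depth vector filters nothing; empty PHS tables refuse
  to bin (error, not silent zero); zero-variance bin vectors make the
  correlation NA with a warning rather than fabricating an r.
- **Problem sizes** in the shipped analyses: 100k loci, 200 genes,
  four tissues, six offspring; property tests use 1k–100k loci as the
  precision of each check requires. These sizes put every simulated
  standard error well below the tested tolerances.

## Repository shape

The package exposes each stage as ordinary functions (this vignette's
sections map one-to-one onto them), and the repository presents the
study as numbered drivers under `analysis/` — simulate, PHS, phasing,
ASE — each a thin narrative over those functions writing tables under
`results/`. There is no shell CLI: the intended users run R, and the
drivers plus `run_pipeline()` (which chains all stages and reconciles
counts through the on-disk formats) are the entry points.

## Known limitations

- PHS assumes random mating within breed and no selection between the
  purebred panels and the commercial cross; panel sizes of ~10 make f
  a noisy estimate at any single locus (binomial SE ~0.1), which is
  why marker sets should be read as enriched, not guaranteed.
- Trio phasing cannot phase het x het trios (~13% of het loci under
  the default model); read-backed or population phasing would be
  needed for those.
- The ASE binomial test is anti-conservative under allelic
  overdispersion; the high-confidence rule (two independent offspring)
  is the package's guard, mirroring standard practice.
- The generator's independence assumptions (unlinked loci, independent
  tissues) are stated above; conclusions about LD-aware analyses are
  out of scope.
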