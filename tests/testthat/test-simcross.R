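test_that("cross_model enforces its invariants", {
  chr <- c(chr1 = 1e6)
  mk <- list(chr1 = c(1e3, 5e5))
  ok <- cross_model(chr, mk, list(chrom = "chr1", pos = 5e5), n_f2 = 100)
  expect_s3_class(ok, "cross_model")
  expect_error(cross_model(chr, mk, list(chrom = "chr1", pos = 123)),
               "coincide with a marker")
  expect_error(cross_model(chr, list(chr1 = c(5e5, 1e3)),
                           list(chrom = "chr1", pos = 5e5)),
               "strictly increasing")
  expect_error(cross_model(chr, mk, list(chrom = "chr1", pos = 5e5),
                           n_f2 = 80, pool_size_w = 50, pool_size_m = 50),
               "exceed n_f2")
  expect_error(cross_model(chr, mk, list(chrom = "chr1", pos = 5e5),
                           n_f2 = 100, error_rate = 0.5),
               "error_rate")
  expect_error(cross_model(chr, list(chr1 = c(1e3, 2e6)),
                           list(chrom = "chr1", pos = 1e3)),
               "lie in")
})

test_that("a monogenic recessive trait segregates 3:1 in the F2", {
  m <- cross_model(c(chr1 = 1e3), list(chr1 = 500),
                   list(chrom = "chr1", pos = 500),
                   n_f2 = 4000, pool_size_w = 1, pool_size_m = 1, seed = 11)
  f2 <- simulate_f2(m)
  frac <- mean(f2$phenotype == "dwarf")
  tol <- 4 * sqrt(0.25 * 0.75 / 4000)
  expect_lt(abs(frac - 0.25), tol)
  # phenotype is determined by the causal dosage
  expect_identical(f2$phenotype == "dwarf", unname(f2$dosage[, 1] == 2L))
})

test_that("linkage behaves correctly at zero and free recombination", {
  # adjacent markers 1 bp apart: recombination fraction ~0, dosages identical
  m0 <- cross_model(c(chr1 = 1e3), list(chr1 = c(500, 501)),
                    list(chrom = "chr1", pos = 500), n_f2 = 500,
                    pool_size_w = 1, pool_size_m = 1, seed = 3)
  f0 <- simulate_f2(m0)
  expect_lt(mean(f0$dosage[, 1] != f0$dosage[, 2]), 0.01)

  # markers 1e9 bp apart: dosages uncorrelated, like independent 1:2:1 draws
  m1 <- cross_model(c(chr1 = 2e9), list(chr1 = c(1, 1e9 + 1)),
                    list(chrom = "chr1", pos = 1), n_f2 = 10000,
                    pool_size_w = 1, pool_size_m = 1, seed = 4)
  f1 <- simulate_f2(m1)
  r_sim <- cor(f1$dosage[, 1], f1$dosage[, 2])
  # oracle: two independent Binomial(2, 1/2) dosage vectors
  set.seed(4)
  r_orc <- cor(rbinom(10000, 2, 0.5), rbinom(10000, 2, 0.5))
  mc <- 4 / sqrt(10000)
  expect_lt(abs(r_sim), mc)
  expect_lt(abs(r_sim - r_orc), 2 * mc)
})

test_that("phenotypic pools have the Mendelian allele frequencies", {
  m <- cross_model(c(chr1 = 1e3), list(chr1 = 500),
                   list(chrom = "chr1", pos = 500),
                   n_f2 = 6000, pool_size_w = 1000, pool_size_m = 1000,
                   seed = 21)
  f2 <- simulate_f2(m)
  pools <- build_pools(f2, m)
  # every M-pool member is homozygous mutant at the causal marker
  expect_equal(pools$freq_m[1], 1.0)
  # oracle: enumeration of the genotype distribution conditional on non-dwarf
  gp <- c(0.25, 0.5, 0.25)           # dosage 0/1/2 in the F2
  cond <- gp[1:2] / sum(gp[1:2])     # non-dwarf carries dosage 0 or 1
  e_freq <- sum(cond * c(0, 1)) / 2  # = 1/3
  expect_equal(e_freq, 1 / 3)
  var_d <- sum(cond * c(0, 1)^2) - sum(cond * c(0, 1))^2
  tol <- 4 * sqrt(var_d / (4 * 1000))
  expect_lt(abs(pools$freq_w[1] - e_freq), tol)
})

test_that("pool construction fails loudly on a phenotype shortfall", {
  m <- cross_model(c(chr1 = 1e3), list(chr1 = 500),
                   list(chrom = "chr1", pos = 500),
                   n_f2 = 60, pool_size_w = 10, pool_size_m = 50, seed = 5)
  f2 <- simulate_f2(m)
  expect_error(build_pools(f2, m), "dwarf")
})

test_that("read sampling follows the allele-flip error model", {
  m <- cross_model(c(chr1 = 1e3), list(chr1 = 500),
                   list(chrom = "chr1", pos = 500),
                   n_f2 = 10, pool_size_w = 1, pool_size_m = 1,
                   depth_mean = 40, depth_model = "fixed", error_rate = 0,
                   seed = 6)
  r1 <- sample_reads(1, m)
  expect_equal(c(r1$ref, r1$alt), c(0L, 40L))
  r0 <- sample_reads(0, m)
  expect_equal(c(r0$ref, r0$alt), c(40L, 0L))

  mhuge <- cross_model(c(chr1 = 1e3), list(chr1 = 500),
                       list(chrom = "chr1", pos = 500),
                       n_f2 = 10, pool_size_w = 1, pool_size_m = 1,
                       depth_mean = 1e5, depth_model = "fixed",
                       error_rate = 0.01, seed = 7)
  rh <- sample_reads(0.5, mhuge)
  # symmetric flips leave a half-and-half pool at expected fraction 1/2
  expect_lt(abs(rh$alt / rh$depth - 0.5), 4 * sqrt(0.25 / 1e5))
})

test_that("datasets round-trip through VCF and are seed-deterministic", {
  m <- cross_model(c(chr1 = 1e6), list(chr1 = seq(2e4, 1e6, by = 2e4)),
                   list(chrom = "chr1", pos = 5e5),
                   n_f2 = 80, pool_size_w = 20, pool_size_m = 15,
                   depth_mean = 40, depth_model = "fixed", error_rate = 0,
                   seed = 8)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "a.vcf"); t1 <- file.path(d, "a.tsv")
  p2 <- file.path(d, "b.vcf"); t2 <- file.path(d, "b.tsv")
  emit_dataset(m, p1, t1)
  emit_dataset(m, p2, t2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(readLines(t1), readLines(t2))

  suppressMessages(back <- read_sites(p1))
  expect_equal(nrow(back), length(m$markers$chr1))
  sim <- simulate(m)
  expect_equal(back$pos, sim$sites$pos)
  expect_identical(back$counts_m, sim$sites$counts_m)

  # the M pool is fixed for the mutant (alt) allele at the causal marker
  truth <- read_truth(t1)
  ci <- which(truth$is_causal)
  cm <- back$counts_m[[ci]]
  expect_equal(cm[1], 0L)
  expect_equal(cm[2], 40L)
  expect_equal(truth$true_freq_m[ci], 1.0)
})
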