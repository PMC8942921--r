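test_that("depth bounds are exclusive on both sides, per pool", {
  cfg <- filter_config()
  expect_equal(passes_filters(make_site(c(20, 20), c(1, 2)), cfg),
               list(pass = FALSE, reason = "depth"))   # depth_m = 3
  expect_equal(passes_filters(make_site(c(60, 60), c(20, 20)), cfg),
               list(pass = FALSE, reason = "depth"))   # depth_w = 120
  expect_true(passes_filters(make_site(c(2, 2), c(20, 20)), cfg)$pass)  # 4
  expect_true(passes_filters(make_site(c(60, 59), c(20, 20)), cfg)$pass) # 119
  # missing allele depths cannot establish an in-bounds depth
  s <- make_site(c(20, 20), c(20, 20))
  s$counts_m <- list(NA_integer_)
  expect_equal(passes_filters(s, cfg)$reason, "depth")
})

test_that("multi-allelic sites fail first, whatever else is wrong", {
  s <- make_site(c(10, 5, 3), c(2, 9, 1), qual = 5, alt = "C,T")
  expect_equal(passes_filters(s)$reason, "multiallelic")
  cfg_lax <- filter_config(require_biallelic = FALSE, min_quality = 1)
  expect_true(passes_filters(s, cfg_lax)$pass)
})

test_that("quality comparison is strict by default and configurable", {
  s20 <- make_site(c(20, 20), c(20, 20), qual = 20)
  expect_equal(passes_filters(s20)$reason, "quality")
  expect_true(passes_filters(s20, filter_config(quality_strict = FALSE))$pass)
  # an annotated base quality is tested too; NA base quality is ignored
  sbq <- make_site(c(20, 20), c(20, 20), qual = 60, base_qual = 15)
  expect_equal(passes_filters(sbq)$reason, "quality")
  expect_true(passes_filters(make_site(c(20, 20), c(20, 20), qual = 21))$pass)
})

test_that("the M-pool allele is the majority allele, ties toward alt", {
  expect_equal(pick_m_allele(make_site(c(1, 1), c(0, 40))), "T")
  expect_equal(pick_m_allele(make_site(c(1, 1), c(40, 0))), "A")
  expect_equal(pick_m_allele(make_site(c(1, 1), c(20, 20))), "T")
  expect_error(pick_m_allele(make_site(c(1, 1), c(0, 0))), "zero M-pool")
})

test_that("SNP-index arithmetic matches hand computation", {
  i1 <- compute_index(make_site(c(27, 13), c(0, 40)))
  expect_equal(i1$snp_index_m, 1.0)
  expect_equal(i1$snp_index_w, 0.325)
  expect_equal(i1$delta, 0.675)
  expect_equal(i1$m_allele, "T")

  i2 <- compute_index(make_site(c(20, 20), c(20, 20)))
  expect_equal(i2$delta, 0)

  i3 <- compute_index(make_site(c(30, 10), c(10, 30)))
  expect_equal(i3$snp_index_m, 0.75)
  expect_equal(i3$snp_index_w, 0.25)
  expect_equal(i3$delta, 0.5)

  expect_error(compute_index(make_site(c(0, 0), c(10, 10))), "zero depth")
})

test_that("index invariants hold on randomized sites", {
  s <- random_sites(400, seed = 31)
  res <- index_sites(s)
  expect_equal(sum(res$tally), nrow(s))
  expect_equal(res$tally[["pass"]], nrow(res$sites))
  if (nrow(res$sites) > 0) {
    expect_true(all(res$sites$snp_index_w >= 0 & res$sites$snp_index_w <= 1))
    expect_true(all(res$sites$snp_index_m >= 0.5))  # majority orientation
    expect_true(all(res$sites$delta >= -1 & res$sites$delta <= 1))
    expect_equal(res$sites$delta,
                 res$sites$snp_index_m - res$sites$snp_index_w)
  }
})

test_that("relaxing thresholds never loses passing sites", {
  s <- random_sites(400, seed = 32)
  base <- index_sites(s, filter_config())$tally[["pass"]]
  wider <- index_sites(
    s, filter_config(min_quality = 10, min_reads_exclusive = 1,
                     max_reads_exclusive = 500))$tally[["pass"]]
  expect_gte(wider, base)
  for (q in c(15, 25, 40)) {
    lo <- index_sites(s, filter_config(min_quality = q))$tally[["pass"]]
    hi <- index_sites(s, filter_config(min_quality = q + 10))$tally[["pass"]]
    expect_gte(lo, hi)
  }
})
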