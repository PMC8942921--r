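fixed_band <- function(upper, lower = -upper, depth = 40, level = 0.95) {
  structure(
    list(depths = depth, levels = level,
         lower = matrix(lower, 1, 1), upper = matrix(upper, 1, 1),
         pool_size_w = 50, pool_size_m = 50, n_reps = 0, seed = 0L),
    class = "bsa_band"
  )
}

test_that("window enumeration follows the anchored, truncated rule", {
  w <- make_windows(200, 100, 50)
  expect_equal(w$start, c(0, 50, 100, 150))
  expect_equal(w$end, c(100, 150, 200, 200))

  # oracle: brute-force enumeration of starts below the chromosome length
  starts <- c(); s <- 0
  while (s < 5e6) { starts <- c(starts, s); s <- s + 2e4 }
  w5 <- make_windows(5e6)
  expect_equal(nrow(w5), 250)
  expect_equal(w5$start, starts)
  expect_true(all(w5$end <= 5e6))

  wt <- make_windows(1e5, 2.5e6, 2e4)
  expect_true(all(wt$end == 1e5))  # every window truncated
  expect_error(make_windows(100, 0, 10), "positive")
})

test_that("window averaging matches the brute-force oracle exactly", {
  # a single site falls into every window covering it
  idx1 <- data.frame(chrom = "chr1", pos = 50001, m_allele = "T",
                     snp_index_w = 0.325, snp_index_m = 1, delta = 0.675,
                     depth_w = 40, depth_m = 40, stringsAsFactors = FALSE)
  w <- aggregate_windows(make_windows(2e5, 1e5, 2.5e4, chrom = "chr1"), idx1)
  hit <- !is.na(w$mean_delta)
  expect_equal(sum(hit), 3)  # windows starting at 0, 25k, 50k
  expect_true(all(w$mean_delta[hit] == 0.675))
  expect_equal(w$n_sites[!hit], rep(0L, sum(!hit)))

  # two sites in one window average without weights
  idx2 <- rbind(idx1, idx1)
  idx2$pos <- c(10, 20); idx2$delta <- c(0.2, 0.8)
  w2 <- aggregate_windows(make_windows(100, 100, 100, chrom = "chr1"), idx2)
  expect_equal(w2$mean_delta, 0.5)

  # randomized fixtures across several geometries
  for (seed in 1:4) {
    s <- random_sites(120, chrom_len = 5e4, seed = seed)
    idx <- index_sites(s)$sites
    set.seed(seed)
    ws <- sample(c(5e3, 1.2e4, 3.3e4), 1)
    st <- sample(c(1e3, 7e3), 1)
    wins <- make_windows(5e4, ws, st, chrom = "chr1")
    expect_equal(aggregate_windows(wins, idx),
                 brute_force_aggregate(wins, idx))
  }
})

test_that("unsorted sites are rejected", {
  idx <- data.frame(chrom = "chr1", pos = c(200, 100), m_allele = "T",
                    snp_index_w = 0.2, snp_index_m = 0.9, delta = 0.7,
                    depth_w = 40, depth_m = 40)
  expect_error(aggregate_windows(make_windows(1e3, 1e3, 1e3), idx), "sorted")
})

test_that("null band is seed-deterministic and tightens with information", {
  b1 <- null_band(n_reps = 400, seed = 123)
  b2 <- null_band(n_reps = 400, seed = 123)
  expect_identical(b1, b2)
  expect_true(all(b1$lower <= 0 & b1$upper >= 0))

  small <- null_band(50, 50, depths = 40, n_reps = 2000, seed = 5)
  big <- null_band(500, 500, depths = 10000, n_reps = 2000, seed = 5)
  width <- function(b) b$upper[1, 1] - b$lower[1, 1]
  expect_lt(width(big), width(small))

  # band width is non-increasing in depth across the default grid
  bg <- null_band(depths = c(10, 20, 40, 80), n_reps = 20000, seed = 6)
  for (lv in c("0.95", "0.99")) {
    w <- bg$upper[, lv] - bg$lower[, lv]
    expect_true(all(diff(w) <= 0.02))  # Monte-Carlo slack
  }
})

test_that("the single-individual, single-read null matches enumeration", {
  exact <- enumerate_null_delta_n1_d1()
  # the oriented statistic collapses to two outcomes at equal probability
  expect_equal(sort(names(exact)), c("0", "1"))
  expect_equal(unname(exact[["0"]]), 0.5)
  draws <- with(list(), {
    set.seed(77)
    bsamap:::null_delta_draws(10000, 1, 1, 1)
  })
  for (v in names(exact)) {
    p_hat <- mean(draws == as.numeric(v))
    tol <- 4 * sqrt(exact[[v]] * (1 - exact[[v]]) / 10000)
    expect_lt(abs(p_hat - exact[[v]]), tol)
  }
})

test_that("regions merge runs of significant windows", {
  wins <- make_windows(4e6, 2.5e6, 2e4, chrom = "chr1")
  wins$n_sites <- 5L
  wins$mean_depth <- 40
  wins$mean_delta <- 0.05
  wins$mean_index_w <- 0.4; wins$mean_index_m <- 0.9
  band <- fixed_band(0.3)

  expect_equal(nrow(call_regions(wins, band)), 0)  # all below the band

  hot <- wins$start >= 2e5 & wins$start <= 2.8e5
  wins$mean_delta[hot] <- 0.6
  reg <- call_regions(wins, band, min_consecutive = 3)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 2e5)
  expect_equal(reg$end, 2.8e5 + 2.5e6)
  expect_equal(reg$n_windows, 5L)

  # runs shorter than min_consecutive are suppressed
  wins$mean_delta[hot] <- 0.05
  wins$mean_delta[wins$start %in% c(1e6, 1.02e6)] <- 0.6
  expect_equal(nrow(call_regions(wins, band, min_consecutive = 3)), 0)
  # empty windows never count as significant
  wins$mean_delta[hot] <- 0.6
  wins$n_sites[hot] <- 0L
  expect_equal(nrow(call_regions(wins, band, min_consecutive = 3)), 0)
})

test_that("band lookup uses the nearest simulated depth", {
  b <- null_band(depths = c(10, 40), n_reps = 300, seed = 9)
  expect_equal(unname(band_lookup(b, 12, 0.95)[, "upper"]),
               unname(b$upper["10", "0.95"]))
  expect_equal(unname(band_lookup(b, 39, 0.95)[, "upper"]),
               unname(b$upper["40", "0.95"]))
  expect_error(band_lookup(b, 40, 0.9), "level")
})

test_that("the scan recovers a causal locus end to end", {
  sim <- simulate(study_cross_model(seed = 31))
  fit <- bsa_scan(sim$sites, chrom_lengths = sim$model$chromosomes,
                  n_reps = 2000, seed = 31)
  truth <- sim$truth[sim$truth$is_causal, ]
  on_chr1 <- fit$regions[fit$regions$chrom == truth$chrom, ]
  expect_gte(nrow(on_chr1), 1)
  covered <- any(on_chr1$start <= truth$pos - 1 & truth$pos - 1 < on_chr1$end)
  expect_true(covered)
})
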