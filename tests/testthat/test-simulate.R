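test_that("brute force oracle is self-consistent on the worked example", {
  y <- c(0, 0, 0, 4, 4, 4)
  bf <- brute_force_pcf(y, gamma = 1)
  expect_equal(bf$start_indices, c(1L, 4L))
  expect_equal(bf$cost_prime, -46)
  expect_equal(bf$means, c(0, 4))
  # oracle cost is a lower bound over any segmentation we can write down
  for (starts in list(1, c(1, 2), c(1, 5), c(1, 3, 5))) {
    expect_lte(bf$cost_prime,
               criterion_value(y, starts, 1, form = "Lprime") + 1e-12)
  }
  expect_equal(brute_force_pcf(3.5, gamma = 1)$start_indices, 1L)
  expect_error(brute_force_pcf(rnorm(20), 1), "p <= 16")
})

test_that("generators are seed-reproducible and honour their specs", {
  a <- simulate_null(500, 3, seed = 19)
  b <- simulate_null(500, 3, seed = 19)
  expect_identical(a, b)
  expect_equal(length(a), 3)
  expect_equal(a[[1]]$truth$start_indices, 1L)
  # alpha = 1, d = 3 inflates the variance ninefold
  v1 <- var(simulate_null(2e4, contamination = contamination_spec(0, 3),
                          seed = 23)[[1]]$values)
  v9 <- var(simulate_null(2e4, contamination = contamination_spec(1, 3),
                          seed = 23)[[1]]$values)
  expect_equal(v1, 1, tolerance = 0.05)
  expect_equal(v9, 9, tolerance = 0.45)
  prof <- simulate_profile(data.frame(length = c(5, 5), level = c(0, 2)))
  expect_equal(prof$values, rep(c(0, 2), each = 5))   # zero noise is exact
  expect_equal(prof$truth$start_indices, c(1L, 6L))
  expect_error(simulate_profile(data.frame(length = 0, level = 1)), ">= 1")
})

test_that("SNP track generator encodes event types faithfully", {
  sim <- simulate_snp_tracks(
    data.frame(length = c(100, 100, 100, 100),
               type = c("balanced", "loss", "gain", "cnloh")),
    seed = 29, baf_sd = 0, hom_fraction = 0)
  tr <- sim$truth
  expect_equal(tr$baf_levels[1], 0.5)                       # balanced
  expect_equal(tr$logr_levels[1], 0)
  expect_lt(tr$logr_levels[2], 0)                           # loss
  expect_gt(tr$logr_levels[3], 0)                           # gain
  expect_equal(tr$logr_levels[4], 0)                        # cn-LOH: flat logR
  expect_lt(tr$baf_levels[4], 0.5)                          # ... shifted BAF
  expect_true(all(sim$baf >= 0 & sim$baf <= 1))
  expect_identical(sim,
                   simulate_snp_tracks(
                     data.frame(length = c(100, 100, 100, 100),
                                type = c("balanced", "loss", "gain", "cnloh")),
                     seed = 29, baf_sd = 0, hom_fraction = 0))
})

test_that("false call rate vanishes for huge penalties", {
  expect_equal(false_call_rate(1e4, p = 2000, n_seq = 3, seed = 37), 0)
})

test_that("tail fractions match the closed-form mixture computation", {
  # pure Gaussian: 0.27% beyond 3 SD, essentially nothing beyond 5 SD
  pure <- tail_fractions_analytic(contamination_spec(0, 1, 1))
  expect_equal(pure$pct_beyond_3sd, 0.27, tolerance = 0.01)
  expect_lt(pure$pct_beyond_5sd, 1e-4)
  mc <- tail_fractions(contamination_spec(0, 1, 1), n = 4e5, seed = 31)
  # Monte Carlo agrees with 2(1 - Phi(3)) within 3 binomial SEs
  se <- 100 * sqrt(0.0027 * (1 - 0.0027) / 4e5)
  expect_lt(abs(mc$pct_beyond_3sd - pure$pct_beyond_3sd), 3 * se)
  # contaminated mixture: scale estimate barely moves, tails inflate
  cont <- tail_fractions_analytic(contamination_spec(0.05, 3, 1))
  expect_equal(cont$pct_beyond_3sd, 1.67, tolerance = 0.01)
  expect_equal(cont$pct_beyond_5sd, 0.417, tolerance = 0.005)
  expect_lt(cont$s, 1.1)
})

test_that("the CLI drives simulate, pcf and bench end to end", {
  dir <- withr::local_tempdir()
  probes <- file.path(dir, "probes.tsv")
  run_pcfseg_cli(c("simulate", "--type", "null", "--p", "200",
                   "--n-seq", "2", "--seed", "7", "--out", probes))
  probes2 <- file.path(dir, "probes2.tsv")
  run_pcfseg_cli(c("simulate", "--type", "null", "--p", "200",
                   "--n-seq", "2", "--seed", "7", "--out", probes2))
  expect_identical(readLines(probes), readLines(probes2))  # seeded determinism
  segs <- file.path(dir, "seg.tsv")
  suppressMessages(
    run_pcfseg_cli(c("pcf", "--in", probes, "--gamma", "40",
                     "--whole-chrom", "--out", segs)))
  seg <- read_segments(segs)
  expect_equal(sum(seg$n.probes), 400)             # both samples covered
  # invalid parameters fail before producing output
  bad <- file.path(dir, "bad.tsv")
  expect_error(run_pcfseg_cli(c("pcf", "--in", probes, "--gamma", "-1",
                                "--out", bad)), "gamma")
  expect_false(file.exists(bad))
  # missing input file: error, no partial output
  expect_error(suppressWarnings(
    run_pcfseg_cli(c("pcf", "--in", file.path(dir, "nope.tsv"),
                     "--out", bad))))
  expect_false(file.exists(bad))
})
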