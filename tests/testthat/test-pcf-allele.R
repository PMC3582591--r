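test_that("BAF mirroring folds onto [0, 0.5] and is idempotent", {
  expect_equal(mirror_baf(c(0.7, 0.5, 0.2)), c(0.3, 0.5, 0.2))
  expect_true(is.na(mirror_baf(NA)))
  x <- runif(50)
  expect_equal(mirror_baf(mirror_baf(x)), mirror_baf(x))
  expect_true(all(mirror_baf(x) <= 0.5 & mirror_baf(x) >= 0))
  expect_error(mirror_baf(1.2), "\\[0, 1\\]")
})

test_that("homozygote filtering drops low mirrored BAF and NA", {
  expect_equal(filter_homozygous(c(0.05, 0.3, NA), 0.1),
               c(FALSE, TRUE, FALSE))
  expect_equal(filter_homozygous(c(0.05, 0.3, NA), 0),
               c(TRUE, TRUE, FALSE))
  expect_true(all(filter_homozygous(c(0.1, 0.2, 0.5), 0.1)))
  expect_error(filter_homozygous(0.3, 0.7), "0.5")
})

test_that("logR probes pair to the nearest retained BAF probe", {
  pair <- pair_logr_to_baf(c(10, 20, 30), c(1, 2, 6), c(12, 29), c(0.4, 0.3))
  expect_equal(pair$map, c(1L, 1L, 2L))           # |20-12| = 8 < |20-29| = 9
  expect_equal(pair$y2, c(1.5, 6))
  # single BAF probe absorbs all logR values
  one <- pair_logr_to_baf(c(1, 5, 9), c(2, 4, 6), 5, 0.5)
  expect_equal(one$y2, 4)
  # identical grids: identity pairing
  id <- pair_logr_to_baf(1:4, c(1, 2, 3, 4), 1:4, rep(0.5, 4))
  expect_equal(id$map, 1:4)
  expect_equal(id$y2, c(1, 2, 3, 4))
  # a BAF probe nearest to no logR probe borrows the closest logR value
  sparse <- pair_logr_to_baf(c(1, 100), c(5, 9), c(1, 50, 100), rep(0.4, 3))
  expect_equal(sparse$y2[2], 5)                    # 50 is nearer to 1 than 100
  expect_error(pair_logr_to_baf(1, 1, numeric(0), numeric(0)), "no retained")
})

test_that("aspcf finds the BAF-only event the joint criterion exists for", {
  set.seed(61)
  p <- 80
  pos <- seq_len(p)
  logr <- rnorm(p, sd = 0.05)                       # flat total copy number
  baf_level <- rep(c(0.5, 0.33), each = p / 2)      # allelic imbalance shift
  baf <- pmin(pmax(baf_level + rnorm(p, sd = 0.02), 0), 1)
  fit <- aspcf_track(pos, logr, pos, baf, gamma = 8, kmin = 2,
                     theta_baf = 0.1)
  expect_equal(fit$n_segments, 2)
  expect_equal(fit$start_indices[2], p / 2 + 1)
  # mirroring folds noise above 0.5 downwards, so the balanced segment's
  # mirrored mean sits at 0.5 - sd * sqrt(2/pi), not at 0.5 itself
  expect_equal(fit$means[, "BAF.mean"],
               c(0.5 - 0.02 * sqrt(2 / pi), 0.33), tolerance = 0.02)
  # breakpoints coincide across tracks by construction: one index set,
  # one row of start/end coordinates
  expect_equal(length(fit$start_pos), fit$n_segments)
})

test_that("aspcf on a duplicated logR track equals two-sample multipcf", {
  set.seed(67)
  y <- rep(c(0, 1), each = 15) + rnorm(30, sd = 0.1)
  b <- pmin(pmax(0.3 + 0 * y, 0), 1)               # constant mirrored BAF
  ref <- multipcf_exact(rbind(b, y), gamma = 5, kmin = 1, normalize = FALSE)
  fit <- aspcf_track(1:30, y, 1:30, b, gamma = 5, kmin = 1,
                     theta_baf = 0, normalize = FALSE)
  expect_identical(fit$start_indices, ref$start_indices)
  expect_equal(unname(fit$means), unname(ref$means), tolerance = 1e-12)
})

test_that("balanced diploid tracks yield a single segment", {
  sim <- simulate_snp_tracks(data.frame(length = 120, type = "balanced"),
                             noise = contamination_spec(0, 1, 0.1),
                             seed = 71)
  fit <- aspcf_track(sim$positions, sim$logr, sim$positions, sim$baf,
                     gamma = 40, kmin = 5)
  expect_equal(fit$n_segments, 1)
  expect_true(all(fit$pair$y1 >= 0 & fit$pair$y1 <= 0.5))
})

test_that("table-level aspcf reports per-arm segments in genomic
           coordinates", {
  sim <- simulate_snp_tracks(
    data.frame(length = c(60, 60), type = c("balanced", "cnloh")),
    noise = contamination_spec(0, 1, 0.1), seed = 73)
  logr_tab <- cn_table(rep("1", 120), sim$positions, cbind(s1 = sim$logr))
  baf_tab <- cn_table(rep("1", 120), sim$positions, cbind(s1 = sim$baf))
  seg <- aspcf(logr_tab, baf_tab, gamma = 15, kmin = 5, whole_chrom = TRUE)
  expect_true(all(c("logR.mean", "BAF.mean") %in% names(seg)))
  expect_equal(sum(seg$n.probes),
               sum(filter_homozygous(mirror_baf(sim$baf), 0.1)))
  expect_equal(nrow(seg), 2)
  # copy-neutral LOH: BAF level moves, logR stays near zero
  expect_lt(seg$BAF.mean[2], 0.4)
  expect_lt(abs(seg$logR.mean[2]), 0.15)
})
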