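test_that("criterion value matches hand arithmetic in both forms", {
  y <- c(0, 0, 0, 4, 4, 4)
  expect_equal(criterion_value(y, 1, gamma = 1), 24 + 1)
  expect_equal(criterion_value(y, c(1, 4), gamma = 1), 0 + 2)
  # the two forms differ by the constant sum(y^2), for any segmentation
  for (starts in list(1, c(1, 4), c(1, 2, 5))) {
    expect_equal(criterion_value(y, starts, 1) -
                   criterion_value(y, starts, 1, form = "Lprime"),
                 sum(y^2))
  }
  expect_error(criterion_value(y, c(2, 4), 1), "begin at 1")
})

test_that("pcf_exact solves the worked step-signal examples", {
  y <- c(0, 0, 0, 4, 4, 4)
  fit <- pcf_exact(y, gamma = 1)
  expect_equal(fit$start_indices, c(1L, 4L))
  expect_equal(fit$means, c(0, 4))
  expect_equal(fit$cost_prime, -48 + 2)
  # high penalty: single segment wins (24 + 30 beats 0 + 60)
  fit30 <- pcf_exact(y, gamma = 30)
  expect_equal(fit30$start_indices, 1L)
  expect_equal(fit30$means, 2)
  # constant input is never split
  expect_equal(pcf_exact(rep(1.7, 12), gamma = 0.01)$n_segments, 1)
  # kmin can forbid every split: p = 3, kmin = 2 leaves only one segment
  fitk <- pcf_exact(c(0, 4, 0), gamma = 0.1, kmin = 2)
  expect_equal(fitk$start_indices, 1L)
  expect_equal(fitk$means, 4 / 3)
  expect_error(pcf_exact(numeric(0), gamma = 1), "empty")
  expect_warning(pcf_exact(c(1, 2), gamma = 1, kmin = 5), "kmin")
})

test_that("vectorized recursion equals the naive double-loop reference", {
  set.seed(101)
  for (rep in 1:20) {
    y <- random_instance(sample(5:40, 1))
    gamma <- runif(1, 0.5, 20)
    dp <- pcfseg:::pcf_dp_core(y, rep(1L, length(y)), gamma)
    ref <- naive_dp_reference(y, gamma)
    expect_equal(dp$e, ref$e, tolerance = 1e-9)
    expect_identical(dp$t, ref$t)
  }
})

test_that("segment means are exact averages and segments partition probes", {
  set.seed(55)
  for (rep in 1:10) {
    y <- random_instance(sample(10:60, 1), "mixture")
    fit <- pcf_exact(y, gamma = runif(1, 1, 10), kmin = sample(1:3, 1))
    expect_equal(sum(fit$lengths), length(y))
    ends <- c(fit$start_indices[-1] - 1L, length(y))
    for (m in seq_along(fit$start_indices)) {
      expect_equal(fit$means[m], mean(y[fit$start_indices[m]:ends[m]]),
                   tolerance = 1e-10)
    }
  }
})

test_that("segment count decreases over the penalty grid with the step
           crossover at gamma = SSE of the merged fit", {
  y <- c(0, 0, 0, 4, 4, 4)
  # split cost 2*gamma vs merged cost 24 + gamma: crossover at gamma = 24
  prof <- pcf_profile_over_gamma(y, c(1, 10, 23.9, 24.1, 30, 1e4))
  expect_equal(prof$n_segments, c(2, 2, 2, 1, 1, 1))
  expect_true(all(diff(prof$n_segments) <= 0))
  expect_equal(pcf_profile_over_gamma(rep(2, 10), c(1, 5))$n_segments,
               c(1, 1))
  expect_error(pcf_profile_over_gamma(y, numeric(0)), "empty")
})

test_that("normalization makes the segmentation scale invariant", {
  set.seed(77)
  prof <- simulate_profile(
    data.frame(length = c(40, 30, 50), level = c(0, 1.5, -0.5)),
    noise = contamination_spec(0, 1, 0.3))
  y <- prof$values
  f1 <- pcf_exact(y, gamma = 15, normalize = TRUE)
  f2 <- pcf_exact(5 * y, gamma = 15, normalize = TRUE)
  expect_identical(f1$start_indices, f2$start_indices)
  expect_equal(f2$means, 5 * f1$means, tolerance = 1e-8)
})

test_that("table-level pcf recovers planted arm-wise segments", {
  set.seed(9)
  y1 <- simulate_profile(data.frame(length = c(30, 30), level = c(0, 2)),
                         noise = contamination_spec(0, 1, 0.2))$values
  y2 <- simulate_profile(data.frame(length = 25, level = -1),
                         noise = contamination_spec(0, 1, 0.2))$values
  tab <- cn_table(rep("1", 85), c(1:60, 2001:2025), c(y1, y2))
  seg <- pcf(tab, gamma = 12, kmin = 5, normalize = TRUE,
             centromeres = data.frame(chrom = "1", centromere_pos = 1000))
  expect_equal(seg$arm, c("p", "p", "q"))
  expect_equal(seg$start.pos, c(1, 31, 2001))
  expect_equal(seg$end.pos, c(30, 60, 2025))
  expect_equal(sum(seg$n.probes), 85)
  expect_equal(seg$mean, c(0, 2, -1), tolerance = 0.15)
})
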