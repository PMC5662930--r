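test_that("evidence equals the enumeration log-sum-exp and bounds the optimum", {
  set.seed(31)
  for (rep in 1:8) {
    T <- sample(8:12, 1)
    J <- sample(1:3, 1)
    ml <- 2
    p <- random_profile(T)
    bf <- oracle_posteriors(p$positions, p$lengths, J, ml)
    ev <- log_evidence(p, J, min_len = ml)
    expect_equal(as.numeric(ev), bf$evidence, tolerance = 1e-9)
    opt <- optimal_segmentation(p, J, min_len = ml)
    expect_gte(as.numeric(ev), opt$log_likelihood - 1e-12)
  }
})

test_that("segmentation posteriors are normalized likelihood shares", {
  set.seed(32)
  p <- random_profile(10)
  ev <- log_evidence(p, 2, min_len = 2)
  bf <- oracle_posteriors(p$positions, p$lengths, 2, 2)
  tops <- top_segmentations(p, 2, N = length(bf$lls), min_len = 2)
  posts <- vapply(tops, segmentation_posterior, numeric(1), log_evidence = ev)
  expect_equal(posts, sort(bf$weights, decreasing = TRUE), tolerance = 1e-9)
  expect_lte(sum(posts), 1 + 1e-9)
  # a unique feasible segmentation has posterior 1
  q <- random_profile(8)
  seg <- optimal_segmentation(q, 2, min_len = 4)
  expect_equal(segmentation_posterior(seg, log_evidence(q, 2, min_len = 4)), 1)
  # mismatched J is a contract error
  expect_error(segmentation_posterior(seg, log_evidence(q, 1, min_len = 4)),
               "J = 1")
})

test_that("zone occupancy matches enumeration, rows sum to 1, endpoints pinned", {
  set.seed(33)
  for (rep in 1:8) {
    T <- sample(8:12, 1)
    J <- sample(2:3, 1)
    ml <- 2
    p <- random_profile(T)
    occ <- zone_occupancy_profiles(p, J, min_len = ml)
    bf <- oracle_posteriors(p$positions, p$lengths, J, ml)
    expect_equal(occ, bf$occupancy, tolerance = 1e-9)
    expect_equal(rowSums(occ), rep(1, T), tolerance = 1e-9)
    expect_equal(occ[1, ], c(1, rep(0, J - 1)))
    expect_equal(occ[T, ], c(rep(0, J - 1), 1))
  }
})

test_that("change-point posteriors match enumeration and respect feasibility", {
  set.seed(34)
  for (rep in 1:8) {
    T <- sample(9:12, 1)
    J <- sample(2:3, 1)
    ml <- 3
    p <- random_profile(T)
    bf <- oracle_posteriors(p$positions, p$lengths, J, ml)
    for (j in seq_len(J - 1)) {
      cp <- changepoint_posterior(p, J, min_len = ml, j = j)
      expect_equal(cp, bf$changepoints[[j]], tolerance = 1e-9)
      expect_equal(sum(cp), 1, tolerance = 1e-9)
      # support excludes indices violating min_len on either side
      expect_true(all(cp[seq_len(j * ml)] == 0))
      expect_true(all(cp[seq.int(T - (J - j) * ml + 2, T)] == 0))
    }
  }
})

test_that("max-type profiles match enumeration and are bounded by occupancy", {
  set.seed(35)
  for (rep in 1:6) {
    T <- sample(8:12, 1)
    J <- sample(2:3, 1)
    p <- random_profile(T)
    pr <- segmentation_probability_profiles(p, J, min_len = 2)
    bf <- oracle_posteriors(p$positions, p$lengths, J, 2)
    expect_equal(pr, bf$profiles, tolerance = 1e-9)
    occ <- zone_occupancy_profiles(p, J, min_len = 2)
    expect_true(all(pr <= occ + 1e-9))
  }
  # a unique feasible segmentation gives 0/1 indicators
  q <- random_profile(8)
  pr <- segmentation_probability_profiles(q, 2, min_len = 4)
  expect_equal(pr, cbind(c(rep(1, 4), rep(0, 4)), c(rep(0, 4), rep(1, 4))))
})

test_that("uncertainty intervals grow greedily toward mass and honor coverage", {
  d <- numeric(20)
  d[10] <- 1
  expect_equal(uncertainty_interval(d, 10, 0.5)[c("lo", "hi")],
               list(lo = 10L, hi = 10L))
  d2 <- numeric(20)
  d2[10:12] <- c(0.5, 0.3, 0.2)
  ui <- uncertainty_interval(d2, 10, 0.75)
  expect_equal(c(ui$lo, ui$hi), c(10L, 11L))
  # exhaustive check: [10,11] is the smallest contiguous superset with
  # mass >= 0.75 containing the MAP
  ui_full <- uncertainty_interval(d2, 10, 1.0)
  expect_equal(c(ui_full$lo, ui_full$hi), c(10L, 12L))
  expect_error(uncertainty_interval(d2, 10, 1.5), "coverage")
  expect_error(uncertainty_interval(d2, 5, 0.9), "support")
})

test_that("posterior summary intervals contain the optimal change points", {
  set.seed(36)
  for (rep in 1:5) {
    g <- generate_profile(profile_spec(list(
      zone_spec("DZ", 150, 6, 0, 1.5),
      zone_spec("EZ", 200, 6 - 60e-3 * 150, 60, 4),
      zone_spec("MZ", 250, 18 - 10e-3 * 350, 10, 9)),
      n_files = 1, seed = 360 + rep))
    ps <- posterior_summary(g$profile, 3)
    for (j in 1:2) {
      ui <- ps$uncertainty_intervals[[j]]
      expect_gte(ps$segmentation$change_points[j], ui$lo)
      expect_lte(ps$segmentation$change_points[j], ui$hi)
    }
    expect_gt(ps$optimal_posterior, 0)
    expect_lte(ps$optimal_posterior, 1)
  }
})

test_that("posteriors concentrate as the noise vanishes", {
  # zone lines with value jumps at the limits: every cell then belongs
  # unambiguously to one zone once the noise is small (with continuous
  # lines the boundary cells genuinely fit both zones and the posterior
  # stays split however small the noise)
  make <- function(sd_scale, seed) {
    generate_profile(profile_spec(list(
      zone_spec("DZ", 150, 6, 0, 1.5 * sd_scale),
      zone_spec("EZ", 200, 12 - 60e-3 * 150, 60, 4 * sd_scale),
      zone_spec("MZ", 250, 50 - 10e-3 * 350, 10, 9 * sd_scale)),
      n_files = 1, seed = seed))
  }
  post_of <- function(sd_scale) {
    g <- make(sd_scale, 37)
    posterior_summary(g$profile, 3)
  }
  noisy <- post_of(1)
  crisp <- post_of(0.02)
  expect_gt(crisp$optimal_posterior, noisy$optimal_posterior)
  width <- function(ps) sum(vapply(ps$uncertainty_intervals,
                                   function(u) u$hi - u$lo, numeric(1)))
  expect_lte(width(crisp), width(noisy))
  expect_gt(crisp$optimal_posterior, 0.9)
  expect_equal(width(crisp), 0)
})

test_that("tidy export lays profiles out one row per cell and zone", {
  g <- generate_profile(spec_arrested(seed = 5, n_files = 1))
  ps <- posterior_summary(g$profile, 1)
  td <- tidy_posterior_profiles(ps, g$profile$positions)
  expect_equal(nrow(td), g$profile$T)
  expect_named(td, c("cell_index", "position_um", "zone", "occupancy",
                     "segmentation_probability"))
})
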