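test_that("fit_segment matches the closed-form OLS solution", {
  p <- cell_profile(c(0, 1, 2), c(1, 2, 4))
  f <- fit_segment(p, 1, 3, min_len = 3)
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, 5 / 6)
  expect_equal(f$rss, 1 / 6)
  # against lm()
  lmf <- lm(x ~ p, data.frame(p = p$positions, x = p$lengths))
  expect_equal(f$slope, unname(coef(lmf)[2]), tolerance = 1e-12)
  expect_equal(f$log_likelihood,
               -3 / 2 * (log(2 * pi * f$rss / 3) + 1), tolerance = 1e-12)
})

test_that("collinear segments are floored and flagged degenerate", {
  p <- cell_profile(c(0, 1, 2), c(1, 2, 3))
  f <- fit_segment(p, 1, 3, min_len = 3)
  expect_equal(f$rss, 0)
  expect_true(f$degenerate)
  expect_equal(f$residual_sd, sqrt(1e-6))
})

test_that("infeasible or degenerate segments error", {
  p <- cell_profile(1:10, rep(2, 10))
  expect_error(fit_segment(p, 3, 3, min_len = 3), "infeasible")
  tied <- cell_profile(rep(5, 4), c(1, 2, 3, 4))
  expect_error(fit_segment(tied, 1, 4, min_len = 3), "slope undefined")
})

test_that("J = 1 optimum is the single full-range fit", {
  set.seed(21)
  p <- random_profile(15)
  seg <- optimal_segmentation(p, 1)
  f <- fit_segment(p, 1, 15)
  expect_equal(seg$J, 1L)
  expect_equal(seg$log_likelihood, f$log_likelihood)
  expect_length(seg$change_points, 0)
})

test_that("dynamic programming equals exhaustive enumeration on small series", {
  set.seed(22)
  for (rep in 1:15) {
    T <- sample(8:14, 1)
    J <- sample(2:3, 1)
    ml <- sample(2:3, 1)
    if (J * ml > T) next
    p <- random_profile(T)
    bf <- sapply(enum_segmentations(T, J, ml),
                 function(cp) oracle_loglik(p$positions, p$lengths, cp))
    seg <- optimal_segmentation(p, J, min_len = ml)
    expect_equal(seg$log_likelihood, max(bf), tolerance = 1e-9)
  }
})

test_that("noiseless three-piece series is recovered at construction boundaries", {
  g <- generate_profile(profile_spec(list(
    zone_spec("DZ", 200, 6, 0, 0),
    zone_spec("EZ", 300, 6 - 60e-3 * 200, 60, 0),
    zone_spec("MZ", 400, 24 - 10e-3 * 500, 10, 0)), n_files = 1, seed = 1))
  seg <- optimal_segmentation(g$profile, 3)
  # the drawn length switches regime when the rootward edge crosses the
  # boundary, so the detected change point is the first cell whose edge
  # lies shootward of the construction limit
  edges <- g$profile$positions - g$profile$lengths / 2
  truth_idx <- vapply(g$truth$limits_um, function(L)
    which(edges >= L - 1e-9)[1], integer(1))
  expect_equal(seg$change_points, truth_idx)
})

test_that("optimal log-likelihood is nondecreasing in J", {
  set.seed(23)
  p <- random_profile(30)
  lls <- vapply(1:5, function(J)
    optimal_segmentation(p, J, min_len = 4)$log_likelihood, numeric(1))
  expect_true(all(diff(lls) >= -1e-9))
})

test_that("top-N ranking matches brute force and saturates without padding", {
  set.seed(24)
  p <- random_profile(10)
  bf <- sapply(enum_segmentations(10, 2, 2),
               function(cp) oracle_loglik(p$positions, p$lengths, cp))
  tops <- top_segmentations(p, 2, N = length(bf) + 10, min_len = 2)
  expect_length(tops, length(bf))          # saturation, no padding
  got <- vapply(tops, `[[`, numeric(1), "log_likelihood")
  expect_equal(got, sort(bf, decreasing = TRUE), tolerance = 1e-9)
  expect_true(all(diff(got) <= 1e-12))     # strictly ordered
  # first element is the optimum
  opt <- optimal_segmentation(p, 2, min_len = 2)
  expect_equal(tops[[1]]$change_points, opt$change_points)
  one <- top_segmentations(p, 2, N = 1, min_len = 2)
  expect_length(one, 1)
  expect_equal(one[[1]]$change_points, opt$change_points)
})

test_that("piecewise evaluation uses the shootward segment at a limit", {
  p <- cell_profile(c(seq(10, 80, by = 10), seq(100, 170, by = 10)),
                    c(rep(5, 8), rep(15, 8)))
  seg <- optimal_segmentation(p, 2)
  expect_equal(seg$limit_positions, 100)
  expect_equal(evaluate_piecewise(seg, 99.9), 5, tolerance = 1e-9)
  expect_equal(evaluate_piecewise(seg, 100), 15, tolerance = 1e-9)
  expect_error(evaluate_piecewise(seg, -5), "outside")
  expect_error(evaluate_piecewise(seg, 1e4), "outside")
})

test_that("jumps at limits carry the shootward-minus-rootward sign", {
  pos <- 1:20
  p1 <- cell_profile(pos, ifelse(pos <= 10, pos, pos + 11.1))
  s1 <- optimal_segmentation(p1, 2)
  expect_equal(jump_at_limit(s1, 1), 11.1, tolerance = 1e-6)
  p2 <- cell_profile(pos, ifelse(pos <= 10, 50, 5.3))
  s2 <- optimal_segmentation(p2, 2)
  expect_equal(jump_at_limit(s2, 1), -44.7, tolerance = 1e-6)
  # continuous construction has zero jump
  p3 <- cell_profile(pos, pos + 1)
  expect_error(jump_at_limit(optimal_segmentation(p3, 1), 1), "out of range")
})
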