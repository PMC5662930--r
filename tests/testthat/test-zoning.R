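make_two_piece <- function(slopes_per_mm, sds, spans = c(400, 800),
                           start = 10, seed = 1) {
  b1 <- slopes_per_mm[1] / 1000
  y_mid <- start + b1 * spans[1]
  generate_profile(profile_spec(list(
    zone_spec("Z1", spans[1], start, slopes_per_mm[1], sds[1]),
    zone_spec("Z2", spans[2], y_mid - slopes_per_mm[2] / 1000 * spans[1],
              slopes_per_mm[2], sds[2])),
    n_files = 1, seed = seed))$profile
}

test_that("slope tests mirror the n.s. annotations", {
  set.seed(61)
  pos <- seq(0, 580, by = 20)
  steep <- cell_profile(pos, 5 + 0.1 * pos + rnorm(30, 0, 0.01))
  f <- fit_segment(steep, 1, 30)
  s <- slope_significant(f)
  expect_true(s$significant)
  expect_lt(s$p_value, 1e-10)
  # type-I error control on flat noisy segments
  rejections <- vapply(1:25, function(i) {
    set.seed(6100 + i)
    p <- cell_profile(pos, pmax(10 + rnorm(30, 0, 1), 0.5))
    slope_significant(fit_segment(p, 1, 30), 0.05)$significant
  }, logical(1))
  expect_gte(mean(!rejections), 0.9)
  # degenerate: collinear with zero residual df
  col3 <- cell_profile(c(0, 1, 2), c(1, 2, 3))
  expect_error(slope_significant(fit_segment(col3, 1, 3, min_len = 3)),
               "undefined")
})

test_that("zone labels follow the cell-length reading of segments", {
  cfg <- zoning_config()
  # one segment: mature zone
  g1 <- generate_profile(spec_arrested(seed = 62, n_files = 1))
  l1 <- label_zones(optimal_segmentation(g1$profile, 1), cfg)
  expect_equal(l1$labels, "MZ")
  # steep significant first slope then shallow: EZ + MZ
  p2 <- make_two_piece(c(120, 10), c(3, 12), seed = 63)
  l2 <- label_zones(optimal_segmentation(p2, 2), cfg)
  expect_equal(l2$labels, c("EZ", "MZ"))
  expect_true(is.na(l2$diagnosis))
  # flat small-cell first segment: DZ + MZ, elongation zone missing
  p3 <- make_two_piece(c(0, 2), c(1.5, 14), start = 6, seed = 64)
  l3 <- label_zones(optimal_segmentation(p3, 2), cfg)
  expect_equal(l3$labels, c("DZ", "MZ"))
  expect_equal(l3$diagnosis, "EZ-missing")
  # three clear zones label positionally with no diagnosis
  g4 <- generate_profile(spec_vigorous(seed = 65))
  l4 <- label_zones(optimal_segmentation(g4$profile, 3), cfg)
  expect_equal(l4$labels, c("DZ", "EZ", "MZ"))
  expect_true(is.na(l4$diagnosis))
  # more than four segments is unsupported
  expect_error(label_zones(optimal_segmentation(g4$profile, 5), cfg),
               "unsupported")
})

test_that("continuity intervals equal the lm() conditional-mean intervals", {
  set.seed(66)
  p <- make_two_piece(c(60, 20), c(2, 8), seed = 66)
  seg <- optimal_segmentation(p, 2)
  ci <- continuity_intervals(seg, 1, level = 0.95)
  x0 <- seg$limit_positions[1]
  for (side in 1:2) {
    f <- seg$fits[[side]]
    d <- data.frame(p = p$positions[f$start:f$end],
                    x = p$lengths[f$start:f$end])
    lmf <- lm(x ~ p, d)
    pred <- predict(lmf, newdata = data.frame(p = x0),
                    interval = "confidence", level = 0.95)
    got <- if (side == 1) ci$rootward else ci$shootward
    expect_equal(got, unname(pred[1, c("lwr", "upr")]), tolerance = 1e-9)
    # midpoint is the fitted value at the limit
    expect_equal(mean(got), unname(pred[1, "fit"]), tolerance = 1e-9)
  }
  # monotone in the confidence level
  wide <- continuity_intervals(seg, 1, level = 0.99)
  expect_lt(wide$rootward[1], ci$rootward[1])
  expect_gt(wide$rootward[2], ci$rootward[2])
})

test_that("continuity overlap reproduces the published examples", {
  expect_true(continuity_overlap(c(15.7, 20.9), c(17.7, 34.4)))
  expect_false(continuity_overlap(c(8.3, 9.6), c(2.7, 6.8)))
  expect_true(continuity_overlap(c(0, 1), c(1, 2)))
})

test_that("the pipeline keeps the optimal segmentation on clear profiles", {
  g <- generate_profile(spec_vigorous(seed = 67))
  z <- select_final_segmentation(g$profile)
  expect_s3_class(z, "zoned_root")
  expect_equal(z$labels, c("DZ", "EZ", "MZ"))
  expect_true(all(diff(z$limits$position_um) > 0))
  # the meristem end is pinned sharply; the elongation-mature limit drifts
  # with the large mature-zone dispersion
  expect_lt(abs(z$limits$position_um[1] - g$truth$limits_um[1]), 100)
  expect_lt(abs(z$limits$position_um[2] - g$truth$limits_um[2]), 300)
})

test_that("a sparse high-variance mature zone triggers exploration one zone up", {
  # short MZ with few large dispersed cells: the slope heuristic tends to
  # merge EZ and MZ; the pipeline must still deliver the three zones
  spec3 <- function(seed) profile_spec(list(
    zone_spec("DZ", 500, 6, 0, 1.4),
    zone_spec("EZ", 600, 6 - 70e-3 * 500, 70, 6),
    zone_spec("MZ", 1200, 48 - 8e-3 * 1100, 8, 30)),
    n_files = 1, seed = seed)
  out <- lapply(1:10, function(i)
    select_final_segmentation(generate_profile(spec3(6700 + i))$profile))
  labs <- vapply(out, function(z) paste(z$labels, collapse = "-"),
                 character(1))
  expect_gte(mean(labs == "DZ-EZ-MZ"), 0.7)
  expect_true(all(vapply(out, function(z)
    z$provenance$source %in% c("optimal", "J+1 model", "alternative"),
    logical(1))))
})

test_that("zone order and determinism hold over randomized profiles", {
  set.seed(68)
  order_ok <- function(labs) {
    ranks <- match(labs, c("DZ", "TZ", "EZ", "MZ"))
    all(diff(ranks) > 0) && labs[length(labs)] == "MZ"
  }
  for (i in 1:25) {
    zones <- list(zone_spec("MZ", 800, 20 + runif(1, 0, 20), runif(1, 5, 30),
                            runif(1, 8, 16)))
    if (runif(1) < 0.6)
      zones <- c(list(zone_spec("EZ", runif(1, 250, 500), 5, runif(1, 40, 120),
                                runif(1, 3, 7))), zones)
    if (length(zones) == 2 && runif(1) < 0.7)
      zones <- c(list(zone_spec("DZ", runif(1, 200, 600), 6, 0, 1.4)), zones)
    # stitch intercepts so zone lines meet approximately
    start <- 0
    for (k in seq_along(zones)) {
      z <- zones[[k]]
      prev_end <- if (k == 1) z$intercept_um else
        zones[[k - 1]]$intercept_um +
          zones[[k - 1]]$slope_per_mm / 1000 * start
      zones[[k]]$intercept_um <- prev_end - z$slope_per_mm / 1000 * start
      start <- start + z$span_um
    }
    g <- generate_profile(profile_spec(zones, n_files = 1, seed = 6800 + i))
    z1 <- select_final_segmentation(g$profile)
    expect_true(order_ok(z1$labels))
    z2 <- select_final_segmentation(g$profile)
    expect_identical(z1$labels, z2$labels)
    expect_identical(z1$segmentation$change_points,
                     z2$segmentation$change_points)
  }
})

test_that("hair matching uses the limit and its uncertainty interval", {
  zoned <- structure(list(
    labels = c("DZ", "EZ", "MZ"),
    limits = data.frame(limit = 1:2, position_um = c(323, 744),
                        lo_um = c(16, 388), hi_um = c(347, 828))),
    class = "zoned_root")
  expect_true(hair_match(zoned, 485))    # rootward of the limit
  expect_true(hair_match(zoned, 744))    # exactly at the limit
  expect_true(hair_match(zoned, 800))    # inside the interval
  expect_false(hair_match(zoned, 900))
  z2 <- structure(list(labels = c("DZ", "EZ"), limits = zoned$limits),
                  class = "zoned_root")
  mz_only <- structure(list(labels = "MZ",
                            limits = zoned$limits[0, ]),
                       class = "zoned_root")
  expect_true(is.na(hair_match(mz_only, 500)))
  a38 <- structure(list(labels = c("DZ", "EZ", "MZ"),
                        limits = data.frame(limit = 1:2,
                                            position_um = c(272, 505),
                                            lo_um = c(267, 426),
                                            hi_um = c(322, 505))),
                   class = "zoned_root")
  expect_false(hair_match(a38, 563))
})

test_that("zoned reports serialize the zones and limits", {
  g <- generate_profile(spec_vigorous(seed = 69))
  z <- select_final_segmentation(g$profile)
  rep <- as_zoned_report(z)
  expect_length(rep$zones, length(z$labels))
  expect_length(rep$limits, length(z$labels) - 1)
  expect_equal(rep$zones[[1]]$label, "DZ")
  expect_equal(rep$limits[[1]]$position_um, z$limits$position_um[1])
})
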