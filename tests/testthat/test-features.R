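test_that("static videos give zero motion features", {
  v <- video_sequence(array(8000, dim = c(20, 20, 15)), 30, 1)
  f <- extract_features(v, c(10, 10))
  expect_equal(f[["sad_density"]], 0)
  expect_equal(f[["temporal_sd"]], 0)
  expect_equal(f[["lag1_autocorr"]], 0)
  expect_error(extract_features(v, c(25, 10)), "outside")
  expect_error(extract_features(v, c(5, 5), window = 4), "odd")
})

test_that("temporal_sd and lag-1 autocorrelation match direct recomputation", {
  set.seed(8)
  series <- round(5000 + cumsum(rnorm(40, sd = 60)))
  fr <- array(0, dim = c(15, 15, 40))
  for (t in 1:40) fr[, , t] <- series[t] # whole frame = the stored sequence
  v <- video_sequence(fr, 30, 1)
  f <- extract_features(v, c(7, 7), window = 7)
  expect_equal(f[["temporal_sd"]], sd(series))
  expect_equal(f[["lag1_autocorr"]], cor(series[-40], series[-1]))
  expect_equal(f[["sad_density"]], sum(abs(diff(series))) / 39)
})

test_that("perfused-vessel locations dominate every background location", {
  scene <- straight_vessel_scene()
  v <- scene$video
  d <- dim(v$frames)
  mid <- c((d[1] - 1) %/% 2, (d[2] - 1) %/% 2) # on the vessel centerline
  f_vessel <- extract_features(v, mid)
  # background probes far away from the tube, same noise-free scene
  set.seed(4)
  bg_rows <- sample(c(2:(d[1] / 4), (3 * d[1] / 4):(d[1] - 2)), 15)
  bg_cols <- sample(2:(d[2] - 2), 15)
  for (i in 1:15) {
    f_bg <- extract_features(v, c(bg_rows[i], bg_cols[i]))
    expect_gt(f_vessel[["sad_density"]], f_bg[["sad_density"]])
  }
})

test_that("classify_flow implements the two-threshold rule and the policy interface", {
  pol <- threshold_policy(10, 5)
  zero <- c(sad_density = 0, temporal_sd = 0, lag1_autocorr = 0)
  expect_false(classify_flow(zero, pol))
  expect_true(classify_flow(c(sad_density = 1e4, temporal_sd = 1e3, lag1_autocorr = 0.9), pol))
  # one criterion alone is not enough
  expect_false(classify_flow(c(sad_density = 1e4, temporal_sd = 0, lag1_autocorr = 0), pol))
  expect_error(classify_flow(c(sad_density = NaN, temporal_sd = 0, lag1_autocorr = 0), pol), "finite")
  expect_error(classify_flow(zero, "otsu"), "policy")
  lenient <- custom_policy(function(f) f[["sad_density"]] > 0, label = "any-motion")
  expect_true(classify_flow(c(sad_density = 0.1, temporal_sd = 0, lag1_autocorr = 0), lenient))
})

test_that("calibrated classifier recovers a half-perfused scene from ground truth", {
  cfg <- sim_config(fov_extent_um = c(360, 240) * 0.78, duration_s = 5,
                    n_segments = 20, seed = 301L)
  net <- assign_perfusion(generate_network(cfg), 0.5, seed = 302L)
  scene <- render_video(net, cfg)
  v <- scene$video
  shape <- dim(v$frames)[1:2]
  # intersections of the full ground-truth skeleton (perfused or not)
  sk <- rasterize_centerlines(net, shape, cfg$pixel_size_um)
  recs <- find_intersections(sk, make_grid(shape))
  expect_gt(nrow(recs), 20)
  pol <- calibrate_policy(v, scene$ground_truth$vessel_mask)
  flow <- vapply(seq_len(nrow(recs)), function(i) {
    classify_flow(extract_features(v, c(recs$row[i], recs$col[i])), pol)
  }, logical(1))
  expect_lt(abs(mean(flow) - 0.5), 0.1)
})
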