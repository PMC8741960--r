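test_that("fully static scenes and static silhouettes give index 0", {
  # silhouettes only: vessels visible in single frames, no RBC motion
  cfg <- tiny_config()
  net <- assign_perfusion(generate_network(cfg), 0, seed = 3)
  scene <- render_video(net, cfg)
  res <- perfusion_index(scene$video)
  expect_equal(res$index, 0)
  # and with no noise either, there are no intersections at all
  cfg0 <- tiny_config(noise_sd = 0)
  scene0 <- render_video(assign_perfusion(generate_network(cfg0), 0, seed = 3), cfg0)
  res0 <- perfusion_index(scene0$video)
  expect_equal(nrow(res0$intersections), 0)
  expect_equal(res0$index, 0)
})

test_that("noise-free index equals the ground-truth crossing count", {
  cfg <- sim_config(fov_extent_um = c(240, 150) * 0.78, duration_s = 2,
                    noise_sd = 0, seed = 41L)
  # three disjoint full-width vessels between the grid rows
  ps <- cfg$pixel_size_um
  W <- cfg$fov_extent_um[1]
  ys <- (c(34, 75, 116) + 0.5) * ps
  net <- manual_network(lapply(ys, function(y) cbind(c(0, W), c(y, y))),
                        fov_extent_um = cfg$fov_extent_um)
  scene <- render_video(net, cfg)
  res <- perfusion_index(scene$video)
  ei <- expected_index(scene$ground_truth, res$grid, ps)
  expect_equal(ei, 30L)
  expect_equal(res$index, ei)
  expect_equal(res$index, nrow(res$intersections))
  # provenance: all flow-positive records sit on the segmentation mask
  on_mask <- mapply(function(r, c) res$segmentation$mask[r + 1, c + 1],
                    res$intersections$row, res$intersections$col)
  expect_true(all(on_mask[res$intersections$flow]))
})

test_that("the index is invariant under global intensity scaling", {
  cfg <- tiny_config(n_segments = 6, seed = 51L)
  scene <- render_video(assign_perfusion(generate_network(cfg), 0.6, seed = 52L), cfg)
  v <- scene$video
  res1 <- perfusion_index(v)
  v_scaled <- video_sequence(v$frames * 2.5, v$frame_rate, v$pixel_size,
                             v$fov_id, v$timepoint)
  res2 <- perfusion_index(v_scaled)
  expect_equal(res2$index, res1$index)
  expect_equal(res2$intersections[c("axis", "line_index", "row", "col", "flow")],
               res1$intersections[c("axis", "line_index", "row", "col", "flow")])
})

test_that("series registration recovers planted drift and keeps the index", {
  cfg <- sim_config(fov_extent_um = c(200, 140) * 0.78, duration_s = 3,
                    noise_sd = 100, seed = 61L)
  # vessels keep an 8-px margin so the planted drift loses no scene content
  ps <- cfg$pixel_size_um
  W <- cfg$fov_extent_um[1]
  net <- manual_network(
    lapply(c(35, 70, 105), function(r) {
      cbind(c(8 * ps, W - 8 * ps), rep((r + 0.5) * ps, 2))
    }),
    fov_extent_um = cfg$fov_extent_um
  )
  base <- render_video(net, cfg, timepoint = "baseline")$video
  drifted <- render_video(net, cfg, drift_px = c(4, -2), timepoint = "hd_1h")$video
  ts <- series_index(list(base, drifted))
  expect_equal(ts$table$offset_rows, c(0, 4))
  expect_equal(ts$table$offset_cols, c(0, -2))
  expect_equal(ts$table$index[2], ts$table$index[1])

  # single timepoint: trivial offsets and one index
  ts1 <- series_index(list(base))
  expect_equal(nrow(ts1$table), 1L)
  expect_equal(unname(unlist(ts1$table[1, c("offset_rows", "offset_cols")])), c(0, 0))
})

test_that("halving the perfused fraction lowers the index", {
  cfg <- sim_config(fov_extent_um = c(240, 160) * 0.78, duration_s = 3,
                    n_segments = 10, seed = 71L)
  net <- generate_network(cfg)
  full <- render_video(assign_perfusion(net, 1.0, seed = 72L), cfg,
                       timepoint = "baseline")$video
  half <- render_video(assign_perfusion(net, 0.5, seed = 72L), cfg,
                       timepoint = "hd_2h", seed = cfg$seed + 1L)$video
  ts <- series_index(list(full, half))
  expect_lt(ts$table$index[2], ts$table$index[1])
})

test_that("unknown quantification parameters are rejected", {
  expect_error(perfusion_index(straight_vessel_scene()$video,
                               params = list(bogus = 1)), "unknown parameter")
})
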