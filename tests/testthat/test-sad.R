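make_video <- function(frames, fps = 30, ps = 1) {
  video_sequence(frames, frame_rate = fps, pixel_size = ps)
}

test_that("compute_sad matches its definition on constructed videos", {
  # constant video -> SAD identically zero
  v <- make_video(array(1234, dim = c(6, 7, 10)))
  s <- compute_sad(v)
  expect_true(all(s$values == 0))
  expect_equal(s$n_pairs, 9L)

  # two frames, one pixel 1000 -> 1300
  fr <- array(1000, dim = c(5, 5, 2))
  fr[3, 3, 2] <- 1300
  s <- compute_sad(make_video(fr))
  expect_equal(s$values[3, 3], 300)
  expect_equal(sum(s$values), 300)

  # signed arithmetic: a decreasing step must not wrap
  fr2 <- array(60000, dim = c(2, 2, 2))
  fr2[1, 1, 2] <- 10
  expect_equal(compute_sad(make_video(fr2))$values[1, 1], 59990)

  expect_error(compute_sad(make_video(array(5, dim = c(3, 3, 1)))), "insufficient")
  expect_error(compute_sad(make_video(array(5, dim = c(3, 3, 4))), step = 4), "insufficient")
})

test_that("compute_sad equals the naive triple-loop oracle on seeded videos", {
  set.seed(77)
  for (rep in 1:6) {
    d <- c(sample(8:24, 1), sample(8:24, 1), sample(5:20, 1))
    fr <- array(sample.int(65535, prod(d), replace = TRUE) - 1L, dim = d)
    step <- sample(1:2, 1)
    if (d[3] <= step) next
    s <- compute_sad(make_video(fr), step = step)
    expect_identical(s$values, naive_sad(fr, step))
  }
})

test_that("SAD algebraic properties: reversal, linearity, concatenation", {
  set.seed(5)
  d <- c(9, 11, 8)
  fr <- array(runif(prod(d), 0, 65535), dim = d)
  v <- make_video(fr)
  s <- compute_sad(v)
  # temporal reversal
  expect_equal(compute_sad(make_video(fr[, , d[3]:1]))$values, s$values)
  # positive scaling
  expect_equal(compute_sad(make_video(0.5 * fr))$values, 0.5 * s$values)
  # concatenation through a shared frame
  fr2 <- array(runif(9 * 11 * 6, 0, 65535), dim = c(9, 11, 6))
  fr2[, , 1] <- fr[, , d[3]]
  joined <- array(c(fr, fr2[, , -1]), dim = c(9, 11, d[3] + 5))
  expect_equal(compute_sad(make_video(joined))$values,
               s$values + compute_sad(make_video(fr2))$values)
})

test_that("normalize_sad divides by n_pairs and is idempotent", {
  fr <- array(0, dim = c(4, 4, 60))
  fr[2, 2, ] <- rep(c(0, 59), 30) # |diff| = 59 per pair
  s <- compute_sad(make_video(fr))
  expect_equal(s$n_pairs, 59L)
  n1 <- normalize_sad(s)
  expect_equal(n1$values[2, 2], 59)
  expect_equal(n1$n_pairs, 1L)
  expect_equal(normalize_sad(n1), n1)
})

test_that("apply_offset shifts, NA-fills, and inverts on the overlap", {
  m <- matrix(as.numeric(1:30), 5, 6)
  s <- sad_image_for_test(m)
  expect_equal(apply_offset(s, c(0, 0))$values, m)
  sh <- apply_offset(s, c(2, 1))
  # index arithmetic on the counting pattern
  expect_equal(sh$values[3:5, 2:6], m[1:3, 1:5])
  expect_true(all(is.na(sh$values[1:2, ])))
  expect_true(all(is.na(sh$values[, 1])))
  back <- apply_offset(sh, c(-2, -1))
  expect_equal(back$values[1:3, 1:5], m[1:3, 1:5])
  expect_error(apply_offset(s, c(9, 0)), "smaller")
})

test_that("register_translation recovers planted shifts exactly", {
  set.seed(12)
  base <- matrix(0, 40, 50)
  base[cbind(sample(5:35, 60, TRUE), sample(5:45, 60, TRUE))] <- runif(60, 100, 1000)
  ref <- sad_image_for_test(base)
  # identity
  r0 <- register_translation(ref, ref, max_shift = 6)
  expect_equal(unname(r0$offset), c(0, 0))
  expect_equal(r0$score, 1)
  for (dr in c(-5, 0, 5)) for (dc in c(-3, 0, 4)) {
    mov <- sad_image_for_test(shift_for_test(base, dr, dc))
    r <- register_translation(ref, mov, max_shift = 6)
    expect_equal(unname(r$offset), c(dr, dc))
    expect_gt(r$score, 0.99)
  }
  # pure noise: some in-bounds offset with a low score, not an error
  n1 <- sad_image_for_test(matrix(runif(40 * 50), 40, 50))
  n2 <- sad_image_for_test(matrix(runif(40 * 50), 40, 50))
  rn <- register_translation(n1, n2, max_shift = 4)
  expect_true(all(abs(rn$offset) <= 4))
  expect_lt(rn$score, 0.5)
  expect_error(register_translation(ref, sad_image_for_test(matrix(0, 4, 4))), "shape")
  expect_error(register_translation(n1, n2, max_shift = 40), "smaller")
})
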