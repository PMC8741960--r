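# SAD (sum of absolute intensity differences) imaging and rigid
# superimposition of repeated acquisitions of one field of view.

#' Construct a video sequence
#'
#' @param frames 3-D array `[rows, cols, frames]` of non-negative
#'   intensities (16-bit count scale; stored as integer when possible).
#'   Pixels invalidated by registration are `NA`.
#' @param frame_rate Frames per second.
#' @param pixel_size um per pixel.
#' @param fov_id,timepoint Labels identifying the acquisition.
#' @param bit_depth Nominal bit depth of the source data (8 or 16).
#' @return An object of class `video_sequence`.
#' @export
video_sequence <- function(frames, frame_rate, pixel_size,
                           fov_id = "fov", timepoint = "baseline",
                           bit_depth = 16L) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a 3-D array [rows, cols, frames]", call. = FALSE)
  }
  if (dim(frames)[3] < 1L) stop("need at least one frame", call. = FALSE)
  if (any(frames < 0, na.rm = TRUE)) stop("intensities must be >= 0", call. = FALSE)
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  structure(
    list(frames = frames, frame_rate = frame_rate, pixel_size = pixel_size,
         fov_id = as.character(fov_id), timepoint = as.character(timepoint),
         bit_depth = as.integer(bit_depth)),
    class = "video_sequence"
  )
}

#' @export
print.video_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("video_sequence '%s' / '%s': %d x %d px, %d frames @ %g fps, %g um/px\n",
              x$fov_id, x$timepoint, d[1], d[2], d[3], x$frame_rate, x$pixel_size))
  invisible(x)
}

#' @export
dim.video_sequence <- function(x) dim(x$frames)

sad_image <- function(values, n_pairs, pixel_size = NA_real_,
                      fov_id = "fov", timepoint = "baseline") {
  structure(
    list(values = values, n_pairs = as.integer(n_pairs),
         pixel_size = pixel_size, fov_id = fov_id, timepoint = timepoint),
    class = "sad_image"
  )
}

#' @export
print.sad_image <- function(x, ...) {
  cat(sprintf("sad_image '%s' / '%s': %d x %d px, %d frame pair(s)\n",
              x$fov_id, x$timepoint, nrow(x$values), ncol(x$values), x$n_pairs))
  invisible(x)
}

#' @export
dim.sad_image <- function(x) dim(x$values)

#' Compute a SAD image from a video sequence
#'
#' Per-pixel sum of absolute intensity differences between frames `step`
#' apart: `values(x) = sum_t |I[t+step](x) - I[t](x)|`, accumulated in
#' double precision so 16-bit counts can never wrap or overflow (even at
#' 1800 frames x 65535 counts). Pixels that carry motion — flowing red
#' blood cells changing local absorption — accumulate large values; static
#' tissue stays near the noise floor. Pixels that are `NA` in any frame
#' (registration sentinels) stay `NA`.
#'
#' @param video A [video_sequence()].
#' @param step Frame lag for differencing (default 1: consecutive frames).
#' @return A `sad_image` with `n_pairs = n_frames - step`.
#' @export
compute_sad <- function(video, step = 1L) {
  stopifnot(inherits(video, "video_sequence"))
  step <- as.integer(step)
  if (step < 1L) stop("`step` must be >= 1", call. = FALSE)
  nt <- dim(video$frames)[3]
  if (nt <= step) {
    stop(sprintf("insufficient frames: need more than %d, got %d", step, nt),
         call. = FALSE)
  }
  d <- dim(video$frames)
  acc <- matrix(0, d[1], d[2])
  # loop over pairs keeps peak memory at two frames, not two stacks
  for (t in seq_len(nt - step)) {
    a <- video$frames[, , t]
    b <- video$frames[, , t + step]
    acc <- acc + abs(as.numeric(b) - as.numeric(a))
  }
  dim(acc) <- d[1:2]
  sad_image(acc, n_pairs = nt - step, pixel_size = video$pixel_size,
            fov_id = video$fov_id, timepoint = video$timepoint)
}

#' Normalize a SAD image to per-frame-pair scale
#'
#' Divides by `n_pairs` so acquisitions of different durations are
#' comparable; `n_pairs` becomes 1 and a second application is a no-op.
#'
#' @param sad A `sad_image`.
#' @return The normalized `sad_image`.
#' @export
normalize_sad <- function(sad) {
  stopifnot(inherits(sad, "sad_image"))
  if (sad$n_pairs < 1L) stop("`n_pairs` must be >= 1", call. = FALSE)
  sad$values <- sad$values / sad$n_pairs
  sad$n_pairs <- 1L
  sad
}

# Shift a matrix by integer (rows, cols), NA-filling exposed pixels.
shift_matrix <- function(m, dr, dc, fill = NA) {
  out <- matrix(fill, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  src_r <- max(1L, 1L - dr):min(nr, nr - dr)
  src_c <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(src_r) > 0 && length(src_c) > 0) {
    out[src_r + dr, src_c + dc] <- m[src_r, src_c]
  }
  out
}

#' Register one SAD image to another by integer translation
#'
#' Exhaustive search over all integer shifts within `+/- max_shift`,
#' scoring each by the Pearson (normalized cross-) correlation of the
#' overlapping region; `NA` pixels are excluded. Ties are broken by the
#' smallest shift magnitude, then by the row offset before the column
#' offset. A low score flags an unreliable superimposition but is not an
#' error.
#'
#' @param reference,moving `sad_image`s of equal shape.
#' @param max_shift Maximum absolute shift searched per axis, px.
#' @return A list of class `registration_result`: `offset` (rows, cols) —
#'   the displacement of `moving` relative to `reference`, so a scene that
#'   drifted by `(dr, dc)` px is recovered as `(dr, dc)` and
#'   `apply_offset(moving, -offset)` aligns it onto the reference —
#'   `score` in `[-1, 1]`, and `overlap_fraction`.
#' @export
register_translation <- function(reference, moving, max_shift = 20L) {
  stopifnot(inherits(reference, "sad_image"), inherits(moving, "sad_image"))
  if (!identical(dim(reference$values), dim(moving$values))) {
    stop("reference and moving images must share one shape", call. = FALSE)
  }
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L) stop("`max_shift` must be >= 0", call. = FALSE)
  d <- dim(reference$values)
  if (max_shift >= min(d)) {
    stop("`max_shift` must be smaller than the image size", call. = FALSE)
  }
  ref <- reference$values
  mov <- moving$values
  shifts <- expand.grid(dr = -max_shift:max_shift, dc = -max_shift:max_shift)
  # deterministic tie-break order: magnitude, then |row|, |col|, row, col
  ord <- order(shifts$dr^2 + shifts$dc^2, abs(shifts$dr), abs(shifts$dc),
               shifts$dr, shifts$dc)
  shifts <- shifts[ord, ]
  best <- list(score = -Inf, dr = 0L, dc = 0L, overlap = 0)
  npx <- prod(d)
  for (i in seq_len(nrow(shifts))) {
    dr <- shifts$dr[i]; dc <- shifts$dc[i]
    sh <- shift_matrix(mov, dr, dc)
    ok <- !is.na(sh) & !is.na(ref)
    n_ok <- sum(ok)
    if (n_ok < 9L) next
    a <- ref[ok]; b <- sh[ok]
    sda <- stats::sd(a); sdb <- stats::sd(b)
    sc <- if (sda > 0 && sdb > 0) stats::cor(a, b) else if (sda == 0 && sdb == 0) 1 else 0
    if (sc > best$score + 1e-12) {
      best <- list(score = sc, dr = dr, dc = dc, overlap = n_ok / npx)
    }
  }
  # the search shifts `moving`; the displacement of the scene is its negation
  structure(
    list(offset = c(rows = -best$dr, cols = -best$dc),
         score = best$score, overlap_fraction = best$overlap),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration: offset (%+d, %+d) px, score %.3f, overlap %.1f%%\n",
              x$offset[1], x$offset[2], x$score, 100 * x$overlap_fraction))
  invisible(x)
}

#' Apply a rigid integer translation
#'
#' Shifts a `sad_image` or every frame of a `video_sequence` by
#' `offset = c(rows, cols)`. Exposed pixels become `NA` and are excluded by
#' all downstream stages; shifting by `offset` and then `-offset` restores
#' the overlap region exactly.
#'
#' @param x A `sad_image` or `video_sequence`.
#' @param offset Integer shift `c(rows, cols)`.
#' @return Object of the same class as `x`.
#' @export
apply_offset <- function(x, offset) UseMethod("apply_offset")

check_offset <- function(offset, d) {
  offset <- as.integer(round(offset))
  if (length(offset) != 2L || any(abs(offset) >= d[1:2])) {
    stop("`offset` must be two integers smaller than the image size", call. = FALSE)
  }
  offset
}

#' @export
apply_offset.sad_image <- function(x, offset) {
  offset <- check_offset(offset, dim(x$values))
  x$values <- shift_matrix(x$values, offset[1], offset[2])
  x
}

#' @export
apply_offset.video_sequence <- function(x, offset) {
  offset <- check_offset(offset, dim(x$frames))
  d <- dim(x$frames)
  out <- array(NA_real_, d)
  for (t in seq_len(d[3])) {
    out[, , t] <- shift_matrix(x$frames[, , t], offset[1], offset[2])
  }
  x$frames <- out
  x
}
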