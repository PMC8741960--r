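# The composed perfusion measurement: SAD -> segmentation -> grid ->
# per-intersection classification -> index, and its longitudinal variant
# over repeated, registered observations of one field of view.

default_quant_params <- function() {
  list(
    step = 1L,             # SAD frame lag
    seg_method = "otsu",
    min_object_px = 30L,
    close_radius = 1,
    seg_quantile = 0.90,
    n_grid = 10L,
    min_separation = 5,
    window = 7L,
    k_sad = 3,
    k_sd = 3,
    n_background = 50L,
    calib_seed = 20231L,
    policy = NULL,         # a flow_policy to bypass calibration
    max_shift = 20L,
    score_floor = 0.2
  )
}

merge_params <- function(params) {
  p <- default_quant_params()
  if (length(params)) {
    unknown <- setdiff(names(params), names(p))
    if (length(unknown)) {
      stop(sprintf("unknown parameter(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
    p[names(params)] <- params
  }
  p
}

#' Perfusion index of one acquisition
#'
#' Composes the full per-acquisition chain: SAD image ([compute_sad()],
#' normalized to per-pair scale), vessel segmentation
#' ([segment_vessels()]), grid overlay ([make_grid()] unless a grid is
#' supplied), intersection enumeration ([find_intersections()]),
#' per-intersection temporal features ([extract_features()]) and the flow
#' decision ([classify_flow()] under a calibrated or supplied policy).
#' The perfusion index is the number of flow-positive grid-vessel
#' intersections; full per-intersection provenance is retained.
#'
#' @param video A [video_sequence()].
#' @param grid Optional [make_grid()] spec (defaults to a fresh 10 + 10
#'   grid on this frame; pass the baseline grid for longitudinal series).
#' @param params Named list overriding [default_quant_params()] entries
#'   (`step`, `seg_method`, `min_object_px`, `close_radius`, `n_grid`,
#'   `min_separation`, `window`, `k_sad`, `k_sd`, `n_background`,
#'   `calib_seed`, `policy`, ...).
#' @return A `perfusion_result`: list with `fov_id`, `timepoint`,
#'   `intersections` (data.frame: axis, line_index, row, col, sad_density,
#'   temporal_sd, lag1_autocorr, flow, classifier), `index`, `sad`,
#'   `segmentation`, `grid`, `policy`, `params`.
#' @export
perfusion_index <- function(video, grid = NULL, params = list()) {
  stopifnot(inherits(video, "video_sequence"))
  p <- merge_params(params)
  sad <- normalize_sad(compute_sad(video, step = p$step))
  seg <- segment_vessels(sad, method = p$seg_method,
                         min_object_px = p$min_object_px,
                         close_radius = p$close_radius,
                         quantile = p$seg_quantile)
  if (is.null(grid)) grid <- make_grid(dim(sad$values), p$n_grid)
  recs <- find_intersections(seg$skeleton, grid, min_separation = p$min_separation)

  policy <- p$policy
  if (is.null(policy)) {
    policy <- calibrate_policy(video, seg$mask, k_sad = p$k_sad, k_sd = p$k_sd,
                               n_background = p$n_background, window = p$window,
                               seed = p$calib_seed)
  }
  n <- nrow(recs)
  feats <- matrix(0, n, 3,
                  dimnames = list(NULL, c("sad_density", "temporal_sd", "lag1_autocorr")))
  flow <- logical(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      f <- extract_features(video, c(recs$row[i], recs$col[i]), window = p$window)
      feats[i, ] <- f
      flow[i] <- classify_flow(f, policy)
    }
  }
  intersections <- cbind(recs, as.data.frame(feats))
  intersections$flow <- flow
  intersections$classifier <- if (n > 0) policy$label else character(0)
  structure(
    list(
      fov_id = video$fov_id, timepoint = video$timepoint,
      intersections = intersections, index = sum(flow),
      sad = sad, segmentation = seg, grid = grid, policy = policy, params = p
    ),
    class = "perfusion_result"
  )
}

#' @export
print.perfusion_result <- function(x, ...) {
  cat(sprintf("perfusion_result '%s' / '%s': index %d (%d of %d intersections flow-positive)\n",
              x$fov_id, x$timepoint, x$index, x$index, nrow(x$intersections)))
  invisible(x)
}

#' Longitudinal perfusion index of one FOV
#'
#' The first acquisition is the baseline: the counting grid is defined
#' once on its frame, and every later acquisition is superimposed on it by
#' registering their SAD images ([register_translation()]) and rigidly
#' shifting the later video ([apply_offset()]); pixels exposed by the
#' shift are `NA` and excluded downstream. The perfusion index is then
#' recomputed per timepoint on the registered data. A registration score
#' below `score_floor` records a warning on that timepoint but still
#' produces its index.
#'
#' @param series List of [video_sequence()]s of one FOV, baseline first.
#' @param params As in [perfusion_index()]; `max_shift` bounds the
#'   registration search and `score_floor` flags weak registrations.
#' @return A `fov_timeseries`: list with `table` (data.frame: fov_id,
#'   timepoint, offset_rows, offset_cols, score, index, low_score) and
#'   `results` (per-timepoint `perfusion_result`s).
#' @export
series_index <- function(series, params = list()) {
  if (!is.list(series) || length(series) < 1L ||
      !all(vapply(series, inherits, logical(1), "video_sequence"))) {
    stop("`series` must be a non-empty list of video_sequence objects", call. = FALSE)
  }
  p <- merge_params(params)
  baseline <- series[[1L]]
  sad_ref <- normalize_sad(compute_sad(baseline, step = p$step))
  grid <- make_grid(dim(sad_ref$values), p$n_grid)
  n <- length(series)
  results <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    vid <- series[[i]]
    if (i == 1L) {
      off <- c(rows = 0L, cols = 0L)
      score <- 1
    } else {
      sad_i <- normalize_sad(compute_sad(vid, step = p$step))
      reg <- register_translation(sad_ref, sad_i, max_shift = p$max_shift)
      off <- reg$offset
      score <- reg$score
      if (any(off != 0)) vid <- apply_offset(vid, -off)
    }
    low <- score < p$score_floor
    if (low) {
      warning(sprintf("timepoint '%s': registration score %.3f below floor %.2f",
                      vid$timepoint, score, p$score_floor), call. = FALSE)
    }
    res <- perfusion_index(vid, grid = grid, params = params)
    results[[i]] <- res
    rows[[i]] <- data.frame(
      fov_id = vid$fov_id, timepoint = vid$timepoint,
      offset_rows = off[[1]], offset_cols = off[[2]],
      score = score, index = res$index, low_score = low
    )
  }
  structure(
    list(table = do.call(rbind, rows), results = results, grid = grid),
    class = "fov_timeseries"
  )
}

#' @export
print.fov_timeseries <- function(x, ...) {
  cat(sprintf("fov_timeseries '%s': %d timepoint(s)\n",
              x$table$fov_id[1], nrow(x$table)))
  print(x$table, digits = 3, row.names = FALSE)
  invisible(x)
}
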