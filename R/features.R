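# Per-intersection temporal features and the two-step flow decision.
# Step 1 of the classification is SAD-based candidate detection
# (segmentation + grid crossings); step 2 is the per-intersection decision
# made here from temporal features of the raw video. The default decision
# rule is a transparent threshold policy calibrated against the
# acquisition's own background noise; any feature -> boolean rule (e.g. a
# trained model) can be plugged in instead.

#' Temporal features of one candidate intersection
#'
#' Over a `window x window` neighbourhood (clipped at image borders)
#' centred on the location, computes:
#' \describe{
#'   \item{sad_density}{mean per-frame-pair SAD over the window — average
#'     absolute intensity change per pixel per pair, counts.}
#'   \item{temporal_sd}{standard deviation over time of the window-mean
#'     intensity, counts.}
#'   \item{lag1_autocorr}{lag-1 autocorrelation of that series (0 when the
#'     series has zero variance). Flowing RBCs produce positively
#'     correlated fluctuations; pure sensor noise does not.}
#' }
#'
#' @param video A [video_sequence()].
#' @param location `c(row, col)` 0-based pixel coordinate.
#' @param window Odd window edge length, px.
#' @return Named numeric vector `sad_density`, `temporal_sd`,
#'   `lag1_autocorr`.
#' @export
extract_features <- function(video, location, window = 7L) {
  stopifnot(inherits(video, "video_sequence"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd and >= 1", call. = FALSE)
  d <- dim(video$frames)
  r0 <- as.integer(location[1]); c0 <- as.integer(location[2])
  if (r0 < 0L || r0 >= d[1] || c0 < 0L || c0 >= d[2]) {
    stop("`location` lies outside the frame", call. = FALSE)
  }
  h <- window %/% 2L
  rr <- max(1L, r0 + 1L - h):min(d[1], r0 + 1L + h)
  cc <- max(1L, c0 + 1L - h):min(d[2], c0 + 1L + h)
  sub <- video$frames[rr, cc, , drop = FALSE]
  npx <- length(rr) * length(cc)
  flat <- matrix(as.numeric(sub), nrow = npx) # pixels x time
  m_t <- colMeans(flat, na.rm = TRUE)
  nt <- length(m_t)
  ts_sd <- stats::sd(m_t)
  if (!is.finite(ts_sd)) ts_sd <- 0
  lag1 <- 0
  if (nt > 2L && ts_sd > 0) {
    a <- m_t[-nt]; b <- m_t[-1L]
    if (stats::sd(a) > 0 && stats::sd(b) > 0) lag1 <- stats::cor(a, b)
  }
  pair_abs <- abs(flat[, -1L, drop = FALSE] - flat[, -nt, drop = FALSE])
  sad_density <- mean(rowSums(pair_abs, na.rm = TRUE) / (nt - 1L), na.rm = TRUE)
  if (!is.finite(sad_density)) sad_density <- 0
  c(sad_density = sad_density, temporal_sd = ts_sd, lag1_autocorr = lag1)
}

#' Transparent threshold flow policy
#'
#' Declares flow when `sad_density >= tau_sad` **and**
#' `temporal_sd >= tau_sd`. Thresholds are usually calibrated per
#' acquisition with [calibrate_policy()].
#'
#' @param tau_sad,tau_sd Decision thresholds (counts).
#' @param label Classifier label stored on each record.
#' @return A `flow_policy` object.
#' @export
threshold_policy <- function(tau_sad, tau_sd, label = "threshold") {
  stopifnot_scalar_number(tau_sad, "tau_sad", nonneg = TRUE)
  stopifnot_scalar_number(tau_sd, "tau_sd", nonneg = TRUE)
  structure(
    list(type = "threshold", tau_sad = tau_sad, tau_sd = tau_sd, label = label),
    class = "flow_policy"
  )
}

#' Wrap an arbitrary decision rule as a flow policy
#'
#' @param fun `function(features) -> logical(1)`.
#' @param label Classifier label stored on each record.
#' @return A `flow_policy` object.
#' @export
custom_policy <- function(fun, label = "custom") {
  stopifnot(is.function(fun))
  structure(list(type = "custom", fun = fun, label = label), class = "flow_policy")
}

#' Calibrate the threshold policy from background noise
#'
#' Samples `n_background` off-mask window centres with a seeded pattern,
#' measures their features, and sets each threshold to `k` times the
#' robust (median) background level. This adapts the decision to the
#' acquisition's own noise floor, which makes the perfusion index
#' invariant under global intensity scaling. With noise-free backgrounds
#' the thresholds collapse to a tiny positive floor, so exactly-zero
#' features still classify as no-flow.
#'
#' @param video A [video_sequence()].
#' @param mask Logical vessel mask (background is sampled off it).
#' @param k_sad,k_sd Multipliers on the background medians (defaults 3).
#' @param n_background Number of background windows.
#' @param window Feature window, px (odd).
#' @param seed Seed for the sampling pattern (fixed default: the default
#'   classifier is deterministic per acquisition).
#' @return A `flow_policy` with the calibrated thresholds; the background
#'   feature table is attached as attribute `background`.
#' @export
calibrate_policy <- function(video, mask, k_sad = 3, k_sd = 3,
                             n_background = 50L, window = 7L, seed = 20231L) {
  stopifnot(inherits(video, "video_sequence"), is.matrix(mask))
  valid <- is.finite(video$frames[, , 1])
  candidates <- which(!mask & valid)
  if (length(candidates) == 0) candidates <- which(valid)
  if (length(candidates) == 0) {
    return(threshold_policy(.Machine$double.eps, .Machine$double.eps,
                            label = "threshold(k-bg)"))
  }
  pick <- with_seed(seed, {
    candidates[sample.int(length(candidates), min(n_background, length(candidates)))]
  })
  nr <- nrow(mask)
  bg <- t(vapply(pick, function(i) {
    r0 <- (i - 1L) %% nr
    c0 <- (i - 1L) %/% nr
    extract_features(video, c(r0, c0), window = window)
  }, numeric(3)))
  tau_sad <- max(k_sad * stats::median(bg[, "sad_density"]), .Machine$double.eps)
  tau_sd <- max(k_sd * stats::median(bg[, "temporal_sd"]), .Machine$double.eps)
  pol <- threshold_policy(tau_sad, tau_sd, label = "threshold(k-bg)")
  attr(pol, "background") <- as.data.frame(bg)
  pol
}

#' Decide whether an intersection carries flow
#'
#' @param features Named numeric vector from [extract_features()].
#' @param policy A `flow_policy` ([threshold_policy()],
#'   [calibrate_policy()] or [custom_policy()]).
#' @return `TRUE` if the intersection is flow-positive.
#' @export
classify_flow <- function(features, policy) {
  if (!inherits(policy, "flow_policy")) {
    stop("unknown classifier policy; use threshold_policy(), calibrate_policy() or custom_policy()",
         call. = FALSE)
  }
  if (any(!is.finite(features))) stop("features must be finite", call. = FALSE)
  if (policy$type == "threshold") {
    isTRUE(features[["sad_density"]] >= policy$tau_sad &&
             features[["temporal_sd"]] >= policy$tau_sd)
  } else if (policy$type == "custom") {
    isTRUE(policy$fun(features))
  } else {
    stop(sprintf("unknown policy type '%s'", policy$type), call. = FALSE)
  }
}
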