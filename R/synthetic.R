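# Seeded synthetic intravital trans-illumination video generator.
#
# Emulates trans-illumination microscopy of a skeletal-muscle microvascular
# bed: dark, slowly varying vessel silhouettes on a bright background, with
# darker red-blood-cell (RBC) absorbers advected along the perfused vessels,
# additive sensor noise and optional photon (Poisson) noise. Every stage of
# the downstream perfusion analysis can be validated against the generator's
# ground truth.

#' Simulation configuration
#'
#' Defaults describe a reduced-scale acquisition that preserves the full
#' acquisition's aspect ratio (1200 x 1920 px) and temporal sampling at
#' 1/16 the pixel count: 300 x 480 px at 0.78 um/px (a 234 x 374 um field),
#' 30 frames/s for 10 s. Full-scale 1200 x 1920 / 60 s acquisitions are a
#' configuration away. Intensities are on a 16-bit count scale.
#'
#' @param fov_extent_um `c(width, height)` of the field of view in um.
#' @param pixel_size_um Pixel pitch, um/px.
#' @param frame_rate Frames per second.
#' @param duration_s Acquisition duration in seconds.
#' @param background_level Bright-field background, counts.
#' @param vessel_attenuation Fractional attenuation of the vessel
#'   silhouette (intensity is multiplied by `1 - vessel_attenuation`).
#' @param rbc_attenuation Additional fractional attenuation where an RBC
#'   absorber is present.
#' @param noise_sd Additive Gaussian sensor noise SD, counts.
#' @param photon_noise If `TRUE`, frames are Poisson-resampled.
#' @param drift_per_timepoint Rigid integer pixel shift `c(rows, cols)`
#'   applied between successive timepoints of one FOV.
#' @param n_segments Number of vessel segments to generate.
#' @param perfused_fraction Fraction of segments carrying RBC flow.
#' @param rbc_velocity_um_s Range (min, max) of RBC advection speeds, um/s.
#' @param rbc_per_mm Range of RBC linear densities, cells per mm.
#' @param diameter_um Range of vessel diameters, um.
#' @param seed Integer seed controlling all generator randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(fov_extent_um = c(480, 300) * 0.78,
                       pixel_size_um = 0.78,
                       frame_rate = 30,
                       duration_s = 10,
                       background_level = 30000,
                       vessel_attenuation = 0.30,
                       rbc_attenuation = 0.40,
                       noise_sd = 200,
                       photon_noise = FALSE,
                       drift_per_timepoint = c(0, 0),
                       n_segments = 12,
                       perfused_fraction = 0.7,
                       rbc_velocity_um_s = c(200, 1000),
                       rbc_per_mm = c(30, 80),
                       diameter_um = c(5, 9),
                       seed = 1L) {
  if (length(fov_extent_um) != 2L || any(!is.finite(fov_extent_um)) ||
      any(fov_extent_um <= 0)) {
    stop("`fov_extent_um` must be two positive numbers (width, height)", call. = FALSE)
  }
  stopifnot_scalar_number(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar_number(frame_rate, "frame_rate", positive = TRUE)
  stopifnot_scalar_number(duration_s, "duration_s", positive = TRUE)
  stopifnot_scalar_number(background_level, "background_level", positive = TRUE)
  stopifnot_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  if (vessel_attenuation <= 0 || vessel_attenuation >= 1) {
    stop("`vessel_attenuation` must be in (0, 1)", call. = FALSE)
  }
  if (rbc_attenuation <= 0 || rbc_attenuation >= 1) {
    stop("`rbc_attenuation` must be in (0, 1)", call. = FALSE)
  }
  if (perfused_fraction < 0 || perfused_fraction > 1) {
    stop("`perfused_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (round(duration_s * frame_rate) < 2) {
    stop("`duration_s` x `frame_rate` must give at least 2 frames", call. = FALSE)
  }
  structure(
    list(
      fov_extent_um = as.numeric(fov_extent_um),
      pixel_size_um = pixel_size_um,
      frame_rate = frame_rate,
      duration_s = duration_s,
      background_level = background_level,
      vessel_attenuation = vessel_attenuation,
      rbc_attenuation = rbc_attenuation,
      noise_sd = noise_sd,
      photon_noise = isTRUE(photon_noise),
      drift_per_timepoint = as.numeric(drift_per_timepoint),
      n_segments = as.integer(n_segments),
      perfused_fraction = perfused_fraction,
      rbc_velocity_um_s = as.numeric(rbc_velocity_um_s),
      rbc_per_mm = as.numeric(rbc_per_mm),
      diameter_um = as.numeric(diameter_um),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Pixel frame shape (rows, cols) implied by a config.
config_shape <- function(config) {
  c(
    rows = as.integer(round(config$fov_extent_um[2] / config$pixel_size_um)),
    cols = as.integer(round(config$fov_extent_um[1] / config$pixel_size_um))
  )
}

# --- polyline helpers (centerlines are n x 2 matrices of (x, y) in um) ----

poly_cumlen <- function(P) {
  d <- sqrt(diff(P[, 1])^2 + diff(P[, 2])^2)
  c(0, cumsum(d))
}

# Points at arc lengths s (vectorized) along polyline P.
poly_point_at <- function(P, s, cum = poly_cumlen(P)) {
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), nrow(P) - 1L)
  seg_len <- cum[i + 1L] - cum[i]
  frac <- ifelse(seg_len > 0, (s - cum[i]) / seg_len, 0)
  cbind(
    P[i, 1] + frac * (P[i + 1L, 1] - P[i, 1]),
    P[i, 2] + frac * (P[i + 1L, 2] - P[i, 2])
  )
}

# Minimum distance from each point in Q (m x 2) to segment p1-p2.
dist_to_segment <- function(qx, qy, p1, p2) {
  vx <- p2[1] - p1[1]
  vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  if (len2 == 0) {
    return(sqrt((qx - p1[1])^2 + (qy - p1[2])^2))
  }
  t <- ((qx - p1[1]) * vx + (qy - p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((qx - (p1[1] + t * vx))^2 + (qy - (p1[2] + t * vy))^2)
}

#' Generate a synthetic vessel network
#'
#' Vessel centerlines are smooth random walks (bounded turning angle)
#' started on the field border and grown until they leave the field, so
#' that segments span the FOV. A rejection step keeps pairwise centerline
#' separation of at least one diameter where feasible. Diameters, RBC
#' velocities and linear densities are drawn from the config ranges;
#' perfusion labels are then assigned with [assign_perfusion()].
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `vessel_network`: list with `segments` (each with `id`,
#'   `centerline` (n x 2 um), `diameter_um`, `perfused`,
#'   `rbc_velocity_um_s`, `rbc_per_mm`) and `fov_extent_um`.
#' @export
generate_network <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_segments < 1L) stop("`n_segments` must be >= 1", call. = FALSE)
  W <- config$fov_extent_um[1]
  H <- config$fov_extent_um[2]
  step_um <- max(min(W, H) / 18, 4 * config$pixel_size_um)
  max_turn <- 25 * pi / 180

  with_seed(seed, {
    segments <- vector("list", config$n_segments)
    existing_pts <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(config$n_segments)) {
      diameter <- stats::runif(1, config$diameter_um[1], config$diameter_um[2])
      best <- NULL
      best_sep <- -Inf
      for (attempt in 1:20) {
        # start on a random border, heading inward +/- 45 deg
        side <- sample.int(4L, 1L)
        u <- stats::runif(1)
        start <- switch(side,
          c(u * W, 0), c(u * W, H), c(0, u * H), c(W, u * H)
        )
        heading <- switch(side,
          pi / 2, -pi / 2, 0, pi
        ) + stats::runif(1, -pi / 4, pi / 4)
        pts <- matrix(start, ncol = 2)
        for (i in 1:400) {
          heading <- heading + stats::runif(1, -max_turn, max_turn)
          nxt <- pts[nrow(pts), ] + step_um * c(cos(heading), sin(heading))
          pts <- rbind(pts, nxt)
          if (nxt[1] < 0 || nxt[1] > W || nxt[2] < 0 || nxt[2] > H) break
        }
        pts[, 1] <- pmin(pmax(pts[, 1], 0), W)
        pts[, 2] <- pmin(pmax(pts[, 2], 0), H)
        if (nrow(pts) < 3L) next
        sep <- if (nrow(existing_pts) == 0) Inf else {
          dens <- poly_point_at(pts, seq(0, poly_cumlen(pts)[nrow(pts)], by = step_um / 2))
          min(sqrt(outer(dens[, 1], existing_pts[, 1], "-")^2 +
                     outer(dens[, 2], existing_pts[, 2], "-")^2))
        }
        if (sep > best_sep) {
          best <- pts
          best_sep <- sep
        }
        if (sep >= diameter) break
      }
      segments[[k]] <- list(
        id = k,
        centerline = best,
        diameter_um = diameter,
        perfused = TRUE,
        rbc_velocity_um_s = stats::runif(1, config$rbc_velocity_um_s[1],
                                         config$rbc_velocity_um_s[2]),
        rbc_per_mm = stats::runif(1, config$rbc_per_mm[1], config$rbc_per_mm[2])
      )
      dens <- poly_point_at(best, seq(0, poly_cumlen(best)[nrow(best)], by = step_um / 2))
      existing_pts <- rbind(existing_pts, dens)
    }
    structure(
      list(segments = segments, fov_extent_um = c(W, H)),
      class = "vessel_network"
    )
  })
}

#' @export
print.vessel_network <- function(x, ...) {
  n <- length(x$segments)
  perf <- sum(vapply(x$segments, `[[`, logical(1), "perfused"))
  cat(sprintf("Synthetic vessel network: %d segments (%d perfused), FOV %.0f x %.0f um\n",
              n, perf, x$fov_extent_um[1], x$fov_extent_um[2]))
  invisible(x)
}

#' Assign perfusion labels to a vessel network
#'
#' Exactly `round(perfused_fraction * n_segments)` segments are labelled
#' perfused, chosen by seeded sampling without replacement; the remainder
#' become static silhouettes with RBC velocity 0.
#'
#' @param network A `vessel_network`.
#' @param perfused_fraction Fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return The network with updated `perfused` / `rbc_velocity_um_s`.
#' @export
assign_perfusion <- function(network, perfused_fraction, seed = 1L) {
  stopifnot(inherits(network, "vessel_network"))
  if (perfused_fraction < 0 || perfused_fraction > 1) {
    stop("`perfused_fraction` must be in [0, 1]", call. = FALSE)
  }
  n <- length(network$segments)
  n_perf <- round(perfused_fraction * n)
  chosen <- with_seed(seed, sample.int(n, n_perf))
  for (k in seq_len(n)) {
    on <- k %in% chosen
    network$segments[[k]]$perfused <- on
    if (!on) network$segments[[k]]$rbc_velocity_um_s <- 0
  }
  network
}

# Rasterize the tube (centerline dilated to diameter) of given segments.
raster_tube <- function(segments, shape, pixel_size) {
  mask <- matrix(FALSE, shape[1], shape[2])
  if (length(segments) == 0) return(mask)
  xc <- (seq_len(shape[2]) - 0.5) * pixel_size # um at pixel centers, by col
  yc <- (seq_len(shape[1]) - 0.5) * pixel_size # by row
  for (seg in segments) {
    P <- seg$centerline
    rad <- seg$diameter_um / 2
    for (i in seq_len(nrow(P) - 1L)) {
      p1 <- P[i, ]
      p2 <- P[i + 1L, ]
      r_lo <- max(1L, floor((min(p1[2], p2[2]) - rad) / pixel_size))
      r_hi <- min(shape[1], ceiling((max(p1[2], p2[2]) + rad) / pixel_size) + 1L)
      c_lo <- max(1L, floor((min(p1[1], p2[1]) - rad) / pixel_size))
      c_hi <- min(shape[2], ceiling((max(p1[1], p2[1]) + rad) / pixel_size) + 1L)
      if (r_lo > r_hi || c_lo > c_hi) next
      rr <- r_lo:r_hi
      cc <- c_lo:c_hi
      qx <- rep(xc[cc], each = length(rr))
      qy <- rep(yc[rr], times = length(cc))
      d <- dist_to_segment(qx, qy, p1, p2)
      hit <- matrix(d <= rad, nrow = length(rr))
      mask[rr, cc] <- mask[rr, cc] | hit
    }
  }
  mask
}

#' Rasterize vessel centerlines to one-pixel-wide paths
#'
#' Dense arc-length sampling (half-pixel step) followed by de-duplication,
#' giving an 8-connected skeleton of the true centerlines. Useful as a
#' ground-truth stand-in for a segmentation-derived skeleton.
#'
#' @param network A `vessel_network`.
#' @param shape Image shape `c(rows, cols)`.
#' @param pixel_size um per pixel.
#' @param perfused_only If `TRUE`, only perfused segments are drawn.
#' @return Logical matrix.
#' @export
rasterize_centerlines <- function(network, shape, pixel_size, perfused_only = FALSE) {
  mask <- matrix(FALSE, shape[1], shape[2])
  for (seg in network$segments) {
    if (perfused_only && !seg$perfused) next
    P <- seg$centerline
    cum <- poly_cumlen(P)
    total <- cum[length(cum)]
    if (total <= 0) next
    pts <- poly_point_at(P, seq(0, total, by = pixel_size / 2), cum)
    r <- pmin(pmax(floor(pts[, 2] / pixel_size) + 1L, 1L), shape[1])
    c <- pmin(pmax(floor(pts[, 1] / pixel_size) + 1L, 1L), shape[2])
    mask[cbind(r, c)] <- TRUE
  }
  mask
}

#' Render a synthetic acquisition and its ground truth
#'
#' Image model: each frame starts at `background_level`; intensity is
#' multiplied by `1 - vessel_attenuation` inside the union of the
#' rasterized vessel tubes and additionally by `1 - rbc_attenuation`
#' inside the union of the RBC discs of that frame. RBC absorbers (discs
#' of the vessel diameter) are advected one-dimensionally along perfused
#' centerlines at the segment's RBC velocity with seeded initial phases
#' and wrap-around, so the number of absorbers per segment is constant
#' over time. Additive Gaussian noise and optional Poisson resampling
#' follow; frames are quantized to the 16-bit range. The result is
#' bit-identical for a fixed seed.
#'
#' @param network A `vessel_network` (with perfusion labels).
#' @param config A [sim_config()].
#' @param drift_px Rigid integer pixel shift `c(rows, cols)` applied to the
#'   whole scene for this acquisition (used to emulate inter-timepoint FOV
#'   drift).
#' @param timepoint,fov_id Labels stored on the resulting video.
#' @param seed Seed for phases and noise (defaults to `config$seed`).
#' @return A list with `video` (a `video_sequence`) and `ground_truth`
#'   (list: `network`, `vessel_mask`, `perfused_mask`, `segment_labels`,
#'   `applied_drift`).
#' @export
render_video <- function(network, config, drift_px = c(0, 0),
                         timepoint = "baseline", fov_id = "fov1",
                         seed = config$seed) {
  stopifnot(inherits(network, "vessel_network"), inherits(config, "sim_config"))
  shape <- config_shape(config)
  ps <- config$pixel_size_um
  n_frames <- as.integer(round(config$duration_s * config$frame_rate))
  if (n_frames < 2L) stop("configuration yields fewer than 2 frames", call. = FALSE)
  for (seg in network$segments) {
    if (any(seg$centerline[, 1] < 0 | seg$centerline[, 1] > config$fov_extent_um[1] |
            seg$centerline[, 2] < 0 | seg$centerline[, 2] > config$fov_extent_um[2])) {
      stop("network does not fit the configured FOV", call. = FALSE)
    }
  }

  drift_px <- round(drift_px)
  shifted <- network
  if (any(drift_px != 0)) {
    for (k in seq_along(shifted$segments)) {
      P <- shifted$segments[[k]]$centerline
      P[, 1] <- P[, 1] + drift_px[2] * ps
      P[, 2] <- P[, 2] + drift_px[1] * ps
      shifted$segments[[k]]$centerline <- P
    }
  }

  vessel_mask <- raster_tube(shifted$segments, shape, ps)
  perfused <- Filter(function(s) s$perfused, shifted$segments)
  perfused_mask <- raster_tube(perfused, shape, ps)
  base <- matrix(config$background_level, shape[1], shape[2])
  base[vessel_mask] <- base[vessel_mask] * (1 - config$vessel_attenuation)

  # Per-segment RBC bookkeeping: arc-length phases + precomputed disc stencil.
  rbc <- lapply(perfused, function(seg) {
    cum <- poly_cumlen(seg$centerline)
    total <- cum[length(cum)]
    n_rbc <- max(1L, as.integer(round(seg$rbc_per_mm * total / 1000)))
    # stencil radius +0.75 px compensates the sub-pixel cell-center offset;
    # discs are clipped to the vessel tube at render time, so the swept
    # union matches the rasterized tube without spilling outside it
    rad_px <- (seg$diameter_um / 2) / ps + 0.75
    R <- max(0L, as.integer(ceiling(rad_px)))
    off <- expand.grid(dr = -R:R, dc = -R:R)
    off <- off[off$dr^2 + off$dc^2 <= rad_px^2, , drop = FALSE]
    if (nrow(off) == 0) off <- data.frame(dr = 0L, dc = 0L)
    list(seg = seg, cum = cum, total = total, n_rbc = n_rbc,
         dr = as.integer(off$dr), dc = as.integer(off$dc))
  })

  frames <- array(0L, dim = c(unname(shape[1]), unname(shape[2]), n_frames))
  with_seed(seed, {
    phases <- lapply(rbc, function(b) stats::runif(b$n_rbc, 0, b$total))
    npx <- shape[1] * shape[2]
    for (t in seq_len(n_frames)) {
      tt <- (t - 1) / config$frame_rate
      fr <- base
      idx_all <- integer(0)
      for (j in seq_along(rbc)) {
        b <- rbc[[j]]
        s <- (phases[[j]] + b$seg$rbc_velocity_um_s * tt) %% b$total
        pts <- poly_point_at(b$seg$centerline, s, b$cum)
        r0 <- as.integer(floor(pts[, 2] / ps)) + 1L
        c0 <- as.integer(floor(pts[, 1] / ps)) + 1L
        r <- rep(r0, each = length(b$dr)) + b$dr
        c <- rep(c0, each = length(b$dc)) + b$dc
        ok <- r >= 1L & r <= shape[1] & c >= 1L & c <= shape[2]
        idx_all <- c(idx_all, (c[ok] - 1L) * shape[1] + r[ok])
      }
      if (length(idx_all)) {
        idx_all <- unique(idx_all)
        idx_all <- idx_all[vessel_mask[idx_all]] # RBCs stay inside the lumen
        fr[idx_all] <- fr[idx_all] * (1 - config$rbc_attenuation)
      }
      if (config$noise_sd > 0) fr <- fr + stats::rnorm(npx, sd = config$noise_sd)
      if (config$photon_noise) fr <- stats::rpois(npx, pmax(fr, 0))
      frames[, , t] <- as.integer(pmin(pmax(round(fr), 0), 65535))
    }
  })

  video <- video_sequence(frames, frame_rate = config$frame_rate,
                          pixel_size = ps, fov_id = fov_id,
                          timepoint = timepoint)
  ground_truth <- list(
    network = shifted,
    vessel_mask = vessel_mask,
    perfused_mask = perfused_mask,
    segment_labels = stats::setNames(
      vapply(shifted$segments, `[[`, logical(1), "perfused"),
      vapply(shifted$segments, `[[`, numeric(1), "id")
    ),
    applied_drift = drift_px
  )
  list(video = video, ground_truth = ground_truth)
}

# Continuous 0-based pixel coordinates of a centerline (pixel center of
# index i sits at (i + 0.5) * pixel_size um).
centerline_px <- function(P, pixel_size) {
  cbind(P[, 1] / pixel_size - 0.5, P[, 2] / pixel_size - 0.5)
}

# Crossing positions of one polyline (continuous px coords) with a
# constant-coordinate line. `axis_coord` selects the coordinate that must
# cross `at`; returns the other coordinate at each crossing.
polyline_line_crossings <- function(Ppx, at, axis = c("row", "col")) {
  axis <- match.arg(axis)
  a <- if (axis == "row") Ppx[, 2] else Ppx[, 1] # coordinate that crosses
  b <- if (axis == "row") Ppx[, 1] else Ppx[, 2] # coordinate reported
  n <- length(a)
  if (n < 2L) return(numeric(0))
  a1 <- a[-n]; a2 <- a[-1L]
  b1 <- b[-n]; b2 <- b[-1L]
  # half-open crossing rule: robust to vertices exactly on the line
  hit <- (a1 <= at & a2 > at) | (a2 <= at & a1 > at)
  if (!any(hit)) return(numeric(0))
  frac <- (at - a1[hit]) / (a2[hit] - a1[hit])
  b1[hit] + frac * (b2[hit] - b1[hit])
}

# Merge sorted 1-D positions closer than min_separation; returns cluster
# centroids (mean position per merged run).
merge_positions <- function(pos, min_separation) {
  if (length(pos) == 0) return(numeric(0))
  pos <- sort(pos)
  grp <- cumsum(c(1, diff(pos) >= min_separation))
  as.numeric(tapply(pos, grp, mean))
}

#' Ground-truth perfusion index of a synthetic scene
#'
#' Counts crossings between the grid lines and the exact centerlines of the
#' perfused segments, merged along each line with the same
#' `min_separation` rule as [find_intersections()]. This is the
#' ground-truth twin of the pipeline's perfusion index.
#'
#' @param ground_truth Result of [render_video()] (`$ground_truth`), or a
#'   `vessel_network`.
#' @param grid A [make_grid()] specification for the rendered frame.
#' @param pixel_size um per pixel (taken from `grid` attr if absent).
#' @param min_separation Crossing-merging distance along a line, px.
#' @param perfused_only Count only perfused segments (default) or all.
#' @return Integer crossing count.
#' @export
expected_index <- function(ground_truth, grid, pixel_size,
                           min_separation = 5, perfused_only = TRUE) {
  network <- if (inherits(ground_truth, "vessel_network")) ground_truth
             else ground_truth$network
  stopifnot(inherits(network, "vessel_network"), inherits(grid, "grid_spec"))
  segs <- Filter(function(s) !perfused_only || s$perfused, network$segments)
  total <- 0L
  for (at in grid$line_rows) {
    pos <- unlist(lapply(segs, function(s) {
      polyline_line_crossings(centerline_px(s$centerline, pixel_size), at, "row")
    }))
    total <- total + length(merge_positions(pos, min_separation))
  }
  for (at in grid$line_cols) {
    pos <- unlist(lapply(segs, function(s) {
      polyline_line_crossings(centerline_px(s$centerline, pixel_size), at, "col")
    }))
    total <- total + length(merge_positions(pos, min_separation))
  }
  as.integer(total)
}
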