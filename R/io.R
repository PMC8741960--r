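# File formats and the manifest-driven pipeline.
#
# Stacks are multi-page grayscale TIFF (8- or 16-bit, uncompressed). No
# TIFF package exists in this R stack, so a minimal baseline TIFF
# reader/writer lives here; it supports exactly what the pipeline needs
# (both byte orders on read, little-endian single-strip on write) and is
# cross-checked against an independent reader in the test suite.

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, rows_per_strip = 278L,
               strip_byte_counts = 279L, sample_format = 339L)

#' Write a video stack as a multi-page grayscale TIFF
#'
#' Uncompressed baseline TIFF, little-endian, one strip per page. A JSON
#' sidecar (`<path>.json`) stores the acquisition metadata (frame rate,
#' pixel size, labels, bit depth) so [read_stack()] can round-trip a
#' [video_sequence()] losslessly.
#'
#' @param x A [video_sequence()] or a 3-D array `[rows, cols, frames]`.
#' @param path Output file path.
#' @param bit_depth 8 or 16.
#' @param sidecar Write the JSON metadata sidecar (default `TRUE` for
#'   `video_sequence` input).
#' @return `path`, invisibly.
#' @export
write_stack <- function(x, path, bit_depth = 16L, sidecar = inherits(x, "video_sequence")) {
  frames <- if (inherits(x, "video_sequence")) x$frames else x
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`x` must be a video_sequence or 3-D array", call. = FALSE)
  }
  if (anyNA(frames)) stop("cannot write NA pixels to a TIFF stack", call. = FALSE)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  maxv <- 2^bit_depth - 1
  if (any(frames < 0) || any(frames > maxv)) {
    stop(sprintf("intensities outside [0, %d]", maxv), call. = FALSE)
  }
  d <- dim(frames)
  H <- d[1]; W <- d[2]; nt <- d[3]
  bytes_px <- bit_depth %/% 8L
  data_size <- H * W * bytes_px
  ifd_size <- 2L + 9L * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")

  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT: low two bytes, then pad
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  offset <- 8L
  for (t in seq_len(nt)) {
    data_offset <- offset + ifd_size
    next_ifd <- if (t < nt) data_offset + data_size else 0L
    writeBin(9L, con, size = 2, endian = "little")
    tag(TIFF_TAGS[["width"]], 4L, 1L, W)
    tag(TIFF_TAGS[["height"]], 4L, 1L, H)
    tag(TIFF_TAGS[["bits"]], 3L, 1L, bit_depth)
    tag(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    tag(TIFF_TAGS[["photometric"]], 3L, 1L, 1L) # BlackIsZero
    tag(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_offset)
    tag(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, H)
    tag(TIFF_TAGS[["strip_byte_counts"]], 4L, 1L, data_size)
    tag(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L) # unsigned integer
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    v <- as.integer(round(as.vector(t(frames[, , t])))) # row-major
    if (bit_depth == 16L) {
      v[v > 32767L] <- v[v > 32767L] - 65536L # two's complement for writeBin
      writeBin(v, con, size = 2, endian = "little")
    } else {
      writeBin(v, con, size = 1, endian = "little")
    }
    offset <- data_offset + data_size
  }

  if (isTRUE(sidecar) && inherits(x, "video_sequence")) {
    meta <- list(frame_rate = x$frame_rate, pixel_size = x$pixel_size,
                 fov_id = x$fov_id, timepoint = x$timepoint,
                 bit_depth = bit_depth)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

read_tiff_array <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- readChar(con, 2, useBytes = TRUE)
  endian <- if (order_bytes == "II") "little" else if (order_bytes == "MM") "big" else {
    stop("not a TIFF file (bad byte-order mark)", call. = FALSE)
  }
  magic <- readBin(con, integer(), size = 2, endian = endian)
  if (magic != 42L) stop("not a TIFF file (bad magic number)", call. = FALSE)
  ifd_offset <- readBin(con, integer(), size = 4, endian = endian)

  read_value_array <- function(type, count, raw4) {
    # raw4 holds the inline value field; larger arrays live at an offset
    size <- if (type == 3L) 2L else 4L
    inline_n <- 4L %/% size
    if (count <= inline_n) {
      readBin(raw4, integer(), n = count, size = size, signed = size >= 4,
              endian = endian)
    } else {
      off <- readBin(raw4, integer(), size = 4, endian = endian)
      cur <- seek(con)
      seek(con, off)
      v <- readBin(con, integer(), n = count, size = size,
                   signed = size >= 4, endian = endian)
      seek(con, cur)
      v
    }
  }

  pages <- list()
  bit_depth <- NULL
  while (ifd_offset != 0L) {
    seek(con, ifd_offset)
    n_tags <- readBin(con, integer(), size = 2, signed = FALSE, endian = endian)
    tags <- list()
    for (i in seq_len(n_tags)) {
      id <- readBin(con, integer(), size = 2, signed = FALSE, endian = endian)
      type <- readBin(con, integer(), size = 2, signed = FALSE, endian = endian)
      count <- readBin(con, integer(), size = 4, endian = endian)
      raw4 <- readBin(con, raw(), 4)
      tags[[as.character(id)]] <- list(type = type, count = count, raw = raw4)
    }
    ifd_offset <- readBin(con, integer(), size = 4, endian = endian)

    get_tag <- function(id, default = NULL) {
      t <- tags[[as.character(id)]]
      if (is.null(t)) return(default)
      read_value_array(t$type, t$count, t$raw)
    }
    W <- get_tag(TIFF_TAGS[["width"]])
    H <- get_tag(TIFF_TAGS[["height"]])
    bits <- get_tag(TIFF_TAGS[["bits"]], 1L)[1]
    comp <- get_tag(TIFF_TAGS[["compression"]], 1L)
    fmt <- get_tag(TIFF_TAGS[["sample_format"]], 1L)[1]
    if (is.null(W) || is.null(H)) stop("TIFF page missing dimensions", call. = FALSE)
    if (comp != 1L) stop("only uncompressed TIFF is supported", call. = FALSE)
    if (!bits %in% c(8L, 16L)) {
      stop(sprintf("unsupported bit depth: %d (need 8 or 16)", bits), call. = FALSE)
    }
    if (!is.null(bit_depth) && bits != bit_depth) {
      stop("mixed bit depths across pages", call. = FALSE)
    }
    if (fmt != 1L) stop("only unsigned-integer samples are supported", call. = FALSE)
    bit_depth <- bits
    offs <- get_tag(TIFF_TAGS[["strip_offsets"]])
    counts <- get_tag(TIFF_TAGS[["strip_byte_counts"]])
    if (is.null(offs) || is.null(counts)) stop("TIFF page missing strip layout", call. = FALSE)
    px <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      n <- counts[s] %/% (bits %/% 8L)
      px <- c(px, readBin(con, integer(), n = n, size = bits %/% 8L,
                          signed = FALSE, endian = endian))
      # 8/16-bit unsigned reads never overflow a 32-bit R integer
    }
    if (length(px) != H * W) stop("TIFF strip data does not match page size", call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(px, nrow = H, byrow = TRUE)
  }
  if (length(pages) == 0) stop("TIFF file contains no pages", call. = FALSE)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("mixed frame shapes across pages", call. = FALSE)
  }
  arr <- array(0L, dim = c(shapes[1, 1], shapes[2, 1], length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  attr(arr, "bit_depth") <- bit_depth
  arr
}

#' Read a multi-page grayscale TIFF stack as a video sequence
#'
#' Supports uncompressed baseline TIFF, 8- or 16-bit grayscale, either
#' byte order, single- or multi-strip pages. Metadata comes from the JSON
#' sidecar written by [write_stack()] when present; explicit arguments
#' override it.
#'
#' @param path TIFF file path.
#' @param frame_rate,pixel_size,fov_id,timepoint Metadata overrides.
#' @return A [video_sequence()].
#' @export
read_stack <- function(path, frame_rate = NULL, pixel_size = NULL,
                       fov_id = NULL, timepoint = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  arr <- read_tiff_array(path)
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  video_sequence(
    structure(arr, bit_depth = NULL),
    frame_rate = frame_rate %||% meta$frame_rate %||% 30,
    pixel_size = pixel_size %||% meta$pixel_size %||% 1,
    fov_id = fov_id %||% meta$fov_id %||% "fov",
    timepoint = timepoint %||% meta$timepoint %||% "baseline",
    bit_depth = attr(arr, "bit_depth")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a SAD image as a single-page TIFF plus JSON sidecar
#'
#' SAD values are stored 16-bit after scaling to the full range (the scale
#' factor is recorded in the sidecar with `n_pairs` and the labels); exact
#' values live in the sidecar-referenced scale, the TIFF is for viewing.
#'
#' @param sad A `sad_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sad <- function(sad, path) {
  stopifnot(inherits(sad, "sad_image"))
  v <- sad$values
  v[!is.finite(v)] <- 0
  scale <- if (max(v) > 0) 65535 / max(v) else 1
  arr <- array(as.integer(round(v * scale)), dim = c(nrow(v), ncol(v), 1))
  write_stack(arr, path, bit_depth = 16L, sidecar = FALSE)
  jsonlite::write_json(
    list(n_pairs = sad$n_pairs, scale = scale, fov_id = sad$fov_id,
         timepoint = sad$timepoint, pixel_size = sad$pixel_size),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write a QC overlay image
#'
#' Renders the (normalized) SAD image in gray, the counting grid in blue,
#' the segmentation mask as a red tint, and flow-positive intersections as
#' green squares; written as PNG.
#'
#' @param result A `perfusion_result`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(result, path) {
  stopifnot(inherits(result, "perfusion_result"))
  v <- result$sad$values
  v[!is.finite(v)] <- 0
  if (max(v) > 0) v <- v / stats::quantile(v[v > 0], 0.99)
  v <- pmin(v, 1)
  H <- nrow(v); W <- ncol(v)
  img <- array(rep(v, 3), dim = c(H, W, 3))
  mask <- result$segmentation$mask
  img[, , 1][mask] <- pmin(img[, , 1][mask] + 0.35, 1)
  for (r in result$grid$line_rows) img[r + 1L, , 3] <- pmin(img[r + 1L, , 3] + 0.5, 1)
  for (cc in result$grid$line_cols) img[, cc + 1L, 3] <- pmin(img[, cc + 1L, 3] + 0.5, 1)
  recs <- result$intersections
  if (nrow(recs)) {
    for (i in which(recs$flow)) {
      rr <- pmax(1L, recs$row[i] - 1L):pmin(H, recs$row[i] + 3L)
      cc <- pmax(1L, recs$col[i] - 1L):pmin(W, recs$col[i] + 3L)
      img[rr, cc, 2] <- 1
      img[rr, cc, c(1, 3)] <- 0
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read an analysis manifest
#'
#' YAML with top-level `seed`, `output_dir`, optional `params` (see
#' [default_quant_params()]), and `fovs`: a list of entries with `fov_id`,
#' `pixel_size`, `frame_rate` and `timepoints` (each `label` + `path`,
#' baseline first). Relative stack paths resolve against the manifest's
#' directory.
#'
#' @param path Manifest YAML path.
#' @return Manifest list (class `analysis_manifest`).
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  m$base_dir <- dirname(normalizePath(path))
  validate_manifest(m)
}

validate_manifest <- function(m) {
  if (is.null(m$fovs) || length(m$fovs) == 0) {
    stop("manifest must list at least one FOV", call. = FALSE)
  }
  m$seed <- as.integer(m$seed %||% 1L)
  m$params <- m$params %||% list()
  m$output_dir <- m$output_dir %||% "ivmflow-results"
  for (f in m$fovs) {
    if (is.null(f$fov_id) || is.null(f$timepoints) || length(f$timepoints) == 0) {
      stop("every manifest FOV needs `fov_id` and a non-empty `timepoints` list",
           call. = FALSE)
    }
  }
  class(m) <- "analysis_manifest"
  m
}

resolve_path <- function(path, base_dir) {
  if (is.null(base_dir) || grepl("^(/|[A-Za-z]:)", path)) path
  else file.path(base_dir, path)
}

#' Run the full manifest-driven analysis
#'
#' For every FOV in the manifest: read its per-timepoint stacks, register
#' later timepoints to baseline, compute per-timepoint perfusion indices
#' ([series_index()]), and write per-FOV intersection tables
#' (`<fov>_intersections.csv`), the combined series table
#' (`series_indices.csv`), optional QC overlays, and a machine-readable
#' run log (`run_log.json`: package version, parameters, seed, per-FOV
#' status). Per-FOV failures are logged and skipped; the run fails only if
#' every FOV fails. Rerunning with an identical manifest and seed is
#' bit-identical.
#'
#' @param manifest An `analysis_manifest` (from [read_manifest()]) or a
#'   manifest-shaped list.
#' @param output_dir Overrides the manifest's `output_dir`.
#' @param qc_overlays Write QC overlay PNGs per timepoint.
#' @return Invisibly, the combined series data.frame.
#' @export
run_pipeline <- function(manifest, output_dir = NULL, qc_overlays = FALSE) {
  if (!inherits(manifest, "analysis_manifest")) manifest <- validate_manifest(manifest)
  out <- output_dir %||% manifest$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  params <- manifest$params
  if (is.null(params$calib_seed)) {
    params$calib_seed <- derive_seed(manifest$seed, "calibration")
  }
  status <- list()
  series_rows <- list()
  for (f in manifest$fovs) {
    res <- tryCatch({
      vids <- lapply(f$timepoints, function(tp) {
        read_stack(resolve_path(tp$path, manifest$base_dir),
                   frame_rate = f$frame_rate, pixel_size = f$pixel_size,
                   fov_id = f$fov_id, timepoint = tp$label)
      })
      ts <- series_index(vids, params = params)
      inter <- do.call(rbind, lapply(ts$results, function(r) {
        if (nrow(r$intersections) == 0) return(NULL)
        cbind(data.frame(fov_id = r$fov_id, timepoint = r$timepoint),
              r$intersections)
      }))
      if (is.null(inter)) {
        inter <- data.frame(fov_id = character(0), timepoint = character(0))
      }
      utils::write.csv(inter, file.path(out, paste0(f$fov_id, "_intersections.csv")),
                       row.names = FALSE)
      if (isTRUE(qc_overlays)) {
        for (r in ts$results) {
          write_qc_overlay(r, file.path(out, sprintf("%s_%s_qc.png", r$fov_id, r$timepoint)))
        }
      }
      series_rows[[f$fov_id]] <- ts$table
      list(ok = TRUE, message = "ok", timepoints = nrow(ts$table))
    }, error = function(e) list(ok = FALSE, message = conditionMessage(e), timepoints = 0L))
    status[[f$fov_id]] <- res
  }
  if (!any(vapply(status, `[[`, logical(1), "ok"))) {
    stop("all FOVs failed; see run log messages", call. = FALSE)
  }
  series <- do.call(rbind, series_rows)
  rownames(series) <- NULL
  utils::write.csv(series, file.path(out, "series_indices.csv"), row.names = FALSE)
  log <- list(
    package = "ivmflow",
    version = as.character(utils::packageVersion("ivmflow")),
    seed = manifest$seed,
    params = params,
    fovs = lapply(status, function(s) s[c("ok", "message", "timepoints")])
  )
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(series)
}

#' Simulate a set of acquisitions to disk
#'
#' Generates one synthetic FOV per entry of `perfused_fractions` per
#' timepoint, writes the TIFF stacks (+ JSON sidecars), the ground truth
#' (vessel polylines, labels, drift) as JSON, the vessel/perfused masks as
#' TIFF, and an analysis manifest covering the whole set. Later timepoints
#' reuse the baseline network (with the configured per-timepoint drift and
#' their own perfusion labels), mimicking repeated observation of one FOV.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param n_fov Number of FOVs.
#' @param timepoints Character vector of timepoint labels, baseline first.
#' @param perfused_fractions Per-timepoint perfused fraction (recycled);
#'   defaults to `config$perfused_fraction` everywhere.
#' @param seed Master seed; per-FOV/timepoint streams derive from it.
#' @return Path of the written manifest YAML.
#' @export
simulate_acquisitions <- function(config, out_dir, n_fov = 1L,
                                  timepoints = "baseline",
                                  perfused_fractions = NULL, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nt <- length(timepoints)
  fracs <- rep(perfused_fractions %||% config$perfused_fraction, length.out = nt)
  fovs <- list()
  for (i in seq_len(n_fov)) {
    fov_id <- sprintf("fov%02d", i)
    net0 <- generate_network(config, seed = derive_seed(seed, paste0(fov_id, "-net")))
    tps <- list()
    gt_all <- list()
    for (j in seq_len(nt)) {
      net <- assign_perfusion(net0, fracs[j],
                              seed = derive_seed(seed, paste0(fov_id, "-perf-", j)))
      drift <- round(config$drift_per_timepoint * (j - 1L))
      out <- render_video(net, config, drift_px = drift,
                          timepoint = timepoints[j], fov_id = fov_id,
                          seed = derive_seed(seed, paste0(fov_id, "-render-", j)))
      stack_path <- file.path(out_dir, sprintf("%s_%s.tif", fov_id, timepoints[j]))
      write_stack(out$video, stack_path)
      gt <- out$ground_truth
      gt_all[[timepoints[j]]] <- list(
        applied_drift = gt$applied_drift,
        segment_labels = as.list(gt$segment_labels),
        segments = lapply(gt$network$segments, function(s) {
          list(id = s$id, diameter_um = s$diameter_um, perfused = s$perfused,
               rbc_velocity_um_s = s$rbc_velocity_um_s,
               centerline = unname(apply(s$centerline, 1, as.numeric, simplify = FALSE)))
        })
      )
      write_stack(array(gt$vessel_mask * 65535L, dim = c(dim(gt$vessel_mask), 1)),
                  file.path(out_dir, sprintf("%s_%s_vessel_mask.tif", fov_id, timepoints[j])),
                  sidecar = FALSE)
      tps[[j]] <- list(label = timepoints[j], path = basename(stack_path))
    }
    jsonlite::write_json(gt_all,
                         file.path(out_dir, paste0(fov_id, "_ground_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    fovs[[i]] <- list(fov_id = fov_id, pixel_size = config$pixel_size_um,
                      frame_rate = config$frame_rate, timepoints = tps)
  }
  manifest <- list(seed = as.integer(seed), output_dir = "results",
                   params = list(), fovs = fovs)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
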