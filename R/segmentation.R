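# Vessel geometry extraction from SAD images: global thresholding,
# morphological cleanup, and topological thinning to 1-px centerlines.
# No image-processing package exists in this R stack, so the classical
# operators (Otsu, closing, Zhang-Suen thinning) are implemented here;
# connected-component labelling goes through igraph on the pixel grid.

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v, n_bins = 256L) {
  rng <- range(v)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(Inf)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- as.numeric(tabulate(findInterval(v, breaks, rightmost.closed = TRUE), n_bins))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  w0 <- w[-n_bins]; w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m[-n_bins] / w0
  mu1 <- (total_m - m[-n_bins]) / w1
  between <- w0 * w1 * (mu0 - mu1)^2
  between[!valid] <- -Inf
  k <- which.max(between)
  breaks[k + 1L]
}

# Binary dilation/erosion with a disc structuring element, by shifting.
disc_offsets <- function(radius) {
  R <- as.integer(ceiling(radius))
  off <- expand.grid(dr = -R:R, dc = -R:R)
  off[off$dr^2 + off$dc^2 <= radius^2, , drop = FALSE]
}

binary_dilate <- function(mask, offsets) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out | shift_matrix(mask, offsets$dr[i], offsets$dc[i], fill = FALSE)
  }
  out
}

binary_erode <- function(mask, offsets) {
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offsets))) {
    out <- out & shift_matrix(mask, offsets$dr[i], offsets$dc[i], fill = FALSE)
  }
  out
}

binary_close <- function(mask, radius) {
  if (radius <= 0) return(mask)
  off <- disc_offsets(radius)
  binary_erode(binary_dilate(mask, off), off)
}

# Remove 8-connected components smaller than min_px (igraph components on
# the pixel adjacency graph).
remove_small_objects <- function(mask, min_px) {
  if (min_px <= 1L || !any(mask)) return(mask)
  nr <- nrow(mask)
  idx <- which(mask)
  edges <- list()
  k <- 1L
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    both <- mask & shift_matrix(mask, -d[1], -d[2], fill = FALSE)
    from <- which(both)
    if (length(from)) {
      edges[[k]] <- cbind(from, from + d[1] + d[2] * nr)
      k <- k + 1L
    }
  }
  vert <- as.character(idx)
  g <- igraph::graph_from_data_frame(
    if (length(edges)) {
      e <- do.call(rbind, edges)
      data.frame(from = as.character(e[, 1]), to = as.character(e[, 2]))
    } else data.frame(from = character(0), to = character(0)),
    directed = FALSE,
    vertices = data.frame(name = vert)
  )
  comp <- igraph::components(g)
  keep_comp <- which(comp$csize >= min_px)
  keep <- idx[comp$membership %in% keep_comp]
  out <- matrix(FALSE, nr, ncol(mask))
  out[keep] <- TRUE
  out
}

# Zhang-Suen topological thinning to 1-px-wide skeleton (vectorized).
zhang_suen_thin <- function(mask) {
  m <- mask
  nbr <- function(m) {
    list(
      p2 = shift_matrix(m, 1L, 0L, FALSE),   # north neighbor value at (r,c)
      p3 = shift_matrix(m, 1L, -1L, FALSE),
      p4 = shift_matrix(m, 0L, -1L, FALSE),
      p5 = shift_matrix(m, -1L, -1L, FALSE),
      p6 = shift_matrix(m, -1L, 0L, FALSE),
      p7 = shift_matrix(m, -1L, 1L, FALSE),
      p8 = shift_matrix(m, 0L, 1L, FALSE),
      p9 = shift_matrix(m, 1L, 1L, FALSE)
    )
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- nbr(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqn <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      A <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) A <- A + (!seqn[[i]] & seqn[[i + 1L]])
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (pass == 1) {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p6) & !(nb$p4 & nb$p6 & nb$p8)
      } else {
        cond <- cond & !(nb$p2 & nb$p4 & nb$p8) & !(nb$p2 & nb$p6 & nb$p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Segment the perfused vessel structure from a SAD image
#'
#' Global thresholding of the SAD image (Otsu by default, or a fixed upper
#' quantile), followed by morphological closing, removal of small objects,
#' and topological thinning to a one-pixel-wide skeleton. Because the SAD
#' image is bright only where red blood cells move, the resulting mask is
#' the geometry of the *actively perfused* vasculature; static (unperfused)
#' vessel silhouettes do not appear. `NA` pixels (registration sentinels)
#' are excluded from threshold estimation and never enter the mask.
#'
#' @param sad A `sad_image`.
#' @param method `"otsu"` (default) or `"quantile"`.
#' @param min_object_px Connected components smaller than this are removed.
#' @param close_radius Disc radius for morphological closing, px.
#' @param quantile Threshold quantile for `method = "quantile"`.
#' @return A list of class `vessel_mask_result`: `mask`, `skeleton`
#'   (logical matrices), `threshold_used`, `method`.
#' @export
segment_vessels <- function(sad, method = c("otsu", "quantile"),
                            min_object_px = 30L, close_radius = 1,
                            quantile = 0.90) {
  stopifnot(inherits(sad, "sad_image"))
  method <- match.arg(method)
  v <- sad$values
  valid <- is.finite(v)
  empty <- function(thr) {
    m <- matrix(FALSE, nrow(v), ncol(v))
    structure(list(mask = m, skeleton = m, threshold_used = thr, method = method),
              class = "vessel_mask_result")
  }
  if (!any(valid)) return(empty(Inf))
  vv <- v[valid]
  if (diff(range(vv)) == 0) return(empty(Inf))
  thr <- switch(method,
    otsu = otsu_threshold(vv),
    quantile = as.numeric(stats::quantile(vv, quantile))
  )
  mask <- !is.na(v) & v >= thr
  mask[!valid] <- FALSE
  mask <- binary_close(mask, close_radius)
  mask[!valid] <- FALSE
  mask <- remove_small_objects(mask, as.integer(min_object_px))
  skeleton <- zhang_suen_thin(mask)
  structure(
    list(mask = mask, skeleton = skeleton, threshold_used = thr, method = method),
    class = "vessel_mask_result"
  )
}

#' @export
print.vessel_mask_result <- function(x, ...) {
  cat(sprintf("vessel mask (%s, thr %.4g): %d mask px, %d skeleton px\n",
              x$method, x$threshold_used, sum(x$mask), sum(x$skeleton)))
  invisible(x)
}
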