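# Radiograph binning with intrapixel statistics, distance-driven-binning
# (DDB) filtered backprojection of list-mode WEPL data, and tomographic
# noise reconstruction by backprojection of the per-bin WET standard error
# convolved with the squared ramp filter.

#' Bin a radiograph from list-mode events
#'
#' Bins the WEPL of every event into a transverse pixel grid at the front
#' or rear tracker plane and computes per-pixel count, mean and sample
#' standard deviation (the intrapixel noise).
#'
#' @param events Event `data.frame`.
#' @param plane `"front"` (entrance measurement, default) or `"rear"`.
#' @param pixel Pixel size in mm.
#' @return Object of class `radiograph`: list with matrices `count`,
#'   `mean`, `sd` (y rows x z columns; `sd` is `NA` where fewer than two
#'   events) and pixel-centre coordinates `y`, `z`.
#' @export
bin_radiograph <- function(events, plane = c("front", "rear"), pixel = 1) {
  plane <- match.arg(plane)
  yy <- if (plane == "front") events$y0 else events$y1
  zz <- if (plane == "front") events$z0 else events$z1
  iy <- floor(yy / pixel); iz <- floor(zz / pixel)
  oy <- min(iy); oz <- min(iz)
  ny <- max(iy) - oy + 1L; nz <- max(iz) - oz + 1L
  idx <- (iy - oy) + (iz - oz) * ny + 1L
  np <- ny * nz
  cnt <- tabulate(idx, np)
  g <- rowsum(cbind(events$wepl, events$wepl^2), idx)
  s1 <- s2 <- numeric(np)
  i <- as.integer(rownames(g))
  s1[i] <- g[, 1]; s2[i] <- g[, 2]
  mu <- ifelse(cnt > 0, s1 / cnt, NA_real_)
  sd <- ifelse(cnt > 1, sqrt(pmax(s2 - cnt * mu^2, 0) / (cnt - 1)), NA_real_)
  structure(list(
    count = matrix(cnt, ny, nz), mean = matrix(mu, ny, nz),
    sd = matrix(sd, ny, nz),
    y = (seq_len(ny) - 1 + oy + 0.5) * pixel,
    z = (seq_len(nz) - 1 + oz + 0.5) * pixel,
    pixel = pixel, plane = plane
  ), class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("<radiograph> %d x %d pixels (%g mm, %s plane), %d events\n",
              length(x$y), length(x$z), x$pixel, x$plane, sum(x$count)))
  invisible(x)
}

#' Mean noise profile of a radiograph
#'
#' Averages the per-pixel WEPL standard deviation along the vertical (z)
#' direction, producing one horizontal noise profile. Pixels with fewer
#' than two events are excluded; empty columns yield `NA`.
#'
#' @param grid A [bin_radiograph()] result.
#' @param band Optional z-range `c(lo, hi)` in mm restricting the vertical
#'   average (e.g. a few rows around the centre for experimental-style
#'   protocols); default: full height.
#' @return `data.frame` with `y` (column centre, mm), `noise` (mm WET) and
#'   `n_pixels` contributing.
#' @export
noise_profile <- function(grid, band = NULL) {
  keep_z <- if (is.null(band)) rep(TRUE, length(grid$z)) else
    grid$z >= band[1] & grid$z <= band[2]
  sdm <- grid$sd[, keep_z, drop = FALSE]
  noise <- apply(sdm, 1, function(r) if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE))
  n_px <- apply(sdm, 1, function(r) sum(!is.na(r)))
  data.frame(y = grid$y, noise = noise, n_pixels = n_px)
}

#' Spatial-domain Ram-Lak (ramp) convolution kernel
#'
#' The band-limited ramp filter sampled at `spacing`: central tap
#' `1/(4 spacing^2)`, odd taps `-1/(pi^2 k^2 spacing^2)`, even taps zero.
#' The truncation residual of the infinite kernel is removed at the two
#' outermost taps so the kernel has an exactly zero DC response (constant
#' projections reconstruct to zero).
#'
#' @param length Odd kernel length (>= 3).
#' @param spacing Sample spacing in mm.
#' @return Numeric kernel of the requested length (units 1/mm^2).
#' @export
ramlak_kernel <- function(length, spacing = 1) {
  if (length < 3) stop("ramlak_kernel: length must be >= 3")
  if (length %% 2 == 0) length <- length + 1
  half <- (length - 1) / 2
  kk <- -half:half
  h <- ifelse(kk == 0, 1 / (4 * spacing^2),
              ifelse(kk %% 2 != 0, -1 / (pi^2 * kk^2 * spacing^2), 0))
  resid <- sum(h)
  h[c(1, length)] <- h[c(1, length)] - resid / 2
  h
}

# FFT convolution of each row of `mat` (rows x samples) with `kern`,
# keeping the central `ncol(mat)` samples ("same" convolution)
.conv_rows <- function(mat, kern) {
  ns <- ncol(mat); nk <- length(kern)
  M <- stats::nextn(ns + nk - 1)
  K <- stats::fft(c(kern, numeric(M - nk)))
  pad <- matrix(0, nrow(mat), M)
  pad[, seq_len(ns)] <- mat
  FM <- t(stats::mvfft(t(pad)))
  conv <- Re(t(stats::mvfft(t(FM * rep(K, each = nrow(mat))), inverse = TRUE))) / M
  off <- (nk - 1) / 2
  conv[, off + seq_len(ns), drop = FALSE]
}

# Distance-driven binning of one projection: WEPL statistics per
# (depth, lateral) bin along each event's path. Returns mean, sd, count
# matrices (depth rows x lateral bins).
.ddb_bin <- function(ev, xd, lat_edges_n, lat_bin, fov, hull, x0, x1, ang) {
  m <- nrow(ev); D <- length(xd)
  if (is.null(hull)) {
    # straight chord between the two tracker measurements
    u <- rep(x0, m); v <- rep(x1, m)
    sl <- (ev$y1 - ev$y0) / (x1 - x0)
    XD <- matrix(xd, m, D, byrow = TRUE)
    Y <- ev$y0 + (XD - x0) * sl
  } else {
    a <- .mlp_anchor(hull, x0, ev$y0, ev$th_y0, x1, ev$y1, ev$th_y1, angle = ang)
    L <- a$v - a$u
    XD <- matrix(xd, m, D, byrow = TRUE)
    t <- (XD - a$u) / ifelse(L > 0, L, 1)
    tc <- pmin(pmax(t, 0), 1)
    h <- .hermite(tc)
    spl <- h$h00 * a$yu + h$h10 * L * ev$th_y0 + h$h01 * a$yv + h$h11 * L * ev$th_y1
    s_in <- ev$y0 + (XD - x0) * ev$th_y0
    s_out <- ev$y1 + (XD - x1) * ev$th_y1
    Y <- ifelse(XD <= a$u, s_in, ifelse(XD >= a$v, s_out, spl))
    Y[a$miss | L <= 0] <- (s_in)[a$miss | L <= 0]
  }
  # bins live in the projection (lab) frame: depth along the beam axis,
  # lateral perpendicular to it; the projection angle only enters at
  # backprojection time
  dstep <- xd[2] - xd[1]
  di <- round((XD - xd[1]) / dstep) + 1
  li <- floor((Y + fov / 2) / lat_bin) + 1
  ok <- di >= 1 & di <= D & li >= 1 & li <= lat_edges_n
  code <- (di[ok] - 1) * lat_edges_n + li[ok]
  w <- rep(ev$wepl, D)[ok]
  np <- D * lat_edges_n
  cnt <- tabulate(code, np)
  s1 <- s2 <- numeric(np)
  gs <- rowsum(cbind(w, w^2), code)
  i <- as.integer(rownames(gs))
  s1[i] <- gs[, 1]; s2[i] <- gs[, 2]
  mu <- ifelse(cnt > 0, s1 / cnt, 0)
  va <- ifelse(cnt > 1, pmax(s2 - cnt * mu^2, 0) / (cnt - 1), NA_real_)
  list(mean = matrix(mu, D, lat_edges_n, byrow = TRUE),
       var = matrix(va, D, lat_edges_n, byrow = TRUE),
       count = matrix(cnt, D, lat_edges_n, byrow = TRUE))
}

# shared geometry setup for the tomographic operators
.tomo_setup <- function(events, n_grid, fov, depth_step) {
  geom <- attr(events, "geometry")
  x0 <- if (!is.null(geom)) geom$x0 else -150
  x1 <- if (!is.null(geom)) geom$x1 else 150
  half_d <- ceiling(fov / 2 * sqrt(2)) + 2
  xd <- seq(-half_d, half_d, by = depth_step)
  lat_bin <- fov / n_grid
  ctr <- (seq_len(n_grid) - (n_grid + 1) / 2) * lat_bin
  px <- matrix(ctr, n_grid, n_grid)
  py <- matrix(ctr, n_grid, n_grid, byrow = TRUE)
  list(x0 = x0, x1 = x1, xd = xd, lat_bin = lat_bin, nlat = n_grid,
       ctr = ctr, px = px, py = py)
}

# backprojection of filtered rows into the phantom-frame grid: bilinear in
# the lateral coordinate, nearest depth row
.backproject <- function(filt, gs, ang) {
  phi <- ang * pi / 180
  cp <- cos(phi); sp <- sin(phi)
  xl <- cp * gs$px - sp * gs$py
  yl <- sp * gs$px + cp * gs$py
  # phantom-frame pixel expressed in this projection's (depth, lateral)
  di <- round((xl - gs$xd[1]) / (gs$xd[2] - gs$xd[1])) + 1
  fl <- (yl + gs$nlat * gs$lat_bin / 2) / gs$lat_bin + 0.5
  l0 <- floor(fl); fr <- fl - l0
  ok <- di >= 1 & di <= length(gs$xd) & l0 >= 1 & l0 < gs$nlat
  out <- matrix(0, nrow(gs$px), ncol(gs$px))
  ii <- which(ok)
  v0 <- filt[cbind(di[ii], l0[ii])]
  v1 <- filt[cbind(di[ii], l0[ii] + 1L)]
  out[ii] <- v0 * (1 - fr[ii]) + v1 * fr[ii]
  out
}

#' Distance-driven-binning tomographic reconstruction
#'
#' For each projection, deposits every event's WEPL along its path into
#' depth-resolved lateral bins, ramp-filters (Ram-Lak) each depth row, and
#' backprojects the filtered rows (parallel geometry, each image pixel
#' reading from the row at its own depth) with `pi/n_projections`
#' weighting. The summed image approximates the RSP map of the central
#' slice.
#'
#' @param events Event `data.frame` covering the projection angles (column
#'   `angle_deg`); at least two projections spanning 180 degrees are
#'   expected.
#' @param n_grid Reconstruction grid size (default 320).
#' @param fov Field of view in mm (default 200; 0.625 mm pixels).
#' @param depth_step Depth bin spacing along the beam axis (mm).
#' @param hull Optional [convex_hull()] used for the spline most-likely
#'   path; without it paths are straight tracker-to-tracker chords.
#' @return Object of class `tomo_grid`: `values` (n x n matrix, RSP),
#'   pixel-centre coordinates `x`, `y` and the geometry.
#' @export
ddb_reconstruct <- function(events, n_grid = 320, fov = 200, depth_step = 1,
                            hull = NULL) {
  angles <- sort(unique(events$angle_deg))
  if (length(angles) < 2) warning("ddb_reconstruct: fewer than 2 projection angles")
  span <- max(angles) - min(angles)
  if (length(angles) >= 2 && span + (angles[2] - angles[1]) < 179)
    warning("ddb_reconstruct: angular coverage below 180 degrees; expect artifacts")
  gs <- .tomo_setup(events, n_grid, fov, depth_step)
  kern <- ramlak_kernel(2 * n_grid - 1, gs$lat_bin)
  wgt <- pi / length(angles)
  acc <- matrix(0, n_grid, n_grid)
  for (ang in angles) {
    ev <- events[events$angle_deg == ang, ]
    bb <- .ddb_bin(ev, gs$xd, gs$nlat, gs$lat_bin, fov, hull, gs$x0, gs$x1, ang)
    filt <- .conv_rows(bb$mean, kern) * gs$lat_bin
    acc <- acc + wgt * .backproject(filt, gs, ang)
  }
  structure(list(values = acc, x = gs$ctr, y = gs$ctr, fov = fov,
                 pixel = gs$lat_bin, what = "rsp"),
            class = "tomo_grid")
}

#' Tomographic noise reconstruction
#'
#' Backprojects, per projection and depth row, the squared standard error
#' of the binned WET (`sd^2 / N` per bin) convolved with the squared
#' Ram-Lak kernel; the summed variance map is returned as its square root
#' (intrapixel noise in RSP units). Bins with fewer than two events take
#' their variance from lateral neighbours by interpolation.
#'
#' `variance_mode = "per-count"` applies the printed normalisation
#' literally with the standard error already squared (an additional `1/N`),
#' for comparison; the default reading is the one consistent with sampling
#' theory and the `1/sqrt(N)` scaling of reconstruction noise.
#'
#' @inheritParams ddb_reconstruct
#' @param variance_mode `"standard-error"` (default) or `"per-count"`.
#' @return A `tomo_grid` with `what = "noise"`.
#' @export
noise_reconstruct <- function(events, n_grid = 320, fov = 200, depth_step = 1,
                              hull = NULL,
                              variance_mode = c("standard-error", "per-count")) {
  variance_mode <- match.arg(variance_mode)
  angles <- sort(unique(events$angle_deg))
  gs <- .tomo_setup(events, n_grid, fov, depth_step)
  kern2 <- ramlak_kernel(2 * n_grid - 1, gs$lat_bin)^2
  wgt <- pi / length(angles)
  acc <- matrix(0, n_grid, n_grid)
  for (ang in angles) {
    ev <- events[events$angle_deg == ang, ]
    bb <- .ddb_bin(ev, gs$xd, gs$nlat, gs$lat_bin, fov, hull, gs$x0, gs$x1, ang)
    se2 <- bb$var / pmax(bb$count, 1)
    if (variance_mode == "per-count") se2 <- se2 / pmax(bb$count, 1)
    # fill undefined bins from lateral neighbours
    se2 <- t(apply(se2, 1, function(r) {
      if (all(is.na(r))) return(rep(0, length(r)))
      idx <- which(!is.na(r))
      stats::approx(idx, r[idx], xout = seq_along(r), rule = 2)$y
    }))
    filt <- .conv_rows(se2, kern2) * gs$lat_bin^2
    acc <- acc + wgt^2 * .backproject(filt, gs, ang)
  }
  structure(list(values = sqrt(pmax(acc, 0)), x = gs$ctr, y = gs$ctr,
                 fov = fov, pixel = gs$lat_bin, what = "noise"),
            class = "tomo_grid")
}

#' @export
print.tomo_grid <- function(x, ...) {
  cat(sprintf("<tomo_grid> %s map, %d x %d pixels (%g mm), FOV %g mm\n",
              x$what, length(x$x), length(x$y), x$pixel, x$fov))
  invisible(x)
}
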