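# Straight-line exit prediction (transvection) and the phenomenological
# cubic-spline most-likely-path through a prior RSP image. Small-angle
# optics: directions are tangents dy/dx (rad), paths are parameterised by
# the beam-axis coordinate x and arc length is approximated by x.

#' Project a parameter vector along a straight line
#'
#' Applies the transvection `R0`: `y -> y + (x1 - x) * theta`, `theta`
#' unchanged. This is the predicted exit measurement for an unscattered
#' particle.
#'
#' @param Y `data.frame` (or list) with fields `y` (mm), `theta` (rad) and
#'   `x` (mm), vectorised over rows.
#' @param x1 Target plane (mm), `x1 >= x`.
#' @return `data.frame` with the projected `y`, `theta`, `x = x1`.
#' @export
project_straight <- function(Y, x1) {
  if (any(x1 < Y$x)) stop("project_straight: target plane upstream of vector")
  data.frame(y = Y$y + (x1 - Y$x) * Y$theta, theta = Y$theta, x = x1)
}

# Hermite basis on t in [0,1]
.hermite <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  list(h00 = 2 * t3 - 3 * t2 + 1, h10 = t3 - 2 * t2 + t,
       h01 = -2 * t3 + 3 * t2, h11 = t3 - t2)
}

# Vectorised MLP machinery shared by spline_mlp, the likelihood filter and
# the distance-driven binning. Computes, per event, the hull crossing of the
# entrance ray (clipped forward) and of the exit ray (clipped backward).
# Measurements are given in the lab frame (beam along +x); the hull lives in
# the phantom frame, rotated by the projection angle (degrees) about z.
# Crossing parameters are reported as lab-x offsets, so u and v are lab-x
# coordinates of the hull boundaries. Events that miss the hull get u = v.
.mlp_anchor <- function(hull, x0, y0, ty0, x1, y1, ty1, angle = 0) {
  n <- length(y0)
  if (is.null(hull$vertices)) {
    mid <- rep((mean(x0) + mean(x1)) / 2, n)
    return(list(u = mid, v = mid, yu = NA_real_, yv = NA_real_, miss = rep(TRUE, n)))
  }
  phi <- angle * pi / 180
  cp <- cos(phi); sp <- sin(phi)
  rot_o <- function(x, y) cbind(cp * x + sp * y, -sp * x + cp * y)
  rot_d <- function(ty) cbind(cp + sp * ty, -sp + cp * ty)
  hin <- ray_hull_entry_exit(rot_o(rep_len(x0, n), y0), rot_d(ty0), hull)
  hout <- ray_hull_entry_exit(rot_o(rep_len(x1, n), y1), rot_d(ty1), hull)
  miss <- is.na(hin$t0) | is.na(hout$t1)
  u <- x0 + hin$t0
  # the hull lies upstream of the rear tracker: its downstream boundary is
  # the "leaving" crossing of the exit ray (clamped at the tracker plane)
  v <- x1 + pmin(hout$t1, 0)
  yu <- y0 + hin$t0 * ty0
  yv <- y1 + (v - x1) * ty1
  bad <- miss | !(v > u)
  u[bad] <- (x0 + x1) / 2; v[bad] <- u[bad]
  list(u = u, v = v, yu = yu, yv = yv, miss = bad)
}

# Evaluate the lateral coordinate of the spline MLP at given x for one
# plane. All arguments vectorised over events; xq may be a vector (same
# length) or a matrix (events x depths).
.mlp_lateral <- function(xq, x0, y0, ty0, x1, y1, ty1, u, v, yu, yv, miss) {
  L <- v - u
  straight_in <- y0 + (xq - x0) * ty0
  straight_out <- y1 + (xq - x1) * ty1
  t <- (xq - u) / ifelse(L > 0, L, 1)
  h <- .hermite(pmin(pmax(t, 0), 1))
  spl <- h$h00 * yu + h$h10 * L * ty0 + h$h01 * yv + h$h11 * L * ty1
  out <- ifelse(xq <= u, straight_in, ifelse(xq >= v, straight_out, spl))
  bad <- rep_len(miss | L <= 0, length(out))
  ifelse(bad, straight_in, out)
}

#' Most-likely-path estimate by a phenomenological cubic spline
#'
#' Between the trackers the path is a straight line in air up to the hull,
#' a cubic Hermite segment inside the hull (interpolating the hull-boundary
#' positions, with tangents along the measured entrance/exit directions
#' scaled by the hull chord length, hence C1 at the boundaries), and a
#' straight line from the hull to the rear tracker. When the rays miss the
#' hull the path degenerates to the entrance straight line.
#'
#' @param entry,exit Lists with fields `x`, `y`, `z`, `theta_y`, `theta_z`:
#'   the front/rear tracker measurements of one particle (mm, rad).
#' @param hull A [convex_hull()] of the prior image (the y-plane hull also
#'   bounds the z extent of the object, which is assumed z-invariant).
#' @param step Sampling step along x in mm (default 1).
#' @return `data.frame` of class `path_estimate` with columns `x`, `y`, `z`.
#' @export
spline_mlp <- function(entry, exit, hull, step = 1) {
  if (exit$x <= entry$x) stop("spline_mlp: exit plane upstream of entry plane")
  xq <- seq(entry$x, exit$x, by = step)
  if (xq[length(xq)] < exit$x) xq <- c(xq, exit$x)
  a <- .mlp_anchor(hull, entry$x, entry$y, entry$theta_y,
                   exit$x, exit$y, exit$theta_y)
  yy <- .mlp_lateral(xq, entry$x, entry$y, entry$theta_y,
                     exit$x, exit$y, exit$theta_y,
                     a$u, a$v, a$yu, a$yv, a$miss)
  # z-plane: independent spline sharing the x-parameterisation and the hull
  # x-range found in the bending (y) plane
  zu <- entry$z + (a$u - entry$x) * entry$theta_z
  zv <- exit$z + (a$v - exit$x) * exit$theta_z
  zz <- .mlp_lateral(xq, entry$x, entry$z, entry$theta_z,
                     exit$x, exit$z, exit$theta_z,
                     a$u, a$v, zu, zv, a$miss)
  structure(data.frame(x = xq, y = yy, z = zz),
            class = c("path_estimate", "data.frame"))
}

#' Line integral of a prior RSP map along a path
#'
#' Predicted water-equivalent path length: the prior RSP sampled along the
#' path (bilinear in-plane, nearest slice) and integrated at the path's
#' x-resolution (trapezoidal rule; arc length approximated by x under the
#' small-angle model).
#'
#' @param path A [spline_mlp()] path (or any data.frame with `x`, `y`, `z`).
#' @param prior An [rsp_image()].
#' @return Predicted WEPL in mm.
#' @export
predicted_exit_wepl <- function(path, prior) {
  r <- sample_rsp(prior, path$x, path$y, path$z)
  .trapz(path$x, r)
}
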