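# RSP voxel maps, analytic phantom constructors, convex hulls and
# ray-hull intersection. Axis convention: x = beam axis, y = lateral,
# z = vertical; phantoms are described in their own (unrotated) frame with
# the origin at the phantom centre. World coordinates refer to voxel
# centres; voxels are half-open.

#' Relative stopping power voxel image
#'
#' @param values 3D numeric array of RSP values (dimensions x, y, z; x
#'   fastest in storage). All values must be non-negative.
#' @param spacing Voxel spacing in mm, length-3 (or scalar, recycled).
#' @param origin World coordinates (mm) of the centre of voxel
#'   `[1, 1, 1]`. Defaults to centring the grid on (0, 0, 0).
#' @return Object of class `rsp_image`.
#' @export
rsp_image <- function(values, spacing = 1, origin = NULL) {
  if (length(dim(values)) != 3) stop("rsp_image: values must be a 3D array")
  if (any(values < 0)) stop("rsp_image: RSP must be non-negative")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("rsp_image: spacing must be positive")
  if (is.null(origin)) origin <- -(dim(values) - 1) / 2 * spacing
  structure(list(values = values, spacing = spacing, origin = as.numeric(origin)),
            class = "rsp_image")
}

#' @export
print.rsp_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<rsp_image> %d x %d x %d voxels, spacing (%g, %g, %g) mm, RSP in [%g, %g]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$values), max(x$values)))
  invisible(x)
}

# world coordinates of voxel centres along one axis
.axis_coords <- function(img, axis) {
  img$origin[axis] + (seq_len(dim(img$values)[axis]) - 1) * img$spacing[axis]
}

#' Uniform cylinder phantom
#'
#' A cylinder of constant RSP with its axis along z, centred at the origin.
#' Voxels outside the cylinder are 0 (air is modelled as RSP 0 for energy
#' loss; its radiation length is handled separately by the scattering
#' models).
#'
#' @param diameter Cylinder diameter in mm (> 0).
#' @param rsp RSP inside the cylinder (default 1.0, water).
#' @param spacing Voxel spacing in mm.
#' @param margin Air margin around the cylinder in mm.
#' @param height Grid extent along z in mm.
#' @param grid Optional explicit grid: list with `dim` (length 3) and
#'   `spacing`; the cylinder must fit inside it.
#' @return An [rsp_image()].
#' @export
make_cylinder <- function(diameter, rsp = 1, spacing = 1, margin = 10,
                          height = 40, grid = NULL) {
  if (diameter < 0) stop("make_cylinder: diameter must be non-negative")
  r <- diameter / 2
  if (is.null(grid)) {
    half <- ceiling((r + margin) / spacing)
    n <- 2L * half + 1L
    nz <- 2L * ceiling(height / 2 / spacing) + 1L
    dims <- c(n, n, nz)
    sp3 <- rep_len(spacing, 3)
  } else {
    dims <- grid$dim
    sp3 <- rep_len(grid$spacing, 3)
    if (r > (dims[1] - 1) / 2 * sp3[1] || r > (dims[2] - 1) / 2 * sp3[2])
      stop("make_cylinder: cylinder exceeds grid")
  }
  vals <- array(0, dims)
  xc <- (seq_len(dims[1]) - (dims[1] + 1) / 2) * sp3[1]
  yc <- (seq_len(dims[2]) - (dims[2] + 1) / 2) * sp3[2]
  inside <- outer(xc^2, yc^2, `+`) < r^2 # strict: a zero-diameter cylinder is empty
  vals[] <- rep(as.numeric(inside) * rsp, dims[3])
  rsp_image(vals, sp3)
}

#' Cylindrical phantom with cylindrical inserts
#'
#' A uniform body cylinder composed with cylindrical inserts (axes along z),
#' applied in order with last-writer-wins semantics. Mirrors the layout of
#' sensitometry modules used to assess RSP accuracy.
#'
#' @param body_diameter Body diameter in mm.
#' @param inserts `data.frame` with columns `x`, `y` (insert centres, mm),
#'   `diameter` (mm) and `rsp`; optionally `name`.
#' @param body_rsp RSP of the body material (default 1.0).
#' @inheritParams make_cylinder
#' @return An [rsp_image()]; insert geometry is attached as attribute
#'   `"inserts"`.
#' @export
make_insert_phantom <- function(body_diameter, inserts, body_rsp = 1,
                                spacing = 1, margin = 10, height = 40) {
  img <- make_cylinder(body_diameter, body_rsp, spacing, margin, height)
  if (nrow(inserts)) {
    rb <- body_diameter / 2
    d <- sqrt(inserts$x^2 + inserts$y^2) + inserts$diameter / 2
    if (any(d > rb)) stop("make_insert_phantom: insert outside body")
    if (nrow(inserts) > 1) {
      for (i in seq_len(nrow(inserts) - 1)) for (j in (i + 1):nrow(inserts)) {
        dd <- sqrt((inserts$x[i] - inserts$x[j])^2 + (inserts$y[i] - inserts$y[j])^2)
        if (dd < (inserts$diameter[i] + inserts$diameter[j]) / 2)
          warning("make_insert_phantom: overlapping inserts; later entries override")
      }
    }
    xc <- .axis_coords(img, 1)
    yc <- .axis_coords(img, 2)
    nz <- dim(img$values)[3]
    for (i in seq_len(nrow(inserts))) {
      m <- outer((xc - inserts$x[i])^2, (yc - inserts$y[i])^2, `+`) <
        (inserts$diameter[i] / 2)^2
      idx <- which(m)
      if (length(idx)) {
        plane <- dim(img$values)[1] * dim(img$values)[2]
        full <- rep(idx, nz) + rep((0:(nz - 1)) * plane, each = length(idx))
        img$values[full] <- inserts$rsp[i]
      }
    }
  }
  attr(img, "inserts") <- inserts
  img
}

#' Sample an RSP image at world coordinates
#'
#' Bilinear interpolation in the transverse (x, y) plane and nearest
#' neighbour along z (phantom slices). Points outside the grid sample 0.
#'
#' @param img An [rsp_image()].
#' @param x,y,z World coordinates in mm (vectorised, equal length or
#'   scalar `z`).
#' @return RSP values.
#' @export
sample_rsp <- function(img, x, y, z = 0) {
  d <- dim(img$values)
  sp <- img$spacing; o <- img$origin
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  fz <- (z - o[3]) / sp[3]
  iz <- pmin.int(pmax.int(round(fz) + 1, 1L), d[3])
  fx <- (x - o[1]) / sp[1]
  fy <- (y - o[2]) / sp[2]
  i0 <- floor(fx); j0 <- floor(fy)
  wx <- fx - i0; wy <- fy - j0
  i0 <- i0 + 1; j0 <- j0 + 1
  ok <- i0 >= 1 & i0 < d[1] & j0 >= 1 & j0 < d[2] &
    fz > -0.5 & fz < d[3] - 0.5
  out <- numeric(n)
  if (any(ok)) {
    i <- i0[ok]; j <- j0[ok]; kk <- iz[ok]
    ax <- wx[ok]; ay <- wy[ok]
    v <- img$values
    v00 <- v[cbind(i, j, kk)]
    v10 <- v[cbind(i + 1L, j, kk)]
    v01 <- v[cbind(i, j + 1L, kk)]
    v11 <- v[cbind(i + 1L, j + 1L, kk)]
    out[ok] <- (1 - ax) * (1 - ay) * v00 + ax * (1 - ay) * v10 +
      (1 - ax) * ay * v01 + ax * ay * v11
  }
  out
}

# ---- convex hull ------------------------------------------------------------

#' Convex hull of the object support
#'
#' Per-slice convex polygon containing every voxel whose RSP exceeds the
#' threshold, taken from the central z slice (phantoms are assumed
#' z-invariant over the imaged band). Paths are straight lines outside the
#' hull; inside, the most-likely-path spline applies.
#'
#' @param img An [rsp_image()].
#' @param threshold RSP threshold defining the object support (default 0.1).
#' @return Object of class `hull` with counter-clockwise `vertices`
#'   (matrix, columns x and y in mm), or empty vertices when nothing is
#'   above threshold.
#' @export
convex_hull <- function(img, threshold = 0.1) {
  if (threshold <= 0) stop("convex_hull: threshold must be positive")
  kz <- (dim(img$values)[3] + 1) %/% 2
  sl <- img$values[, , kz]
  idx <- which(sl > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(structure(list(vertices = NULL, threshold = threshold), class = "hull"))
  xs <- .axis_coords(img, 1)[idx[, 1]]
  ys <- .axis_coords(img, 2)[idx[, 2]]
  h <- grDevices::chull(xs, ys)
  # chull returns clockwise ordering; reverse for counter-clockwise
  verts <- cbind(x = xs[rev(h)], y = ys[rev(h)])
  structure(list(vertices = verts, threshold = threshold), class = "hull")
}

#' @export
print.hull <- function(x, ...) {
  if (is.null(x$vertices)) cat("<hull> empty\n")
  else cat(sprintf("<hull> %d vertices, threshold %g\n", nrow(x$vertices), x$threshold))
  invisible(x)
}

#' Entry and exit of rays through a convex hull
#'
#' Clips rays against the hull polygon (Cyrus-Beck clipping against the
#' convex edges). The ray is parameterised as `origin + t * direction`;
#' `t` is reported in the units of `direction` (pass a unit vector for
#' distances, or direction `(1, tan)` for the parameter to advance with x).
#' Tangent rays (touching a vertex or running along an edge) are treated as
#' misses.
#'
#' @param origin,direction Matrices with columns (x, y), one row per ray
#'   (vectors are accepted for a single ray).
#' @param hull A [convex_hull()].
#' @return `data.frame` with `t0`, `t1` (entry/exit parameters) and the
#'   entry/exit coordinates `x0`, `y0`, `x1`, `y1`; `NA` rows for misses.
#' @export
ray_hull_entry_exit <- function(origin, direction, hull) {
  if (is.null(dim(origin))) origin <- matrix(origin, ncol = 2)
  if (is.null(dim(direction))) direction <- matrix(direction, ncol = 2)
  n <- nrow(origin)
  t0 <- rep(-Inf, n); t1 <- rep(Inf, n)
  v <- hull$vertices
  if (is.null(v) || nrow(v) < 3) {
    t0 <- rep(NA_real_, n); t1 <- rep(NA_real_, n)
  } else {
    nv <- nrow(v)
    for (e in seq_len(nv)) {
      a <- v[e, ]; b <- v[if (e == nv) 1 else e + 1, ]
      # inward normal of a counter-clockwise polygon edge
      nx <- -(b[2] - a[2]); ny <- b[1] - a[1]
      denom <- direction[, 1] * nx + direction[, 2] * ny
      num <- (a[1] - origin[, 1]) * nx + (a[2] - origin[, 2]) * ny
      entering <- denom > 0
      leaving <- denom < 0
      t0[entering] <- pmax(t0[entering], num[entering] / denom[entering])
      t1[leaving] <- pmin(t1[leaving], num[leaving] / denom[leaving])
      par <- denom == 0 & num > 0 # parallel ray fully outside this edge
      t0[par] <- Inf
    }
    miss <- !(t0 < t1) # strict: tangents are misses
    t0[miss] <- NA_real_; t1[miss] <- NA_real_
  }
  data.frame(
    t0 = t0, t1 = t1,
    x0 = origin[, 1] + t0 * direction[, 1],
    y0 = origin[, 2] + t0 * direction[, 2],
    x1 = origin[, 1] + t1 * direction[, 1],
    y1 = origin[, 2] + t1 * direction[, 2]
  )
}

# straight-ray path length (mm) through the hull for rays along +x with
# tangent ty, used for the aggregate Highland factor; returns 0 for misses
.hull_chord <- function(hull, x0, y0, ty) {
  n <- length(y0)
  if (is.null(hull$vertices)) return(numeric(n))
  dirn <- cbind(rep(1, n), ty)
  hit <- ray_hull_entry_exit(cbind(rep_len(x0, n), y0), dirn, hull)
  chord <- (hit$t1 - hit$t0) * sqrt(1 + ty^2)
  chord[is.na(chord)] <- 0
  chord
}
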