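# Event filters: hard WEPL cuts, the pixel-statistics sigma filter with a
# mode window, and the likelihood-based filter that compares every particle
# against an electromagnetic-model prediction through a prior RSP map.
#
# All filters return a "filter mask": a data.frame with one row per event,
# a logical `accept` and a `reason` (NA for accepted events). Rejection is
# strict (value beyond the threshold); equality is accepted.

.new_mask <- function(id, accept, reason) {
  data.frame(id = id, accept = accept, reason = ifelse(accept, NA_character_, reason))
}

#' Hard WEPL cuts
#'
#' Removes physically non-meaningful WEPL values: below `lower` (0 mm) or
#' above `upper` (260 mm, roughly the range of a 200 MeV/u beam).
#'
#' @param events Event `data.frame` with a `wepl` column (mm).
#' @param lower,upper Cut bounds in mm; boundary values are accepted.
#' @return Filter mask (`id`, `accept`, `reason`).
#' @export
hard_wepl_cut <- function(events, lower = 0, upper = 260) {
  ok <- events$wepl >= lower & events$wepl <= upper
  .new_mask(events$id, ok, "hard-cut")
}

#' Scattering angle of an event
#'
#' `theta_s = sqrt((th_y0 - th_y1)^2 + (th_z0 - th_z1)^2)`: the magnitude of
#' the direction change between the front and rear tracker measurements.
#'
#' @param events Event `data.frame`.
#' @return Scattering angles in rad.
#' @export
scattering_angle <- function(events) {
  sqrt((events$th_y0 - events$th_y1)^2 + (events$th_z0 - events$th_z1)^2)
}

#' Combine filter masks (logical AND)
#'
#' @param ... Filter masks over the same events (matched by position).
#' @return A mask accepting events accepted by every input; the reason is
#'   taken from the first rejecting mask.
#' @export
combine_masks <- function(...) {
  ms <- list(...)
  out <- ms[[1]]
  for (m in ms[-1]) {
    newly <- out$accept & !m$accept
    out$reason[newly] <- m$reason[newly]
    out$accept <- out$accept & m$accept
  }
  out
}

# ---- sigma filter -----------------------------------------------------------

# Windowed per-pixel statistics of one quantity. `pix` are integer pixel
# codes in 1..np. The mode is found on a histogram with bins of `binwidth`
# (lowest bin wins ties); mean/sd are computed over values within
# [0.7, 1.3] x mode. Pixels with fewer than `min_count` windowed values, or
# (if `mode_floor` is given) with a mode below it, fall back to the plain
# mean/sd of the whole pixel; pixels still below `min_count` never reject.
.windowed_stats <- function(pix, value, np, binwidth, min_count = 3,
                            mode_floor = NULL) {
  bin <- pmax(floor(value / binwidth), 0) + 1
  nb <- max(bin) + 1L
  code <- (pix - 1) * nb + bin
  o <- order(code)
  r <- rle(code[o])
  gpix <- (r$values - 1) %/% nb + 1
  gbin <- (r$values - 1) %% nb + 1
  # per pixel: bin with the highest count, lowest bin on ties
  sel <- order(gpix, -r$lengths, gbin)
  first <- !duplicated(gpix[sel])
  mode_val <- rep(NA_real_, np)
  mode_val[gpix[sel][first]] <- (gbin[sel][first] - 0.5) * binwidth

  mv <- mode_val[pix]
  inw <- value >= 0.7 * mv & value <= 1.3 * mv
  if (!is.null(mode_floor)) {
    plain <- !is.na(mv) & mv < mode_floor
    inw[plain] <- TRUE # degenerate window: use the whole pixel
  }
  stat <- function(keep) {
    nw <- s1 <- s2 <- numeric(np)
    g <- rowsum(cbind(1, value[keep], value[keep]^2), pix[keep])
    i <- as.integer(rownames(g))
    nw[i] <- g[, 1]; s1[i] <- g[, 2]; s2[i] <- g[, 3]
    mean_w <- ifelse(nw > 0, s1 / nw, NA_real_)
    var_w <- ifelse(nw > 1, pmax(s2 - nw * mean_w^2, 0) / (nw - 1), NA_real_)
    list(n = nw, mean = mean_w, sd = sqrt(var_w))
  }
  st <- stat(inw)
  # window emptied a populated pixel entirely: fall back to plain stats
  tot <- tabulate(pix, np)
  redo <- which(st$n < min_count & tot >= min_count)
  if (length(redo)) {
    inw2 <- inw | (pix %in% redo)
    st <- stat(inw2)
  }
  list(mode = mode_val, n = st$n, mean = st$mean, sd = st$sd,
       reject_capable = st$n >= min_count & !is.na(st$sd))
}

#' Sigma filter (pixel-statistics filter)
#'
#' The distribution-based filter: events are binned into a transverse pixel
#' grid on their measured positions; per pixel, the mode, mean and standard
#' deviation of both WEPL and scattering angle are computed over values
#' within 0.7x to 1.3x the bin mode (shielding the statistics from
#' distribution tails), and any event whose WEPL or scattering angle lies
#' more than `sigma_t` standard deviations from its bin mean is removed.
#' With `sigma_t = 3` this is the classic 3-sigma filter.
#'
#' Pixels with fewer than `min_count` in-window events accept all their
#' members; near-zero scattering-angle modes (below 1 mrad, where the
#' multiplicative window degenerates) fall back to plain per-pixel
#' statistics.
#'
#' @param events Event `data.frame`.
#' @param sigma_t Threshold in standard deviations (default 3).
#' @param pixel Pixel size in mm (default 1).
#' @param plane `"rear"` (measured exit positions, default) or `"front"`.
#' @param min_count Minimum windowed count for a pixel to reject.
#' @param wepl_bin,angle_bin Histogram bin widths for the mode search
#'   (1 mm and 2 mrad).
#' @return Filter mask with attribute `"stats"`: a per-pixel `data.frame`
#'   of class `sigma_bin_stats` (pixel centres, counts, mode/mean/sd of
#'   WEPL and scattering angle).
#' @export
sigma_filter <- function(events, sigma_t = 3, pixel = 1,
                         plane = c("rear", "front"), min_count = 3,
                         wepl_bin = 1, angle_bin = 0.002) {
  if (sigma_t <= 0) stop("sigma_filter: sigma_t must be positive")
  plane <- match.arg(plane)
  pr <- .sigma_prepare(events, pixel, plane, min_count, wepl_bin, angle_bin)
  .sigma_apply(pr, sigma_t)
}

# shared preparation for sigma_filter and ROC sweeps
.sigma_prepare <- function(events, pixel = 1, plane = "rear", min_count = 3,
                           wepl_bin = 1, angle_bin = 0.002) {
  yy <- if (plane == "rear") events$y1 else events$y0
  zz <- if (plane == "rear") events$z1 else events$z0
  iy <- floor(yy / pixel); iz <- floor(zz / pixel)
  iy <- iy - min(iy); iz <- iz - min(iz)
  ny <- max(iy) + 1L
  pix <- as.integer(iy + iz * ny + 1L)
  np <- max(pix)
  w <- events$wepl
  th <- scattering_angle(events)
  sw <- .windowed_stats(pix, pmax(w, 0), np, wepl_bin, min_count)
  st <- .windowed_stats(pix, th, np, angle_bin, min_count, mode_floor = 1e-3)
  occupied <- tabulate(pix, np) > 0
  stats <- data.frame(
    pixel = which(occupied),
    y = (((which(occupied) - 1) %% ny) + min(floor(yy / pixel)) + 0.5) * pixel,
    z = (((which(occupied) - 1) %/% ny) + min(floor(zz / pixel)) + 0.5) * pixel,
    count = tabulate(pix, np)[occupied],
    wepl_mode = sw$mode[occupied], wepl_mean = sw$mean[occupied],
    wepl_sd = sw$sd[occupied], wepl_n = sw$n[occupied],
    angle_mode = st$mode[occupied], angle_mean = st$mean[occupied],
    angle_sd = st$sd[occupied], angle_n = st$n[occupied]
  )
  class(stats) <- c("sigma_bin_stats", "data.frame")
  list(events = events, pix = pix, w = w, th = th, sw = sw, st = st, stats = stats)
}

.sigma_apply <- function(pr, sigma_t) {
  pix <- pr$pix
  # strict rejection with a float-rounding guard so that zero-variance
  # bins keep their (identical) members
  tol_w <- 1e-10 * pmax(abs(pr$sw$mean[pix]), 1)
  tol_t <- 1e-10 * pmax(abs(pr$st$mean[pix]), 1)
  rej_w <- pr$sw$reject_capable[pix] &
    abs(pr$w - pr$sw$mean[pix]) > sigma_t * pr$sw$sd[pix] + tol_w
  rej_t <- pr$st$reject_capable[pix] &
    abs(pr$th - pr$st$mean[pix]) > sigma_t * pr$st$sd[pix] + tol_t
  reason <- ifelse(rej_w, "sigma-wepl", ifelse(rej_t, "sigma-angle", NA))
  mask <- .new_mask(pr$events$id, !(rej_w | rej_t), reason)
  attr(mask, "stats") <- pr$stats
  mask
}

# ---- likelihood filter ------------------------------------------------------

#' Coverage probability of a residual under a (bi)variate normal model
#'
#' Maps a residual to the probability mass of the model distribution
#' contained inside the ellipse (or interval) through the observation:
#' univariate `erf(|d|/(sigma sqrt(2)))`, bivariate the chi-square(2) CDF
#' of the Mahalanobis radius, i.e. `1 - exp(-m^2/2)`. Under a correct model
#' the coverage is uniform on \[0, 1\]; thresholding coverage at `Pt`
#' reproduces the sigma-equivalence of the likelihood threshold (a 1-sigma
#' univariate cut corresponds to `Pt = 0.68`).
#'
#' @param residual Numeric vector (univariate) or two-column matrix
#'   (bivariate residuals, one row per event).
#' @param scale Univariate: standard deviations (vectorised). Bivariate: a
#'   2x2 covariance matrix, or a matrix/data.frame with columns
#'   `(sigma_y2, sigma_ytheta, sigma_theta2)`, one row per event.
#' @return Coverage probabilities in \[0, 1\].
#' @export
component_probability <- function(residual, scale) {
  if (is.null(dim(residual)) || ncol(as.matrix(residual)) == 1) {
    sigma <- as.numeric(scale)
    if (any(sigma <= 0)) stop("component_probability: scale must be positive")
    return(2 * stats::pnorm(abs(as.numeric(residual)) / sigma) - 1)
  }
  residual <- as.matrix(residual)
  if (is.matrix(scale) && nrow(scale) == 2 && ncol(scale) == 2)
    scale <- matrix(c(scale[1, 1], scale[1, 2], scale[2, 2]),
                    nrow(residual), 3, byrow = TRUE)
  scale <- as.matrix(scale)
  syy <- scale[, 1]; syt <- scale[, 2]; stt <- scale[, 3]
  det <- syy * stt - syt^2
  bad <- det <= 0 | syy <= 0 | stt <= 0
  if (any(bad)) {
    warning("component_probability: singular covariance; using floored diagonal")
    syt[bad] <- 0
    syy[bad] <- pmax(syy[bad], 9)
    stt[bad] <- pmax(stt[bad], 1e-6)
    det <- syy * stt - syt^2
  }
  m2 <- (residual[, 1]^2 * stt - 2 * residual[, 1] * residual[, 2] * syt +
           residual[, 2]^2 * syy) / det
  -expm1(-m2 / 2)
}

#' Per-particle electromagnetic prediction against a prior RSP map
#'
#' For every event: estimates the most-likely path (cubic-spline through
#' the hull of the prior), integrates the prior RSP along it for the
#' predicted WEPL, slows the particle down along the path for the energy
#' profile, accumulates the Fermi-Eyges moments (water radiation length
#' inside the object, air outside) for the shared transverse covariance,
#' and evaluates the Tschalar straggling width parameterised in WEPL.
#' Residuals are taken against the straight-line (transvection) projection
#' of the entrance vector and the measured WEPL. Minimum standard
#' deviations of 3 mm (position) and 3 mm WEPL are enforced after model
#' evaluation, and each residual is mapped to a coverage probability
#' (`p_y`, `p_z`, `p_e`) via [component_probability()].
#'
#' @param events Event `data.frame` (see [simulate_projection()]).
#' @param prior An [rsp_image()] prior; for simulated data this can be the
#'   phantom itself (ideal prior) or a first sigma-filtered reconstruction.
#' @param species Primary ion species (default: from the events).
#' @param hull Optional precomputed [convex_hull()] of the prior.
#' @param n_steps Number of path samples inside the hull (default 200,
#'   about 1 mm resolution for a 20 cm object).
#' @param sigma_floor_pos,sigma_floor_wepl Floors in mm.
#' @return `data.frame` of class `prior_prediction` with predicted WEPL,
#'   residuals, covariance components, straggling width and the three
#'   coverage probabilities.
#' @export
prior_predict <- function(events, prior, species = NULL, hull = NULL,
                          n_steps = 200, sigma_floor_pos = 3,
                          sigma_floor_wepl = 3) {
  sp <- .as_species(if (is.null(species)) as.character(events$species[1]) else species)
  if (is.null(hull)) hull <- convex_hull(prior)
  k <- .ionct_const
  n <- nrow(events)
  geom <- attr(events, "geometry")
  x0 <- if (!is.null(geom)) geom$x0 else -150
  x1 <- if (!is.null(geom)) geom$x1 else 150

  out <- data.frame(wepl_pred = numeric(n), dwepl = numeric(n),
                    sigma_wepl = numeric(n), dy = numeric(n), dth_y = numeric(n),
                    dz = numeric(n), dth_z = numeric(n), sigma_y2 = numeric(n),
                    sigma_ytheta = numeric(n), sigma_theta2 = numeric(n),
                    p_y = numeric(n), p_z = numeric(n), p_e = numeric(n))

  for (ang in unique(events$angle_deg)) {
    g <- which(events$angle_deg == ang)
    ev <- events[g, ]
    m <- length(g)
    phi <- ang * pi / 180
    cp <- cos(phi); sph <- sin(phi)

    a <- .mlp_anchor(hull, x0, ev$y0, ev$th_y0, x1, ev$y1, ev$th_y1, angle = ang)
    zu <- ev$z0 + (a$u - x0) * ev$th_z0
    zv <- ev$z1 + (a$v - x1) * ev$th_z1
    L <- a$v - a$u
    dL <- L / n_steps

    E <- ev$e_in
    w <- numeric(m)
    I0 <- I1 <- I2 <- Ts <- numeric(m)
    inside <- L > 0
    for (j in seq_len(n_steps)) {
      t <- (j - 0.5) / n_steps
      h <- .hermite(t)
      xj <- a$u + t * L
      yj <- h$h00 * a$yu + h$h10 * L * ev$th_y0 + h$h01 * a$yv + h$h11 * L * ev$th_y1
      zj <- h$h00 * zu + h$h10 * L * ev$th_z0 + h$h01 * zv + h$h11 * L * ev$th_z1
      yj[!inside] <- 0; zj[!inside] <- 0 # unused (dL = 0)
      r <- sample_rsp(prior, cp * xj + sph * yj, -sph * xj + cp * yj, zj)
      w <- w + r * dL
      X0l <- ifelse(r > 0.1, k$X0_water, k$X0_air)
      Ee <- pmax(E, .RANGE_EMIN)
      pvv <- Ee * (Ee + 2 * sp$mc2) / (Ee + sp$mc2)
      gg <- (sp$z * k$E0_highland / pvv)^2 / X0l
      I0 <- I0 + gg * dL
      I1 <- I1 + gg * (x1 - xj) * dL
      I2 <- I2 + gg * (x1 - xj)^2 * dL
      Ts <- Ts + dL / X0l
      E <- pmax(E - .sp_raw(Ee, sp$mc2, sp$z) * r * dL, 0.5)
    }
    E_exit <- E

    # closed-form air contributions before and after the hull
    air <- function(E_at, xa, xb) { # segment [xa, xb], constant energy
      Ee <- pmax(E_at, .RANGE_EMIN)
      pvv <- Ee * (Ee + 2 * sp$mc2) / (Ee + sp$mc2)
      g0 <- (sp$z * k$E0_highland / pvv)^2 / k$X0_air
      len <- pmax(xb - xa, 0)
      list(I0 = g0 * len,
           I1 = g0 * ((x1 - xa)^2 - (x1 - xb)^2) / 2,
           I2 = g0 * ((x1 - xa)^3 - (x1 - xb)^3) / 3,
           Ts = len / k$X0_air)
    }
    pre <- air(ev$e_in, rep(x0, m), a$u)
    post <- air(E_exit, a$v, rep(x1, m))
    I0 <- I0 + pre$I0 + post$I0
    I1 <- I1 + pre$I1 + post$I1
    I2 <- I2 + pre$I2 + post$I2
    Ts <- Ts + pre$Ts + post$Ts

    f2 <- pmax(1 + log(pmax(Ts, 1e-12)) / 9, 0.25)^2
    syy <- f2 * I2; syt <- f2 * I1; stt <- f2 * I0
    # positional floor, keeping the covariance matrix positive definite
    low <- syy < sigma_floor_pos^2
    syy[low] <- sigma_floor_pos^2
    cap <- 0.999 * sqrt(syy * stt)
    syt <- pmin(pmax(syt, -cap), cap)

    Eout_pred <- energy_from_wepl(ev$e_in, pmin(w, csda_range(ev$e_in, sp) - 1), sp)
    Eout_pred <- pmax(Eout_pred, 2)
    sE <- sqrt(tschalar_variance(ev$e_in, Eout_pred, sp))
    s_w <- pmax(sE / .sp_raw(Eout_pred, sp$mc2, sp$z), sigma_floor_wepl)

    Lx <- x1 - x0
    dy <- ev$y1 - (ev$y0 + Lx * ev$th_y0)
    dthy <- ev$th_y1 - ev$th_y0
    dz <- ev$z1 - (ev$z0 + Lx * ev$th_z0)
    dthz <- ev$th_z1 - ev$th_z0
    dw <- ev$wepl - w

    Sig <- cbind(syy, syt, stt)
    out$wepl_pred[g] <- w
    out$dwepl[g] <- dw
    out$sigma_wepl[g] <- s_w
    out$dy[g] <- dy; out$dth_y[g] <- dthy
    out$dz[g] <- dz; out$dth_z[g] <- dthz
    out$sigma_y2[g] <- syy; out$sigma_ytheta[g] <- syt; out$sigma_theta2[g] <- stt
    out$p_y[g] <- component_probability(cbind(dy, dthy), Sig)
    out$p_z[g] <- component_probability(cbind(dz, dthz), Sig)
    out$p_e[g] <- component_probability(dw, s_w)
  }
  class(out) <- c("prior_prediction", "data.frame")
  out
}

#' Likelihood-based filter against a prior RSP map
#'
#' Rejects events whose measured exit vector (in either transverse plane)
#' or measured WEPL falls outside the `Pt`-coverage region of the
#' electromagnetic-model prediction from [prior_predict()]. With the
#' default per-component rule an event is rejected as a likely nuclear
#' interaction or large-angle scatter when any of its three coverage
#' probabilities exceeds `Pt`; `combine = "product"` instead thresholds the
#' product of the three coverages against `Pt^3`.
#'
#' @inheritParams prior_predict
#' @param Pt Probability threshold in (0, 1); published working points are
#'   0.6 for protons and 0.4 for helium.
#' @param prediction Optional precomputed [prior_predict()] result (used by
#'   threshold sweeps to avoid recomputation).
#' @param combine `"per-component"` (default) or `"product"`.
#' @return Filter mask with the prediction attached as attribute
#'   `"prediction"`.
#' @export
prior_filter <- function(events, prior, Pt = 0.6, species = NULL, hull = NULL,
                         prediction = NULL, combine = c("per-component", "product"),
                         ...) {
  if (Pt <= 0 || Pt >= 1) stop("prior_filter: Pt must be in (0, 1)")
  combine <- match.arg(combine)
  if (is.null(prediction))
    prediction <- prior_predict(events, prior, species = species, hull = hull, ...)
  if (combine == "per-component") {
    rej_y <- prediction$p_y > Pt
    rej_z <- prediction$p_z > Pt
    rej_e <- prediction$p_e > Pt
    reason <- ifelse(rej_y, "prior-Y", ifelse(rej_z, "prior-Z", "prior-E"))
    mask <- .new_mask(events$id, !(rej_y | rej_z | rej_e), reason)
  } else {
    rej <- prediction$p_y * prediction$p_z * prediction$p_e > Pt^3
    mask <- .new_mask(events$id, !rej, "prior-combined")
  }
  attr(mask, "prediction") <- prediction
  mask
}
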