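# Shared fixtures, built lazily in code and cached for the session so that
# the more expensive Monte Carlo runs are reused across test files.

.fix <- new.env()

fix_cylinder <- function() {
  if (is.null(.fix$cyl)) .fix$cyl <- make_cylinder(200, rsp = 1)
  .fix$cyl
}

fix_hull <- function() {
  if (is.null(.fix$hull)) .fix$hull <- convex_hull(fix_cylinder())
  .fix$hull
}

# electromagnetic-only proton projection (straggling + MCS, no nuclear)
fix_em_proton <- function() {
  if (is.null(.fix$emp)) {
    b <- beam_spec("proton", 200, n = 6e4, width = 300, height = 10, seed = 42)
    .fix$emp <- simulate_projection(fix_cylinder(), b, nuclear = no_nuclear("proton"))
  }
  .fix$emp
}

# fully labelled helium projection with all nuclear channels
fix_helium <- function() {
  if (is.null(.fix$he)) {
    b <- beam_spec("helium", 200, n = 1e5, width = 300, height = 20, seed = 99)
    .fix$he <- simulate_projection(fix_cylinder(), b)
  }
  .fix$he
}

# helium prediction against the ideal prior, reused by filter/ROC tests
fix_helium_prediction <- function() {
  if (is.null(.fix$hep)) {
    ev <- fix_helium()
    keep <- hard_wepl_cut(ev)$accept
    .fix$he_kept <- ev[keep, ]
    .fix$hep <- prior_predict(.fix$he_kept, fix_cylinder(), hull = fix_hull())
  }
  .fix$hep
}

fix_helium_kept <- function() {
  fix_helium_prediction()
  .fix$he_kept
}

# a small water slab profile sampled at `step` mm
slab_profile <- function(thickness = 200, E0 = 200, species = "proton", step = 1,
                         rsp = 1) {
  xs <- seq(0, thickness, by = step)
  slowdown_profile(xs, rep(rsp, length(xs)), E0, species)
}

# adaptive-quadrature oracle for the Fermi-Eyges moments of a profile,
# integrating the profile's piecewise-linear energy interpolant per segment
# (independent of the package's Gauss-Legendre accumulation)
fe_oracle <- function(profile, species = "proton") {
  k <- physics_constants()
  sp <- ion_species(species)
  x <- profile$x
  x1 <- x[length(x)]
  Efun <- stats::approxfun(x, profile$E)
  total <- 0
  segs <- cbind(x[-length(x)], x[-1], profile$X0[-length(x)])
  tt <- sum((segs[, 2] - segs[, 1]) / segs[, 3])
  f <- max(1 + log(tt) / 9, 0.25)
  mom <- function(p) {
    s <- 0
    for (i in seq_len(nrow(segs))) {
      g <- function(xx) {
        E <- pmax(Efun(xx), 0.5)
        (sp$z * k$E0_highland / pv(E, sp))^2 / segs[i, 3] * (x1 - xx)^p
      }
      s <- s + stats::integrate(g, segs[i, 1], segs[i, 2], rel.tol = 1e-10)$value
    }
    f^2 * s
  }
  list(sigma_theta2 = mom(0), sigma_ytheta = mom(1), sigma_y2 = mom(2))
}
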