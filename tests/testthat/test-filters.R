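# Hard cuts, sigma filter (with brute-force oracle), coverage probabilities
# and the likelihood filter.

test_that("hard WEPL cuts use the printed bounds", {
  ev <- data.frame(id = 1:3, wepl = c(130, -1, 261))
  m <- hard_wepl_cut(ev)
  expect_equal(m$accept, c(TRUE, FALSE, FALSE))
  expect_equal(m$reason, c(NA, "hard-cut", "hard-cut"))
})

test_that("scattering angle is the quadrature sum of plane deflections", {
  ev <- data.frame(th_y0 = 0, th_y1 = 0.003, th_z0 = 0, th_z1 = 0.004)
  expect_equal(scattering_angle(ev), 0.005) # 3-4-5
  flip <- data.frame(th_y0 = 0, th_y1 = -0.003, th_z0 = 0, th_z1 = -0.004)
  expect_equal(scattering_angle(flip), 0.005)
  none <- data.frame(th_y0 = 0.01, th_y1 = 0.01, th_z0 = -0.02, th_z1 = -0.02)
  expect_equal(scattering_angle(none), 0)
})

test_that("sigma filter matches a brute-force recomputation of windowed statistics", {
  set.seed(12)
  n <- 800
  ev <- data.frame(
    id = seq_len(n),
    y0 = stats::runif(n, 0, 3), z0 = stats::runif(n, 0, 2),
    y1 = stats::runif(n, 0, 3), z1 = stats::runif(n, 0, 2),
    th_y0 = 0, th_z0 = 0,
    th_y1 = stats::rnorm(n, 0, 0.03), th_z1 = stats::rnorm(n, 0, 0.03),
    wepl = stats::rnorm(n, 180, 4)
  )
  st <- 2.5
  m <- sigma_filter(ev, sigma_t = st, pixel = 1)
  th <- scattering_angle(ev)
  pix <- paste(floor(ev$y1), floor(ev$z1))
  brute <- function(v, bw, floor_mode = NULL) {
    out <- logical(n)
    for (p in unique(pix)) {
      idx <- which(pix == p)
      bins <- floor(v[idx] / bw)
      tab <- table(bins)
      mode_bin <- min(as.numeric(names(tab)[tab == max(tab)])) # lowest on ties
      mv <- (mode_bin + 0.5) * bw
      if (!is.null(floor_mode) && mv < floor_mode) {
        inw <- rep(TRUE, length(idx))
      } else {
        inw <- v[idx] >= 0.7 * mv & v[idx] <= 1.3 * mv
      }
      if (sum(inw) < 3) { inw <- rep(TRUE, length(idx)) }
      if (sum(inw) < 3) { out[idx] <- FALSE; next }
      mu <- mean(v[idx][inw]); sd_ <- stats::sd(v[idx][inw])
      if (is.na(sd_)) { out[idx] <- FALSE; next }
      out[idx] <- abs(v[idx] - mu) > st * sd_
    }
    out
  }
  rej_w <- brute(pmax(ev$wepl, 0), 1)
  rej_t <- brute(th, 0.002, floor_mode = 1e-3)
  expect_equal(!m$accept, rej_w | rej_t)
})

test_that("sigma filter keeps identical bins and everything at huge thresholds", {
  ev <- data.frame(id = 1:20, y0 = 0.5, z0 = 0.5, y1 = 0.5, z1 = 0.5,
                   th_y0 = 0, th_z0 = 0, th_y1 = 0.01, th_z1 = 0,
                   wepl = rep(150, 20))
  m <- sigma_filter(ev, 3)
  expect_true(all(m$accept)) # sigma = 0, deviation 0: kept by <= convention
  he <- fix_helium()
  m_inf <- sigma_filter(he, sigma_t = 1e9)
  expect_true(all(m_inf$accept))
})

test_that("an injected far outlier is rejected at 3 sigma", {
  set.seed(8)
  n <- 1000
  ev <- data.frame(id = seq_len(n + 1),
                   y0 = 0.5, z0 = 0.5, y1 = 0.5, z1 = 0.5,
                   th_y0 = 0, th_z0 = 0,
                   th_y1 = c(stats::rnorm(n, 0.03, 0.003), 0.03),
                   th_z1 = 0,
                   wepl = c(stats::rnorm(n, 200, 2), 200 + 10 * 2))
  m <- sigma_filter(ev, 3)
  expect_false(m$accept[n + 1])
  expect_equal(m$reason[n + 1], "sigma-wepl")
})

test_that("coverage probabilities reproduce the sigma mapping", {
  expect_equal(component_probability(0, 1), 0)
  expect_equal(component_probability(1, 1), 0.6827, tolerance = 1e-3) # 1 sigma
  expect_equal(component_probability(c(-2, 2), c(1, 1))[1],
               component_probability(2, 1))
  # bivariate coverage at Mahalanobis radius r against a Monte Carlo oracle
  set.seed(33)
  Sig <- matrix(c(4, 1.2, 1.2, 1), 2)
  L <- chol(Sig)
  draws <- matrix(stats::rnorm(4e5), ncol = 2) %*% L
  m2 <- rowSums((draws %*% solve(Sig)) * draws)
  for (r in c(0.5, 1, 2)) {
    mc <- mean(m2 <= r^2)
    got <- component_probability(matrix(c(r * sqrt(Sig[1, 1]), r * Sig[1, 2] /
                                            sqrt(Sig[1, 1])), 1, 2), Sig)
    expect_equal(got, mc, tolerance = 0.01)
  }
  # singular covariance falls back with a warning
  expect_warning(component_probability(cbind(1, 1), cbind(0, 0, 0)), "singular")
})

test_that("prior predictions are exact on their own prediction and floored", {
  ph <- fix_cylinder()
  geom <- list(x0 = -150, x1 = 150, energy = 200)
  mk <- function(y0, wepl, th1 = 0) {
    ev <- data.frame(id = 1, angle_deg = 0, y0 = y0, th_y0 = 0, z0 = 0,
                     th_z0 = 0, y1 = y0, th_y1 = th1, z1 = 0, th_z1 = 0,
                     e_in = 200, e_out = NA, wepl = wepl, species = "proton")
    attr(ev, "geometry") <- geom
    ev
  }
  # an event missing the phantom entirely: empty-path prediction, floors apply
  far <- mk(140, 0)
  pf <- prior_predict(far, ph)
  expect_equal(pf$wepl_pred, 0)
  expect_equal(pf$sigma_wepl, 3)
  expect_gte(pf$sigma_y2, 9)
  expect_equal(pf$p_y, 0, tolerance = 1e-9)
  expect_equal(pf$p_e, 0)
  # measured WEPL one (floored) sigma away: pE is the 1-sigma coverage
  off <- mk(140, 3)
  po <- prior_predict(off, ph)
  expect_equal(po$p_e, 2 * stats::pnorm(1) - 1, tolerance = 1e-9)
  # central event on its prediction: all coverages at their minimum
  ctr <- mk(0, 0)
  pc <- prior_predict(ctr, ph)
  ctr$wepl <- pc$wepl_pred
  pc2 <- prior_predict(ctr, ph)
  expect_equal(pc2$p_e, 0)
  expect_equal(pc2$p_y, 0)
  expect_equal(pc2$wepl_pred, 200, tolerance = 1.8)
})

test_that("the likelihood filter matches per-event recomputation and threshold limits", {
  ev <- fix_helium_kept()
  pred <- fix_helium_prediction()
  sub <- sample(nrow(ev), 200)
  m <- prior_filter(ev, fix_cylinder(), Pt = 0.4, prediction = pred)
  # brute force per event from the prediction components
  for (i in sub) {
    Sig <- matrix(c(pred$sigma_y2[i], pred$sigma_ytheta[i],
                    pred$sigma_ytheta[i], pred$sigma_theta2[i]), 2)
    py <- 1 - exp(-0.5 * drop(t(c(pred$dy[i], pred$dth_y[i])) %*% solve(Sig) %*%
                                c(pred$dy[i], pred$dth_y[i])))
    pz <- 1 - exp(-0.5 * drop(t(c(pred$dz[i], pred$dth_z[i])) %*% solve(Sig) %*%
                                c(pred$dz[i], pred$dth_z[i])))
    pe <- 2 * stats::pnorm(abs(pred$dwepl[i]) / pred$sigma_wepl[i]) - 1
    expect_equal(m$accept[i], py <= 0.4 && pz <= 0.4 && pe <= 0.4)
  }
  # Pt -> 1 limit: the acceptance set grows towards "all finite
  # residuals"; at Pt = 1 - 1e-12 only events whose coverage has
  # numerically saturated against 1 (secondaries tens of sigma out)
  # remain rejected, and every electromagnetically consistent event
  # is accepted
  m_all <- prior_filter(ev, fix_cylinder(), Pt = 1 - 1e-12, prediction = pred)
  m_mid <- prior_filter(ev, fix_cylinder(), Pt = 0.95, prediction = pred)
  expect_true(all(m_all$accept >= m_mid$accept))
  mild <- pred$p_y <= 0.999 & pred$p_z <= 0.999 & pred$p_e <= 0.999
  expect_true(all(m_all$accept[mild]))
  expect_true(all(m_all$accept[ev$label == "primary"] |
                    !mild[ev$label == "primary"]))
})

test_that("filter masks partition events and nest over threshold sweeps", {
  ev <- fix_helium_kept()
  pred <- fix_helium_prediction()
  prev <- NULL
  for (Pt in c(0.2, 0.4, 0.6, 0.8)) {
    m <- prior_filter(ev, fix_cylinder(), Pt = Pt, prediction = pred)
    expect_equal(sum(m$accept) + sum(!m$accept), nrow(ev))
    expect_true(all(is.na(m$reason) == m$accept))
    if (!is.null(prev)) expect_true(all(m$accept >= prev)) # rejection shrinks
    prev <- m$accept
  }
  prev <- NULL
  pr <- ionct:::.sigma_prepare(ev)
  for (st in c(1, 2, 3, 5, 8)) {
    m <- ionct:::.sigma_apply(pr, st)
    if (!is.null(prev)) expect_true(all(m$accept >= prev))
    prev <- m$accept
  }
})

test_that("the likelihood filter is calibrated on electromagnetic-only data", {
  # on straggling+MCS-only simulations the coverage of each component is
  # uniform, so at Pt = 0.68 each component keeps >= 68% (more where the
  # 3 mm floors widen the envelope); the joint acceptance must sit between
  # Pt^3 and 1, and each component's rejection rate must not exceed 1 - Pt
  ev <- fix_em_proton()
  keep <- hard_wepl_cut(ev)$accept
  ev <- ev[keep, ]
  pred <- prior_predict(ev, fix_cylinder(), hull = fix_hull())
  Pt <- 0.68
  for (p in list(pred$p_y, pred$p_z, pred$p_e)) {
    rej <- mean(p > Pt)
    expect_lte(rej, (1 - Pt) + 0.02)
    expect_gte(rej, 0)
  }
  acc <- mean(pred$p_y <= Pt & pred$p_z <= Pt & pred$p_e <= Pt)
  expect_gte(acc, Pt^3 - 0.02)
})
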