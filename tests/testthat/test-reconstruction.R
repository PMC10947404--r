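# Radiograph statistics, ramp kernel, DDB reconstruction and the
# tomographic noise backprojection.

test_that("radiograph pixels carry count, mean and sample standard deviation", {
  ev <- data.frame(id = 1:2, y0 = c(0.2, 0.7), z0 = 0.5,
                   y1 = 0, z1 = 0, wepl = c(10, 20))
  rg <- bin_radiograph(ev, "front", 1)
  expect_equal(rg$count[1, 1], 2)
  expect_equal(rg$mean[1, 1], 15)
  expect_equal(rg$sd[1, 1], sqrt(50))
  same <- data.frame(id = 1:5, y0 = 0.1, z0 = 0.1, y1 = 0, z1 = 0, wepl = 42)
  expect_equal(bin_radiograph(same, "front")$sd[1, 1], 0)
  # Gaussian pixels recover the generative sigma within 4 standard errors
  set.seed(14)
  n <- 4000
  g <- data.frame(id = 1:n, y0 = 0.5, z0 = 0.5, y1 = 0, z1 = 0,
                  wepl = stats::rnorm(n, 200, 3))
  sdg <- bin_radiograph(g, "front")$sd[1, 1]
  expect_lt(abs(sdg - 3), 4 * 3 / sqrt(2 * (n - 1)))
})

test_that("noise profile averages pixel noise vertically", {
  set.seed(2)
  ny <- 5; nz <- 8
  ev <- do.call(rbind, lapply(seq_len(ny), function(i)
    do.call(rbind, lapply(seq_len(nz), function(j)
      data.frame(id = 1, y0 = i - 0.5 + stats::runif(20, -0.4, 0.4),
                 z0 = j - 0.5, y1 = 0, z1 = 0,
                 wepl = stats::rnorm(20, 100, i))))))
  rg <- bin_radiograph(ev, "front", 1)
  np <- noise_profile(rg)
  # brute-force column averages
  for (i in seq_len(ny))
    expect_equal(np$noise[i], mean(rg$sd[i, ], na.rm = TRUE))
  one_row <- noise_profile(rg, band = c(2, 3))
  expect_equal(one_row$noise, rg$sd[, 3])
  flat <- rg; flat$sd[] <- 1.5
  expect_true(all(abs(noise_profile(flat)$noise - 1.5) < 1e-12))
})

test_that("Ram-Lak kernel has the closed-form taps and rejects DC", {
  h <- ramlak_kernel(321, spacing = 0.625)
  expect_lt(abs(sum(h)), 1e-12)
  expect_equal(h[161], 1 / (4 * 0.625^2), tolerance = 1e-12)
  expect_equal(h[162], -1 / (pi^2 * 0.625^2), tolerance = 1e-12)
  expect_equal(h[164], h[158]) # symmetric
  expect_true(all(h[161 + seq(2, 100, by = 2)] == 0))
  # a constant projection is rejected wherever the kernel fully overlaps it
  h81 <- ramlak_kernel(81, 1)
  flat <- matrix(7, 1, 200)
  out <- ionct:::.conv_rows(flat, h81)
  expect_lt(max(abs(out[, 50:150])), 1e-9)
  expect_error(ramlak_kernel(2), ">= 3")
})

test_that("DDB reconstruction recovers the uniform cylinder and insert ordering", {
  ph <- fix_cylinder(); h <- fix_hull()
  b <- beam_spec("proton", 200, n = 3500, width = 300, height = 6, seed = 11)
  ev <- simulate_scan(ph, b, nuclear = no_nuclear("proton"),
                      n_projections = 30, angle_step = 6)
  tg <- ddb_reconstruct(ev, n_grid = 128, fov = 220, hull = h)
  expect_equal(roi_noise(tg, c(0, 0), 20), 1, tolerance = 0.02)
  expect_equal(roi_noise(tg, c(0, 60), 16), 1, tolerance = 0.03)

  # zero-WEPL events reconstruct to a zero image
  ev0 <- ev; ev0$wepl <- 0
  tg0 <- ddb_reconstruct(ev0, n_grid = 64, fov = 220, hull = h)
  expect_lt(max(abs(tg0$values)), 1e-9)

  # insert phantom: ROI means ordered like the ground-truth RSPs
  ins <- data.frame(x = c(-40, 0, 40), y = c(0, 45, 0),
                    diameter = 24, rsp = c(0.4, 1.4, 1.9),
                    name = c("low", "mid", "high"))
  php <- make_insert_phantom(150, ins)
  bi <- beam_spec("proton", 200, n = 3500, width = 220, height = 6, seed = 12)
  evi <- simulate_scan(php, bi, nuclear = no_nuclear("proton"),
                       n_projections = 30, angle_step = 6)
  tgi <- ddb_reconstruct(evi, n_grid = 128, fov = 200, hull = convex_hull(php))
  tab <- rsp_error_table(tgi, ins, roi_diameter = 12)
  expect_equal(order(tab$measured), order(tab$reference))
})

test_that("noise backprojection matches the homogeneous closed form and 1/N scaling", {
  # synthetic single-angle-replicated events with Gaussian WEPL everywhere:
  # the variance map must equal the direct convolution/backprojection of
  # the per-bin squared standard error with the squared kernel
  set.seed(6)
  n <- 6000
  mk <- function(nn) {
    ev <- data.frame(id = seq_len(nn),
                     y0 = stats::runif(nn, -60, 60), th_y0 = 0,
                     z0 = 0, th_z0 = 0, y1 = 0, th_y1 = 0, z1 = 0, th_z1 = 0,
                     e_in = 200, e_out = 100,
                     wepl = stats::rnorm(nn, 100, 5), species = "proton")
    ev$y1 <- ev$y0
    ev <- do.call(rbind, lapply(c(0, 45, 90, 135), function(a) {
      e <- ev; e$angle_deg <- a; e
    }))
    attr(ev, "geometry") <- list(x0 = -150, x1 = 150, energy = 200)
    ev
  }
  ev <- mk(n)
  ng <- 48; fov <- 96
  nz <- noise_reconstruct(ev, n_grid = ng, fov = fov)
  # independent oracle: plain O(n^2) convolution and nearest-neighbour
  # backprojection of the per-bin squared standard error
  lat_bin <- fov / ng
  xd <- seq(-ceiling(fov / 2 * sqrt(2)) - 2, ceiling(fov / 2 * sqrt(2)) + 2, 1)
  kern2 <- ramlak_kernel(2 * ng - 1, lat_bin)^2
  ctr <- (seq_len(ng) - (ng + 1) / 2) * lat_bin
  one <- ev[ev$angle_deg == 0, ]
  li <- floor((one$y0 + fov / 2) / lat_bin) + 1
  se2_bins <- sapply(seq_len(ng), function(b) {
    v <- one$wepl[li == b]
    if (length(v) < 2) NA else stats::var(v) / length(v)
  })
  se2_bins <- stats::approx(which(!is.na(se2_bins)), se2_bins[!is.na(se2_bins)],
                            seq_len(ng), rule = 2)$y
  conv <- sapply(seq_len(ng), function(s)
    sum(sapply(seq_len(ng), function(sp) {
      kk <- s - sp + (length(kern2) + 1) / 2
      if (kk >= 1 && kk <= length(kern2)) se2_bins[sp] * kern2[kk] else 0
    }))) * lat_bin^2
  # every depth row holds the same statistics, angles are replicated, so
  # the oracle variance at a pixel is 4 * (pi/4)^2 * mean of the four
  # rotated lateral reads; compare at the centre where all reads coincide
  ctr_idx <- ng / 2
  oracle_var <- 4 * (pi / 4)^2 * conv[ctr_idx]
  expect_equal(nz$values[ctr_idx, ctr_idx]^2, oracle_var, tolerance = 0.02)

  # duplicating every event halves the variance map exactly
  ev2 <- ev; ev2$id <- ev2$id + n
  both <- rbind(ev, ev2)
  attr(both, "geometry") <- attr(ev, "geometry")
  nz2 <- noise_reconstruct(both, n_grid = ng, fov = fov)
  centre <- abs(outer(nz$x, nz$y, function(a, b) sqrt(a^2 + b^2))) < 30
  ratio <- nz$values[centre]^2 / nz2$values[centre]^2
  expect_equal(mean(ratio), 2, tolerance = 0.01)

  # constant WEPL in every bin: zero noise map
  evc <- ev; evc$wepl <- 123
  attr(evc, "geometry") <- attr(ev, "geometry")
  nzc <- noise_reconstruct(evc, n_grid = ng, fov = fov)
  expect_lt(max(nzc$values), 1e-9)
})
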