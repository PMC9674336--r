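# Straightness, band extraction, correlation, peak fitting, indices.

test_that("junction_straightness: line, semicircle, brute-force oracle", {
  expect_equal(junction_straightness(rbind(c(0, 0), c(10, 3))), 0)
  theta <- seq(0, pi, length.out = 41)
  arc <- cbind(cos(theta), sin(theta))     # semicircle over its diameter chord
  expect_equal(junction_straightness(arc), 0.5, tolerance = 1e-9)

  set.seed(7)
  for (k in 1:5) {
    pts <- cbind(sort(runif(12, 0, 50)), runif(12, -3, 3))
    chord <- pts[12, ] - pts[1, ]
    u <- chord / sqrt(sum(chord^2))
    brute <- max(vapply(1:12, function(i) {
      v <- pts[i, ] - pts[1, ]
      abs(v[1] * u[2] - v[2] * u[1])
    }, 0)) / sqrt(sum(chord^2))
    expect_equal(junction_straightness(pts), brute)
  }
  expect_error(junction_straightness(rbind(c(1, 1), c(2, 2), c(1, 1))),
               "zero chord")
})

test_that("extract_band: row arithmetic and exact crop on an aligned scene", {
  # 400 nm at 20 nm/px -> 2*floor(400/40) + 1 = 21 rows
  p <- small_params(seed = 31L)
  sim <- simulate_junction_scene(p)
  band <- extract_band(sim$pair, sim$trace, width = 400)
  expect_identical(nrow(band$chan1), 21L)

  # horizontal straight trace at an integer row with the TJ line on it:
  # the band equals the image crop exactly
  tr <- sim$trace                      # default path: y = 63.5 -> build our own
  img <- matrix(0, 64, 64)
  img[33, ] <- 5                       # TJ row, y = 32 (0-based)
  img[30, 10] <- 2; img[36, 40] <- 3   # structure inside the band
  pair <- image_pair(img, img, 20, "planar")
  tr2 <- junction_trace(rbind(c(6, 32), c(58, 32)))
  b <- extract_band(pair, tr2, width = 400, center_on = "reference")
  crop <- img[(33 - 10):(33 + 10), 7:59]
  expect_equal(b$chan2, crop)
  expect_identical(b$n_dropped, 0L)

  # straightness filter applies in planar orientation
  wavy <- junction_trace(rbind(c(6, 20), c(30, 40), c(58, 20)))
  expect_error(extract_band(pair, wavy), "straightness")
})

test_that("extract_band is rotation-equivariant within interpolation tolerance", {
  base <- scene_params(image_shape = c(160L, 160L), n_clusters = 10L,
                       offset_perp_sd = 60, seed = 13L)
  sim <- simulate_junction_scene(base)
  band0 <- extract_band(sim$pair, sim$trace, width = 400)

  # rotate the scene 45 degrees about the image center and re-render
  # analytically (same physical scene, different raster orientation)
  ctr <- (base$image_shape[2:1] - 1) / 2 * base$pixel_size
  rot <- function(p, ang = pi / 4) {
    R <- rbind(c(cos(ang), -sin(ang)), c(sin(ang), cos(ang)))
    sweep(sweep(as.matrix(p), 2, ctr) %*% t(R), 2, ctr, `+`)
  }
  centers_r <- rot(sim$truth$centers_nm)
  path_r <- rot(base$junction_path * base$pixel_size) / base$pixel_size
  pr <- base; pr$junction_path <- path_r
  ch1r <- junctionmap:::render_tj_line(pr)
  ch2r <- render_channel(centers_r, pr, fwhm = sim$truth$fwhm_nm,
                         amplitude = sim$truth$amplitude)
  pair_r <- image_pair(ch1r, ch2r, base$pixel_size, "planar")
  band_r <- extract_band(pair_r, junction_trace(path_r), width = 400)

  n <- min(ncol(band0$chan2), ncol(band_r$chan2))
  d <- band0$chan2[, 1:n] - band_r$chan2[, 1:n]
  rms <- sqrt(mean(d^2))
  expect_lt(rms / max(band0$chan2), 0.02)
})

test_that("concatenate_bands: identity, lengths, seam-safe correlation oracle", {
  p <- small_params(seed = 41L)
  b1 <- extract_band(simulate_junction_scene(p)$pair,
                     simulate_junction_scene(p)$trace, width = 400)
  one <- concatenate_bands(list(b1))
  expect_equal(one$chan1, b1$chan1)
  p2 <- small_params(seed = 42L)
  sim2 <- simulate_junction_scene(p2)
  b2 <- extract_band(sim2$pair, sim2$trace, width = 400)
  both <- concatenate_bands(list(b1, b2))
  expect_identical(ncol(both$chan1), ncol(b1$chan1) + ncol(b2$chan1))

  # composite correlation = pair-count-weighted combination of per-band
  # correlations (independent oracle: stats::cor per band)
  max_lag <- 10L
  cc <- correlation_function(both$chan1, both$chan2, both$band_id, max_lag)
  for (d in c(-7L, 0L, 4L)) {
    num <- 0; den <- 0
    for (b in list(b1, b2)) {
      n <- ncol(b$chan1)
      ia <- if (d >= 0) 1:(n - d) else (1 - d):n
      ib <- if (d >= 0) (1 + d):n else 1:(n + d)
      r <- stats::cor(as.vector(b$chan1[, ia]), as.vector(b$chan2[, ib]))
      w <- length(ia) * nrow(b$chan1)
      num <- num + w * r; den <- den + w
    }
    expect_equal(cc$values[cc$lags == d], num / den, tolerance = 1e-12)
  }

  bad <- b2; bad$chan1 <- bad$chan1[-1, ]; bad$chan2 <- bad$chan2[-1, ]
  expect_error(concatenate_bands(list(b1, bad)), "heterogeneous")
})

test_that("correlation_function: autocorrelation, shift theorem, null, symmetry", {
  set.seed(5)
  a <- matrix(rnorm(21 * 300), 21, 300)
  auto <- correlation_function(a, a, max_lag = 12)
  expect_equal(auto$values[auto$lags == 0], 1)
  expect_true(all(abs(auto$values) <= 1 + 1e-12))

  k <- 4L
  b <- cbind(a[, (300 - k + 1):300], a[, 1:(300 - k)])   # B = A shifted by k
  sh <- correlation_function(a, b, max_lag = 12)
  expect_identical(sh$lags[which.max(sh$values)], k)

  # white-noise null at ~1e5 pixel pairs
  set.seed(6)
  w1 <- matrix(rnorm(21 * 5000), 21, 5000)
  w2 <- matrix(rnorm(21 * 5000), 21, 5000)
  nul <- correlation_function(w1, w2, max_lag = 10)
  expect_true(all(abs(nul$values) < 0.02))

  # symmetry: A-vs-B equals B-vs-A with lags negated
  ab <- correlation_function(a, b, max_lag = 12)
  ba <- correlation_function(b, a, max_lag = 12)
  expect_equal(ab$values, rev(ba$values), tolerance = 1e-9)

  expect_error(correlation_function(matrix(1, 3, 50), a[1:3, 1:50], max_lag = 5),
               "zero variance")
})

test_that("peak_amplitude: flat, delta, constructed Gaussian", {
  flat <- structure(list(lags = -20:20, values = rep(0.3, 41)),
                    class = "correlation_curve")
  expect_equal(peak_amplitude(flat), 0, tolerance = 1e-9)

  delta <- structure(list(lags = -20:20, values = c(rep(0, 20), 1, rep(0, 20))),
                     class = "correlation_curve")
  expect_equal(peak_amplitude(delta, exclude_zero_lag = FALSE), 1, tolerance = 1e-3)

  lags <- -30:30
  curve <- structure(list(lags = lags,
                          values = 0.2 + 0.5 * exp(-lags^2 / (2 * 3.2^2))),
                     class = "correlation_curve")
  expect_equal(peak_amplitude(curve), 0.5, tolerance = 1e-3)
  expect_error(peak_amplitude(structure(list(lags = -20:20,
                                             values = c(rep(0, 20), NA, rep(0, 20))),
                                        class = "correlation_curve")),
               "non-finite")
})

test_that("proximity_indices and venn_fractions follow the defining ratios", {
  r <- proximity_indices(0.8, 0.4, 0.2)
  expect_equal(r$P1, 0.5)
  expect_equal(r$P2, 0.25)
  expect_equal(proximity_indices(1, 1, 0)$P1, 0)
  a <- 0.37
  ri <- proximity_indices(a, a, a)
  expect_equal(ri$P1, 1); expect_equal(ri$P2, 1)
  expect_error(proximity_indices(0, 1, 0.5), "> 0")

  v <- venn_fractions(r)
  expect_equal(unname(v$protein1), c(0.5, 0.5))
  expect_equal(unname(v$protein2), c(0.25, 0.75))
  v1 <- venn_fractions(proximity_indices(0.2, 0.2, 0.4))  # P > 1 clamps in venn
  expect_equal(unname(v1$protein1), c(1, 0))
})

test_that("PPI invariances: identity, affine intensity, band self-pairing", {
  p <- small_params(seed = 51L, poisson_noise = TRUE)
  sim <- simulate_junction_scene(p)
  ch <- sim$pair$channel_target

  idp <- image_pair(ch, ch, p$pixel_size, "planar")
  res <- ppi_analysis(list(idp), list(sim$trace), center_on = "trace")
  expect_equal(res$P1, 1, tolerance = 1e-6)
  expect_equal(res$P2, 1, tolerance = 1e-6)

  # affine rescaling of one channel leaves the indices unchanged
  aff <- image_pair(ch, 3.5 * ch + 12, p$pixel_size, "planar")
  res_aff <- ppi_analysis(list(aff), list(sim$trace), center_on = "trace")
  expect_equal(res_aff$P1, res$P1, tolerance = 1e-6)
  expect_equal(res_aff$P2, res$P2, tolerance = 1e-6)
})

test_that("PPI null calibration: disjoint channels give index near 0", {
  sims <- lapply(1:30, function(s) simulate_pair_with_overlap(
    scene_params(image_shape = c(192L, 512L), n_clusters = 8L,
                 offset_perp_sd = 60, poisson_noise = TRUE, seed = 100L + s),
    0, min_sep = 5 * 80))
  res <- ppi_on_sims(sims)
  expect_gte(res$P1, -0.05); expect_lte(res$P1, 0.10)
  expect_gte(res$P2, -0.05); expect_lte(res$P2, 0.10)
})

test_that("apparent PPI rises when resolution along the separation axis drops", {
  # same 3D-offset configuration: channel B displaced 150 nm from channel A
  # perpendicular to the junction; with an 80-nm PSF the pair is resolved,
  # with a 550-nm PSF along that axis (axial resolution of an apico-basal
  # projection) it is not
  mk <- function(psf_perp) {
    p <- scene_params(image_shape = c(192L, 384L), n_clusters = 10L,
                      offset_perp_sd = 30, seed = 61L)
    sim <- simulate_junction_scene(p)
    ca <- sim$truth$centers_nm
    cb <- ca; cb[, 2] <- cb[, 2] - 150
    pair <- image_pair(render_channel(ca, p, psf_fwhm = c(80, psf_perp)),
                       render_channel(cb, p, psf_fwhm = c(80, psf_perp)),
                       p$pixel_size, "planar")
    ppi_on_sims(list(list(pair = pair, trace = sim$trace)))$P1
  }
  expect_gt(mk(550), mk(80) + 0.2)
})
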