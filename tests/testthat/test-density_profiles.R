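# Bilinear sampling, profile extraction, reference rules, pooling.

test_that("bilinear_sample matches the closed form and reproduces affine fields", {
  img <- matrix(c(0, 1, 0, 1), 2, 2)        # f(x, y) = y with 0-based coords
  expect_equal(bilinear_sample(img, 0.5, 0.5), 0.5)

  # closed-form oracle on random 2x2 values at (0.25, 0.75)
  set.seed(1)
  v <- matrix(runif(4), 2, 2)               # v[r, c], (x, y) = (c-1, r-1)
  fx <- 0.25; fy <- 0.75
  oracle <- (1 - fx) * (1 - fy) * v[1, 1] + fx * (1 - fy) * v[1, 2] +
    (1 - fx) * fy * v[2, 1] + fx * fy * v[2, 2]
  expect_equal(bilinear_sample(v, 0.25, 0.75), oracle)

  # ramp f(x, y) = x is reproduced exactly at any interior point
  ramp <- matrix(rep(0:9, each = 8), 8, 10, byrow = FALSE)
  ramp <- t(matrix(rep(0:9, 8), 10, 8))     # ramp[r, c] = c - 1 = x
  xs <- runif(20, 0, 9); ys <- runif(20, 0, 7)
  expect_equal(bilinear_sample(ramp, xs, ys), xs, tolerance = 1e-12)

  # affine field a + b x + c y exact (bilinear reproduces affine)
  a <- 2; b <- -0.7; cc <- 1.3
  aff <- outer(0:7, 0:9, function(r, c) a + b * c + cc * r)
  expect_equal(bilinear_sample(aff, xs, ys), a + b * xs + cc * ys,
               tolerance = 1e-12)

  expect_error(bilinear_sample(ramp, -0.1, 2), "outside image interior")
  expect_error(bilinear_sample(ramp, 2, 7.5), "outside image interior")
})

test_that("sample_perpendicular_profiles: line count, constants, ramp oracle", {
  px <- 20
  img_c <- matrix(3.7, 64, 64)
  pair <- image_pair(img_c, img_c, px, "planar")
  tr <- junction_trace(rbind(c(10, 32), c(50, 32)))   # arc length 40 px = 800 nm
  st <- sample_perpendicular_profiles(pair, tr, half_length = 200, step = px)
  expect_equal(nrow(st$ref), floor(800 / 20) + 1)       # floor(L/s) + 1 lines
  expect_true(all(st$ref == 3.7))
  expect_true(all(st$target == 3.7))

  # ramp f(x,y) = y sampled perpendicular to a horizontal trace is linear
  # with slope 1/pixel_size per nm (direction = perp of +x tangent = +y)
  ramp <- matrix(rep(0:63, 64), 64, 64)        # ramp[r, c] = r - 1 = y
  pair2 <- image_pair(ramp, ramp, px, "planar")
  st2 <- sample_perpendicular_profiles(pair2, tr, half_length = 200, step = px)
  expected <- 32 + st2$positions / px          # y = 32 at the trace
  for (i in seq_len(nrow(st2$ref))) expect_equal(st2$ref[i, ], expected)

  # out-of-interior lines are dropped and counted
  tr_edge <- junction_trace(rbind(c(10, 2), c(50, 2)))
  st3 <- sample_perpendicular_profiles(pair, tr_edge, half_length = 200, step = px)
  expect_identical(nrow(st3$ref), 0L)
  expect_identical(st3$n_dropped, 41L)
})

test_that("planar_reference: symmetry, ties, parabola oracle", {
  s <- 20
  expect_equal(planar_reference(c(0, 1, 0), c(-s, 0, s)), 0)
  expect_equal(planar_reference(c(0, 0.8, 1, 0.8, 0), c(-2, -1, 0, 1, 2) * s), 0)
  # closed-form three-point parabola on an asymmetric peak
  y <- c(0, 0.6, 1.0, 0.9, 0)
  delta <- 0.5 * (y[2] - y[4]) / (y[2] - 2 * y[3] + y[4])
  expect_equal(planar_reference(y, (0:4) * s), 2 * s + delta * s)
  expect_error(planar_reference(c(2, 2, 2)), "constant")
  # tie broken toward the midpoint (discrete max at index 2, parabola +0.5)
  expect_equal(planar_reference(c(1, 0, 1, 1, 0, 1), 0:5), 2.5)
})

test_that("apicobasal_reference: exact hit, interpolated crossing, flagged", {
  r1 <- apicobasal_reference(c(0, 1.5, 3, 9, 6), 1/3)   # threshold 3
  expect_equal(r1$index, 2)
  expect_false(r1$flagged)

  r2 <- apicobasal_reference(c(0, 2, 4, 8), 1/3)        # threshold 8/3
  expect_equal(r2$index, 1 + (8/3 - 2) / (4 - 2))
  expect_false(r2$flagged)

  r3 <- apicobasal_reference(c(9, 1, 2), 1/3)
  expect_identical(r3$index, 0)
  expect_true(r3$flagged)
  expect_error(apicobasal_reference(c(0, 0, 0)), "maximum must be > 0")
})

test_that("align_and_normalize: scale invariance, unit integral, shift oracle", {
  positions <- seq(-200, 200, by = 20)
  shape <- exp(-(positions / 60)^2)
  stack <- structure(list(positions = positions,
                          ref = rbind(shape, shape),
                          target = rbind(2 * shape, 2 * shape),
                          step = 20, n_dropped = 0L),
                     class = "profile_stack")
  a <- align_and_normalize(stack, c(0, 0), "unit_integral")
  stack5 <- stack; stack5$ref <- 5 * stack$ref; stack5$target <- 5 * stack$target
  b <- align_and_normalize(stack5, c(0, 0), "unit_integral")
  expect_equal(a$target, b$target)            # scale invariance (exact)
  expect_equal(sum(a$target) * 20, 1, tolerance = 1e-9)
  expect_equal(sum(a$ref) * 20, 1, tolerance = 1e-9)

  # two identical shapes whose references differ by exactly 2 samples align
  sh2 <- c(shape[-(1:2)], 0, 0)               # shape shifted left 2 samples
  stack_sh <- stack
  stack_sh$ref <- rbind(shape, sh2); stack_sh$target <- rbind(shape, sh2)
  al <- align_and_normalize(stack_sh, c(0, -40), "unit_max")
  ok <- !is.na(al$target)
  one <- align_and_normalize(structure(list(positions = positions,
                                            ref = rbind(shape), target = rbind(shape),
                                            step = 20, n_dropped = 0L),
                                       class = "profile_stack"), 0, "unit_max")
  expect_equal(al$target[ok], one$target[ok], tolerance = 1e-9)

  expect_error(align_and_normalize(structure(list(positions = positions,
                                                  ref = stack$ref[0, , drop = FALSE],
                                                  target = stack$target[0, , drop = FALSE],
                                                  step = 20), class = "profile_stack"),
                                   numeric(0)), "empty")
})

test_that("pool_density: SD semantics and mismatched grids", {
  jp <- function(v, pos = seq_along(v)) structure(
    list(positions = pos, ref = v, target = v, n_lines = 1L),
    class = "junction_profile")
  two <- pool_density(list(jp(c(1, 2, 3)), jp(c(1, 2, 3))))
  expect_equal(two$mean, c(1, 2, 3))
  expect_true(all(two$sd == 0))
  mix <- pool_density(list(jp(c(0, 0)), jp(c(1, 0))), channel = "target")
  expect_equal(mix$mean[1], 0.5)
  expect_equal(mix$sd[1], 0.7071, tolerance = 1e-4)
  expect_identical(mix$n_junctions, 2L)
  expect_error(pool_density(list(jp(c(1, 2)), jp(c(1, 2, 3), 1:3))), "grid")
  # mean + SD envelope always lies at or above the mean
  expect_true(all(mix$mean + mix$sd >= mix$mean))
})

test_that("pooled profiles recover simulated perpendicular offsets", {
  profs <- lapply(1:10, function(s) {
    p <- small_params(offset_perp_mean = 200, offset_perp_sd = 30, seed = s,
                      poisson_noise = TRUE)
    sim <- simulate_junction_scene(p)
    profile_junction(sim$pair, sim$trace, half_length = 600)
  })
  pooled <- pool_density(profs)
  peak <- pooled$positions[which.max(pooled$mean)]
  expect_lte(abs(peak - 200), 20)
  # TJ-reference channel peaks at 0 by construction of the reference
  ref <- pool_density(profs, "ref")
  expect_lte(abs(ref$positions[which.max(ref$mean)]), 20)
})

test_that("density_map_2d is the outer product with labeled axes", {
  dp <- function(m, pos) structure(list(positions = pos, mean = m,
                                        sd = m * 0, n_junctions = 1L),
                                   class = "density_profile")
  pl <- dp(c(0, 1, 0), c(-20, 0, 20))
  ab <- dp(c(0, 0, 2, 0), c(-20, 0, 20, 40))
  m <- density_map_2d(pl, ab)
  expect_equal(dim(m$map), c(4L, 3L))
  expect_equal(sum(m$map != 0), 1L)
  expect_equal(m$map[3, 2], 2)
  # uniform profiles give a uniform map; rows proportional to the AB profile
  u <- density_map_2d(dp(rep(1, 3), pl$positions), dp(rep(2, 4), ab$positions))
  expect_true(all(u$map == 2))
  set.seed(2)
  r1 <- dp(runif(5), 1:5); r2 <- dp(runif(7), 1:7)
  mm <- density_map_2d(r1, r2)
  expect_equal(mm$map, outer(r2$mean, r1$mean))
  expect_equal(rowSums(mm$map), r2$mean * sum(r1$mean))
})

test_that("apico-basal junction profiles use the 1/3-max apical edge", {
  # TJ line spread along the apico-basal axis; target clusters apical of it
  p <- scene_params(image_shape = c(128L, 128L), n_clusters = 8L,
                    tj_line_width = 150, offset_perp_mean = 150,
                    offset_perp_sd = 20, seed = 21L)
  sim <- simulate_junction_scene(p, orientation = "apico_basal")
  prof <- profile_junction(sim$pair, sim$trace, half_length = 600)
  # positive perpendicular offsets point along the apical direction, so the
  # target peak must sit apical (positive) of the TJ reference
  expect_gt(prof$positions[which.max(prof$target)], 0)
})
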