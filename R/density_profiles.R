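# Junction-referenced protein density profiles.
#
# Pipeline: sample intensity profiles perpendicular to the junction (planar)
# or along the apico-basal axis (apico-basal sections), all along each
# junction, using bilinear sub-pixel interpolation; locate the TJ-marker
# reference on every line (planar: intensity maximum, refined by a 3-point
# parabola; apico-basal: most apical 1/3-of-max crossing); re-index each
# line so the reference sits at 0; normalize per junction; pool across
# junctions into a mean +- SD density curve.

#' Bilinear sub-pixel sampling
#'
#' Interpolates image intensity at sub-pixel positions using the four
#' surrounding pixel centers. Coordinates are 0-based pixel centers
#' (x = column, y = row): the matrix entry `image[r, c]` sits at
#' (x, y) = (c-1, r-1). Vectorized over points.
#'
#' @param image numeric matrix.
#' @param x,y coordinates; every point must satisfy 0 <= x <= ncol-1 and
#'   0 <= y <= nrow-1.
#' @return numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(image, x, y) {
  nr <- nrow(image); nc <- ncol(image)
  bad <- which(x < 0 | x > nc - 1 | y < 0 | y > nr - 1 |
               !is.finite(x) | !is.finite(y))
  if (length(bad))
    stopf("sample point outside image interior: (x=%.4g, y=%.4g)",
          x[bad[1]], y[bad[1]])
  ix <- pmin(floor(x), nc - 2); iy <- pmin(floor(y), nr - 2)
  fx <- x - ix; fy <- y - iy
  i00 <- (ix) * nr + iy + 1          # column-major linear index of (iy, ix)
  v00 <- image[i00];      v10 <- image[i00 + nr]
  v01 <- image[i00 + 1];  v11 <- image[i00 + nr + 1]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Sample intensity profiles along a junction
#'
#' Lays one sampling line per arc-length step along the trace. Planar
#' orientation: lines run along the local perpendicular (from the
#' central-difference tangent of the trace). Apico-basal orientation: lines
#' run along the trace's `apical_direction`. Both channels are sampled with
#' [bilinear_sample()] at uniform steps; positive positions point toward
#' the positive perpendicular (planar) or apically (apico-basal). Lines
#' with any sample outside the image interior are dropped and counted.
#'
#' @param pair an [image_pair()].
#' @param trace a [junction_trace()] on that image.
#' @param half_length half line length in nm (profile spans +-half_length).
#' @param step sample (and line) spacing in nm; default = pixel size.
#' @return a `profile_stack`: list with `positions` (signed nm), matrices
#'   `ref` and `target` (lines x samples), `step`, `n_dropped`,
#'   `line_centers_px`.
#' @export
sample_perpendicular_profiles <- function(pair, trace,
                                          half_length = 1000,
                                          step = pair$pixel_size) {
  if (step <= 0) stopf("step must be > 0")
  if (half_length < step) stopf("half_length must be >= step")
  px <- pair$pixel_size
  rs <- polyline_resample(trace$points, step / px)  # arc steps in px
  n_lines <- nrow(rs$positions)
  positions <- seq(-half_length, half_length, by = step)
  if (pair$orientation == "apico_basal") {
    if (is.null(trace$apical_direction))
      stopf("apico-basal sampling needs trace$apical_direction")
    dirs <- matrix(rep(trace$apical_direction, each = n_lines), ncol = 2)
  } else {
    dirs <- t(apply(rs$tangents, 1, perp2))
  }
  nr <- nrow(pair$channel_ref); nc <- ncol(pair$channel_ref)
  ref <- matrix(NA_real_, n_lines, length(positions))
  tgt <- matrix(NA_real_, n_lines, length(positions))
  keep <- logical(n_lines)
  for (i in seq_len(n_lines)) {
    xs <- rs$positions[i, 1] + dirs[i, 1] * positions / px
    ys <- rs$positions[i, 2] + dirs[i, 2] * positions / px
    if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)) next
    ref[i, ] <- bilinear_sample(pair$channel_ref, xs, ys)
    tgt[i, ] <- bilinear_sample(pair$channel_target, xs, ys)
    keep[i] <- TRUE
  }
  structure(list(positions = positions,
                 ref = ref[keep, , drop = FALSE],
                 target = tgt[keep, , drop = FALSE],
                 step = step, n_dropped = sum(!keep),
                 line_centers_px = rs$positions[keep, , drop = FALSE]),
            class = "profile_stack")
}

#' Planar TJ reference: sub-sample intensity maximum
#'
#' Position of the maximum of a TJ-marker profile, refined to sub-sample
#' precision by fitting a parabola through the maximum and its two
#' neighbors. Ties in the discrete maximum are broken toward the profile
#' midpoint.
#'
#' @param values profile intensities.
#' @param positions sample positions (uniform step); defaults to 0-based
#'   sample indices.
#' @return reference position in the units of `positions`.
#' @export
planar_reference <- function(values, positions = seq_along(values) - 1) {
  if (length(values) < 2 || diff(range(values)) == 0)
    stopf("no reference: profile is constant")
  mx <- which(values == max(values))
  mid <- (length(values) + 1) / 2
  i <- mx[which.min(abs(mx - mid))]
  if (i > 1 && i < length(values)) {
    y0 <- values[i - 1]; y1 <- values[i]; y2 <- values[i + 1]
    den <- y0 - 2 * y1 + y2
    delta <- if (den != 0) 0.5 * (y0 - y2) / den else 0
    delta <- min(max(delta, -0.5), 0.5)
  } else delta <- 0
  s <- if (length(positions) > 1) positions[2] - positions[1] else 1
  positions[i] + delta * s
}

#' Apico-basal TJ reference: most apical 1/3-of-max crossing
#'
#' Scanning a TJ-marker profile from its apical end, returns the first
#' position where intensity reaches `fraction` of the profile maximum, with
#' linear interpolation between the bracketing samples. TJs spread along
#' the apico-basal axis by variable amounts (up to about threefold), so a
#' fractional-threshold crossing gives a reproducible apical edge where the
#' raw maximum does not.
#'
#' @param values intensities ordered apical first.
#' @param fraction threshold as a fraction of the maximum (default 1/3).
#' @return list with `index` (0-based fractional sample position along the
#'   apical-to-basal ordering) and `flagged` (TRUE when the first sample is
#'   already at/above threshold, in which case the apical end is returned).
#' @export
apicobasal_reference <- function(values, fraction = 1/3) {
  m <- max(values)
  if (m <= 0) stopf("no reference: profile maximum must be > 0")
  thr <- fraction * m
  if (values[1] >= thr) return(list(index = 0, flagged = TRUE))
  i <- which(values >= thr)[1]
  idx <- (i - 2) + (thr - values[i - 1]) / (values[i] - values[i - 1])
  list(index = idx, flagged = FALSE)
}

#' Align lines on their reference and normalize per junction
#'
#' Re-indexes each sampled line so its TJ reference sits at position 0,
#' re-grids all lines of the junction onto the stack's common grid by
#' linear interpolation, averages them, and scales the result: mode
#' `"unit_integral"` scales each channel so its integral (sum x step) is 1;
#' `"unit_max"` scales each channel to maximum 1. Either mode removes
#' junction-to-junction intensity variation.
#'
#' @param stack a `profile_stack` from [sample_perpendicular_profiles()].
#' @param refs per-line reference positions (same units as
#'   `stack$positions`).
#' @param mode `"unit_integral"` (default; density reading) or `"unit_max"`.
#' @return a `junction_profile`: list with `positions`, `ref`, `target`
#'   (normalized mean profiles; NA where no line covers the grid point),
#'   `n_lines`.
#' @export
align_and_normalize <- function(stack, refs,
                                mode = c("unit_integral", "unit_max")) {
  mode <- match.arg(mode)
  n <- nrow(stack$ref)
  if (n == 0) stopf("empty profile stack")
  if (length(refs) != n) stopf("need one reference per line (%d lines)", n)
  if (any(!is.finite(refs))) stopf("references must be finite")
  grid <- stack$positions
  regrid <- function(mat) {
    out <- matrix(NA_real_, n, length(grid))
    for (i in seq_len(n)) {
      out[i, ] <- stats::approx(stack$positions - refs[i], mat[i, ],
                                xout = grid, rule = 1)$y
    }
    colMeans(out, na.rm = TRUE)
  }
  ref_m <- regrid(stack$ref)
  tgt_m <- regrid(stack$target)
  ref_m[is.nan(ref_m)] <- NA; tgt_m[is.nan(tgt_m)] <- NA
  scale_one <- function(v) {
    s <- if (mode == "unit_integral") sum(v, na.rm = TRUE) * stack$step
         else max(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stopf("cannot normalize: profile has no mass")
    v / s
  }
  structure(list(positions = grid, ref = scale_one(ref_m),
                 target = scale_one(tgt_m), n_lines = n),
            class = "junction_profile")
}

#' Pool per-junction profiles into a density curve
#'
#' Mean and sample SD (n-1 denominator; SD = 0 when n = 1) across junctions
#' at each position, the junction being the statistical unit. All profiles
#' must share the same position grid.
#'
#' @param junction_profiles list of `junction_profile` objects.
#' @param channel `"target"` (default) or `"ref"`.
#' @return a `density_profile`: list with `positions` (signed nm, 0 = TJ
#'   reference), `mean`, `sd`, `n_junctions`.
#' @export
pool_density <- function(junction_profiles, channel = c("target", "ref")) {
  channel <- match.arg(channel)
  if (!length(junction_profiles)) stopf("need >= 1 junction profile")
  grid <- junction_profiles[[1]]$positions
  for (jp in junction_profiles)
    if (length(jp$positions) != length(grid) || any(jp$positions != grid))
      stopf("junction profiles are on mismatched grids")
  m <- do.call(rbind, lapply(junction_profiles, `[[`, channel))
  n <- nrow(m)
  mu <- colMeans(m, na.rm = TRUE)
  sdv <- if (n == 1) rep(0, ncol(m)) else apply(m, 2, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv)] <- 0
  structure(list(positions = grid, mean = mu, sd = sdv, n_junctions = n,
                 channel = channel),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  pk <- x$positions[which.max(x$mean)]
  cat(sprintf("<density_profile> %s channel, %d junctions, peak at %+g nm\n",
              x$channel, x$n_junctions, pk))
  invisible(x)
}

#' Plot a pooled density profile (mean, with mean+SD envelope)
#'
#' Dark curve: mean; light curve: mean + SD.
#'
#' @param x a `density_profile`.
#' @param col base color.
#' @param ... passed to [graphics::plot()].
#' @export
plot.density_profile <- function(x, col = "magenta4", ...) {
  graphics::plot(x$positions, x$mean + x$sd, type = "l",
                 col = grDevices::adjustcolor(col, 0.4),
                 xlab = "position vs. TJ reference (nm)",
                 ylab = "normalized density", ...)
  graphics::lines(x$positions, x$mean, col = col, lwd = 2)
  invisible(x)
}

#' 2D product map of planar and apico-basal density profiles
#'
#' `map[i, j] = apico_basal$mean[i] * planar$mean[j]`: the outer product
#' used to visualize average protein localization in the plane spanned by
#' the apico-basal axis and the junction-perpendicular, with (0, 0) at the
#' TJ reference.
#'
#' @param planar,apico_basal `density_profile` objects.
#' @return a `density_map`: list with `map`, `ab_positions`,
#'   `planar_positions`.
#' @export
density_map_2d <- function(planar, apico_basal) {
  if (!length(planar$mean) || !length(apico_basal$mean))
    stopf("profiles must be non-empty")
  structure(list(map = outer(apico_basal$mean, planar$mean),
                 ab_positions = apico_basal$positions,
                 planar_positions = planar$positions),
            class = "density_map")
}

#' Per-junction density profile (convenience wrapper)
#'
#' Samples profiles along one junction, finds the per-line TJ reference
#' (planar maximum or apico-basal 1/3-max crossing, per the pair's
#' orientation), and returns the aligned, normalized junction profile.
#'
#' @param pair an [image_pair()].
#' @param trace a [junction_trace()].
#' @param half_length,step see [sample_perpendicular_profiles()].
#' @param fraction apico-basal threshold fraction (default 1/3).
#' @param mode normalization mode, see [align_and_normalize()].
#' @param apical_positive logical; in apico-basal stacks, positions are
#'   signed with apical positive (the sampling direction).
#' @return a `junction_profile`.
#' @export
profile_junction <- function(pair, trace, half_length = 1000,
                             step = pair$pixel_size, fraction = 1/3,
                             mode = "unit_integral", apical_positive = TRUE) {
  stack <- sample_perpendicular_profiles(pair, trace, half_length, step)
  if (nrow(stack$ref) == 0) stopf("all sampling lines left the image interior")
  refs <- vapply(seq_len(nrow(stack$ref)), function(i) {
    v <- stack$ref[i, ]
    if (pair$orientation == "planar") {
      planar_reference(v, stack$positions)
    } else {
      # stack positions run basal -> apical when apical_positive; the
      # reference scan runs apical -> basal
      ord <- rev(seq_along(v))
      r <- apicobasal_reference(v[ord], fraction)
      rev(stack$positions)[1] - r$index * stack$step
    }
  }, 0)
  align_and_normalize(stack, refs, mode)
}
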