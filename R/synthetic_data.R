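# Ground-truthed synthetic junction scenes and immunogold particle sets.
#
# Forward model: every fluorescent structure is an isotropic 2D Gaussian of
# known integrated intensity. A protein cluster of FWHM w imaged through a
# Gaussian PSF of FWHM p is again Gaussian with variance sigma_w^2 +
# sigma_p^2, so blurred scenes are rendered analytically (exact, and mass
# is conserved away from borders by construction). The tight-junction
# marker is a line source: a Gaussian cross-section of tj_line_width FWHM
# swept along the junction polyline. Poisson noise, when enabled, is
# applied last to gain * image.

#' Parameters of a synthetic junction scene
#'
#' Defaults describe the imaging regime the analysis is built for: 20 nm
#' pixels (4 px per 80-nm PSF FWHM), protein clusters 80-200 nm in size,
#' and a bright tight-junction line along a junction path.
#'
#' @param image_shape c(rows, cols) in pixels.
#' @param pixel_size nm per pixel, > 0.
#' @param junction_path n x 2 polyline in 0-based pixel coordinates, or NULL
#'   for a horizontal line through the image center.
#' @param tj_amplitude integrated TJ-line intensity per nm of junction length
#'   (arbitrary units).
#' @param tj_line_width FWHM (nm) of the TJ line cross-section before PSF.
#' @param n_clusters clusters per target channel.
#' @param cluster_fwhm length-2 range (nm); each cluster's FWHM is drawn
#'   uniformly in it. Must lie within [40, 400] nm.
#' @param cluster_amplitude integrated intensity per cluster (scalar, or
#'   length-2 range for uniform draws).
#' @param offset_perp_mean,offset_perp_sd signed perpendicular offset (nm) of
#'   target clusters from the junction: Normal(mean, sd). The positive
#'   perpendicular is the path tangent rotated +90 degrees; for the default
#'   left-to-right path in image coordinates (y down) it points toward
#'   larger y. The same direction serves as the apical axis of apico-basal
#'   scenes, so positive offsets read as apical of the junction.
#' @param overlap_fraction fraction in [0, 1] of channel-B cluster centers
#'   copied from channel A (used by [simulate_pair_with_overlap()]).
#' @param psf_fwhm Gaussian PSF FWHM in nm.
#' @param background constant background intensity per pixel.
#' @param poisson_noise logical; apply Poisson noise as the last step.
#' @param gain counts per intensity unit for the Poisson stage.
#' @param seed integer; identical seed and parameters give bit-identical
#'   scenes.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(256L, 256L),
                         pixel_size = 20,
                         junction_path = NULL,
                         tj_amplitude = 200,
                         tj_line_width = 60,
                         n_clusters = 30L,
                         cluster_fwhm = c(80, 200),
                         cluster_amplitude = 1000,
                         offset_perp_mean = 0,
                         offset_perp_sd = 60,
                         overlap_fraction = 0,
                         psf_fwhm = 80,
                         background = 10,
                         poisson_noise = FALSE,
                         gain = 1,
                         seed = 1L) {
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be > 0")
  if (!is_scalar_num(overlap_fraction) || overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must lie in [0, 1]")
  if (length(cluster_fwhm) == 1) cluster_fwhm <- rep(cluster_fwhm, 2)
  if (cluster_fwhm[1] < 40 || cluster_fwhm[2] > 400 || cluster_fwhm[1] > cluster_fwhm[2])
    stopf("cluster_fwhm range must lie within [40, 400] nm")
  if (length(cluster_amplitude) == 1) cluster_amplitude <- rep(cluster_amplitude, 2)
  if (is.null(junction_path)) {
    rows <- image_shape[1]; cols <- image_shape[2]
    margin_px <- ceiling(3 * fwhm_to_sigma(psf_fwhm) / pixel_size) + 2
    junction_path <- rbind(c(margin_px, (rows - 1) / 2),
                           c(cols - 1 - margin_px, (rows - 1) / 2))
  }
  p <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
            junction_path = as.matrix(junction_path),
            tj_amplitude = tj_amplitude, tj_line_width = tj_line_width,
            n_clusters = as.integer(n_clusters), cluster_fwhm = cluster_fwhm,
            cluster_amplitude = cluster_amplitude,
            offset_perp_mean = offset_perp_mean, offset_perp_sd = offset_perp_sd,
            overlap_fraction = overlap_fraction, psf_fwhm = psf_fwhm,
            background = background, poisson_noise = isTRUE(poisson_noise),
            gain = gain, seed = as.integer(seed))
  structure(p, class = "scene_params")
}

# nm extent of the image (pixel centers span 0 .. (n-1)*pixel_size)
scene_extent_nm <- function(params) {
  c(x = (params$image_shape[2] - 1) * params$pixel_size,
    y = (params$image_shape[1] - 1) * params$pixel_size)
}

#' Render one channel from cluster centers
#'
#' Renders `background + sum of Gaussian blobs convolved with the PSF`; each
#' blob k has integrated intensity `amplitude[k]` and total sigma
#' `sqrt(sigma_fwhm[k]^2 + sigma_psf^2)`. Poisson noise is applied last when
#' `params$poisson_noise` is TRUE (on `gain * image`, then divided by gain).
#'
#' @param centers n x 2 matrix of (x, y) cluster centers in nm; must lie
#'   within the image bounds.
#' @param params a [scene_params()] object.
#' @param fwhm per-cluster FWHM (nm), recycled; defaults to the midpoint of
#'   `params$cluster_fwhm`.
#' @param amplitude per-cluster integrated intensity, recycled.
#' @param psf_fwhm PSF FWHM in nm; a length-2 vector gives an anisotropic
#'   PSF (x, y) — used to emulate the poorer axial resolution of apico-basal
#'   projections.
#' @param noise override the `poisson_noise` flag (logical or NULL).
#' @return numeric image matrix (rows x cols), intensities >= 0.
#' @export
render_channel <- function(centers, params, fwhm = NULL, amplitude = NULL,
                           psf_fwhm = params$psf_fwhm, noise = NULL) {
  centers <- matrix(as.numeric(centers), ncol = 2)
  ext <- scene_extent_nm(params)
  if (nrow(centers)) {
    bad <- which(centers[, 1] < 0 | centers[, 1] > ext["x"] |
                 centers[, 2] < 0 | centers[, 2] > ext["y"])
    if (length(bad))
      stopf("cluster center(s) outside image bounds: index %s",
            paste(bad, collapse = ", "))
  }
  if (is.null(fwhm)) fwhm <- mean(params$cluster_fwhm)
  if (is.null(amplitude)) amplitude <- mean(params$cluster_amplitude)
  fwhm <- rep_len(fwhm, nrow(centers))
  amplitude <- rep_len(amplitude, nrow(centers))
  if (length(psf_fwhm) == 1) psf_fwhm <- rep(psf_fwhm, 2)
  img <- matrix(params$background, params$image_shape[1], params$image_shape[2])
  px <- params$pixel_size
  for (k in seq_len(nrow(centers))) {
    sx <- sqrt(fwhm_to_sigma(fwhm[k])^2 + fwhm_to_sigma(psf_fwhm[1])^2)
    sy <- sqrt(fwhm_to_sigma(fwhm[k])^2 + fwhm_to_sigma(psf_fwhm[2])^2)
    img <- add_gaussian_blob(img, centers[k, 1], centers[k, 2], sx, sy,
                             amplitude[k], px)
  }
  apply_noise(img, params, noise)
}

# add one 2D Gaussian of integrated mass `amp` (center cx, cy nm; sigmas nm)
# evaluated on pixel centers within a +-6 sigma window
add_gaussian_blob <- function(img, cx, cy, sx, sy, amp, px) {
  c0 <- max(0L, floor((cx - 6 * sx) / px)); c1 <- min(ncol(img) - 1L, ceiling((cx + 6 * sx) / px))
  r0 <- max(0L, floor((cy - 6 * sy) / px)); r1 <- min(nrow(img) - 1L, ceiling((cy + 6 * sy) / px))
  if (c0 > c1 || r0 > r1) return(img)
  xs <- (c0:c1) * px; ys <- (r0:r1) * px
  gx <- exp(-(xs - cx)^2 / (2 * sx^2))
  gy <- exp(-(ys - cy)^2 / (2 * sy^2))
  dens <- amp * px^2 / (2 * pi * sx * sy)
  img[(r0:r1) + 1L, (c0:c1) + 1L] <- img[(r0:r1) + 1L, (c0:c1) + 1L] +
    dens * (gy %o% gx)
  img
}

# TJ marker: line source along the junction path; amplitude is intensity per
# nm of junction length. Approximated by dense point sources every sigma/5.
render_tj_line <- function(params, noise = NULL) {
  px <- params$pixel_size
  s_line <- fwhm_to_sigma(params$tj_line_width)
  s_psf <- fwhm_to_sigma(params$psf_fwhm)
  s_tot <- sqrt(s_line^2 + s_psf^2)
  path_nm <- params$junction_path * px
  step <- s_tot / 5
  rs <- polyline_resample(path_nm, step)
  img <- matrix(params$background, params$image_shape[1], params$image_shape[2])
  for (i in seq_len(nrow(rs$positions))) {
    img <- add_gaussian_blob(img, rs$positions[i, 1], rs$positions[i, 2],
                             s_tot, s_tot, params$tj_amplitude * step, px)
  }
  apply_noise(img, params, noise)
}

apply_noise <- function(img, params, noise = NULL) {
  use <- if (is.null(noise)) params$poisson_noise else isTRUE(noise)
  if (use) {
    v <- stats::rpois(length(img), pmax(img, 0) * params$gain) / params$gain
    img <- matrix(v, nrow(img), ncol(img))
  }
  pmax(img, 0)
}

# draw cluster centers along the junction path: arc position uniform, signed
# perpendicular offset Normal(mean, sd); centers are kept >= 3 sigma_psf from
# the borders (rejection sampling, bounded retries)
draw_cluster_centers <- function(params, n = params$n_clusters) {
  px <- params$pixel_size
  path_nm <- params$junction_path * px
  rs <- polyline_resample(path_nm, px)
  margin <- 3 * fwhm_to_sigma(params$psf_fwhm)
  ext <- scene_extent_nm(params)
  centers <- matrix(NA_real_, n, 2)
  offsets <- numeric(n)
  for (k in seq_len(n)) {
    for (try in seq_len(1000)) {
      t <- stats::runif(1, 0, rs$length)
      off <- stats::rnorm(1, params$offset_perp_mean, params$offset_perp_sd)
      at <- polyline_point_at(path_nm, t)
      p <- at$point + perp2(at$tangent) * off
      if (p[1] >= margin && p[1] <= ext["x"] - margin &&
          p[2] >= margin && p[2] <= ext["y"] - margin) {
        centers[k, ] <- p; offsets[k] <- off; break
      }
    }
    if (is.na(centers[k, 1]))
      stopf("could not place cluster %d within bounds after 1000 tries", k)
  }
  list(centers = centers, offsets = offsets)
}

#' Simulate a two-channel junction scene
#'
#' Channel 1 (reference) is a tight-junction marker line along
#' `params$junction_path`; channel 2 (target) is `n_clusters` protein
#' clusters at signed perpendicular offsets Normal(offset_perp_mean,
#' offset_perp_sd) from the junction. Ground truth (centers, offsets,
#' per-cluster FWHM and amplitude) is recorded.
#'
#' @param params a [scene_params()] object.
#' @param orientation orientation tag for the resulting [image_pair()]. For
#'   `"apico_basal"` the trace carries the apical direction (the positive
#'   perpendicular of the path).
#' @return list with elements `pair` ([image_pair()]), `trace`
#'   ([junction_trace()]) and `truth` (list: `centers_nm`, `offsets_nm`,
#'   `fwhm_nm`, `amplitude`).
#' @export
simulate_junction_scene <- function(params, orientation = c("planar", "apico_basal")) {
  orientation <- match.arg(orientation)
  if (nrow(params$junction_path) < 2) stopf("junction_path needs >= 2 points")
  with_seed(params$seed, {
    dr <- draw_cluster_centers(params)
    fw <- stats::runif(params$n_clusters, params$cluster_fwhm[1], params$cluster_fwhm[2])
    amp <- stats::runif(params$n_clusters, params$cluster_amplitude[1],
                        params$cluster_amplitude[2])
    ch1 <- render_tj_line(params)
    ch2 <- render_channel(dr$centers, params, fwhm = fw, amplitude = amp)
    apical <- {
      rs <- polyline_resample(params$junction_path, 1)
      u <- perp2(rs$tangents[1, ]); u / vnorm(u)
    }
    pair <- image_pair(ch1, ch2, params$pixel_size, orientation,
                       id = sprintf("sim-seed%d", params$seed))
    trace <- junction_trace(params$junction_path,
                            image_id = pair$id,
                            apical_direction = if (orientation == "apico_basal") apical else NULL)
    list(pair = pair, trace = trace,
         truth = list(centers_nm = dr$centers, offsets_nm = dr$offsets,
                      fwhm_nm = fw, amplitude = amp))
  })
}

#' Simulate a two-protein channel pair with a known shared-center fraction
#'
#' Both channels are cluster channels along the same junction path. A
#' fraction `f` of channel-B centers are exact copies of channel-A centers;
#' the remaining B centers are drawn at least `min_sep` away (Euclidean)
#' from every A center. This is the ground truth the proximity index is
#' supposed to estimate: intermediate index values read as the fraction of
#' one protein population in close proximity to the other.
#'
#' @param params a [scene_params()] object.
#' @param f overlap fraction in [0, 1]; `round(f * n_clusters)` centers are
#'   shared.
#' @param min_sep minimum distance (nm) of non-shared B centers from all A
#'   centers; default 3 x PSF FWHM.
#' @return list with `pair` ([image_pair()]: channel_ref = protein A,
#'   channel_target = protein B), `trace`, and `truth` (centers per channel,
#'   `shared_ids` (indices into B), `overlap_fraction`).
#' @export
simulate_pair_with_overlap <- function(params, f, min_sep = 3 * params$psf_fwhm) {
  if (!is_scalar_num(f) || f < 0 || f > 1) stopf("f must lie in [0, 1]")
  with_seed(params$seed, {
    n <- params$n_clusters
    a <- draw_cluster_centers(params)
    fw_a <- stats::runif(n, params$cluster_fwhm[1], params$cluster_fwhm[2])
    amp_a <- stats::runif(n, params$cluster_amplitude[1], params$cluster_amplitude[2])
    n_shared <- round(f * n)
    centers_b <- matrix(NA_real_, n, 2)
    fw_b <- numeric(n); amp_b <- numeric(n)
    shared_ids <- integer(0)
    if (n_shared > 0) {
      pick <- sample.int(n, n_shared)
      centers_b[seq_len(n_shared), ] <- a$centers[pick, , drop = FALSE]
      # a shared center is the same physical cluster seen in both channels
      fw_b[seq_len(n_shared)] <- fw_a[pick]
      amp_b[seq_len(n_shared)] <- amp_a[pick]
      shared_ids <- seq_len(n_shared)
    }
    if (n_shared < n) {
      margin <- 3 * fwhm_to_sigma(params$psf_fwhm)
      ext <- scene_extent_nm(params)
      path_nm <- params$junction_path * params$pixel_size
      rs <- polyline_resample(path_nm, params$pixel_size)
      for (k in (n_shared + 1):n) {
        placed <- FALSE
        for (try in seq_len(1000)) {
          t <- stats::runif(1, 0, rs$length)
          off <- stats::rnorm(1, params$offset_perp_mean, params$offset_perp_sd)
          at <- polyline_point_at(path_nm, t)
          p <- at$point + perp2(at$tangent) * off
          d2 <- (a$centers[, 1] - p[1])^2 + (a$centers[, 2] - p[2])^2
          if (min(d2) >= min_sep^2 &&
              p[1] >= margin && p[1] <= ext["x"] - margin &&
              p[2] >= margin && p[2] <= ext["y"] - margin) {
            centers_b[k, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed)
          stopf("could not place non-overlapping center %d after 1000 tries (scene too crowded)", k)
      }
    }
    if (n_shared < n) {
      idx <- (n_shared + 1):n
      fw_b[idx] <- stats::runif(length(idx), params$cluster_fwhm[1],
                                params$cluster_fwhm[2])
      amp_b[idx] <- stats::runif(length(idx), params$cluster_amplitude[1],
                                 params$cluster_amplitude[2])
    }
    ch_a <- render_channel(a$centers, params, fwhm = fw_a, amplitude = amp_a)
    ch_b <- render_channel(centers_b, params, fwhm = fw_b, amplitude = amp_b)
    pair <- image_pair(ch_a, ch_b, params$pixel_size, "planar",
                       id = sprintf("pair-f%.2f-seed%d", f, params$seed))
    trace <- junction_trace(params$junction_path, image_id = pair$id)
    list(pair = pair, trace = trace,
         truth = list(centers_a_nm = a$centers, centers_b_nm = centers_b,
                      shared_ids = shared_ids,
                      overlap_fraction = n_shared / n))
  })
}

#' Simulate an immunogold particle set with known membrane distances
#'
#' `(1 - outlier_fraction) * n` particles are placed at half-normal
#' distances (scale `displacement_sd`) from the membrane polyline — the
#' regime of membrane-anchored epitopes labeled through a primary +
#' gold-conjugated secondary antibody linkage. The remainder are placed in
#' a far zone (uniform distance in `far_zone`), standing in for cytoplasmic
#' label. Construction distances are recorded as ground truth.
#'
#' @param n number of particles, >= 1.
#' @param membrane m x 2 polyline (nm), m >= 2.
#' @param displacement_sd half-normal scale (nm) for membrane-bound particles.
#' @param outlier_fraction fraction in [0, 1] placed in the far zone.
#' @param seed integer seed.
#' @param far_zone length-2 range (nm) of far-zone distances.
#' @param tj_reference TJ reference point (nm); defaults to the first
#'   membrane vertex.
#' @param apical_axis unit vector; defaults to the average membrane normal.
#' @param side +1 or -1: which side of the membrane particles are placed on.
#' @return a [gold_particle_set()] whose `particles` data.frame additionally
#'   carries `true_distance_nm` and `is_outlier`.
#' @export
simulate_gold_particles <- function(n, membrane, displacement_sd,
                                    outlier_fraction = 0, seed = 1L,
                                    far_zone = c(100, 500),
                                    tj_reference = NULL, apical_axis = NULL,
                                    side = 1) {
  if (n < 1) stopf("n must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction > 1)
    stopf("outlier_fraction must lie in [0, 1]")
  membrane <- as.matrix(membrane)
  if (nrow(membrane) < 2) stopf("membrane polyline needs >= 2 points")
  with_seed(seed, {
    rs <- polyline_resample(membrane, 1)
    n_out <- round(outlier_fraction * n)
    n_near <- n - n_out
    d_true <- c(if (n_near) abs(stats::rnorm(n_near, 0, displacement_sd)) else numeric(0),
                if (n_out) stats::runif(n_out, far_zone[1], far_zone[2]) else numeric(0))
    is_out <- c(rep(FALSE, n_near), rep(TRUE, n_out))
    # keep a margin at the ends so the perpendicular foot is the true minimum
    margin <- min(max(d_true, 0) + 1, rs$length / 4)
    ts <- stats::runif(n, margin, rs$length - margin)
    xy <- t(vapply(seq_len(n), function(k) {
      at <- polyline_point_at(membrane, ts[k])
      at$point + side * perp2(at$tangent) * d_true[k]
    }, numeric(2)))
    if (is.null(apical_axis)) {
      u <- perp2(colMeans(rs$tangents)); apical_axis <- u / vnorm(u) * side
    }
    if (is.null(tj_reference)) tj_reference <- membrane[1, ]
    particles <- data.frame(id = seq_len(n), x_nm = xy[, 1], y_nm = xy[, 2],
                            true_distance_nm = d_true, is_outlier = is_out)
    gold_particle_set(particles, tj_reference, apical_axis, membrane)
  })
}
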