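# Protein-protein proximity index (PPI) on straightened junction bands.
#
# Junctions are straightened into two-channel bands 400 nm across, centered
# on the TJ reference (or on the trace itself for pair scenes without a TJ
# channel), concatenated, and auto-/cross-correlated along the junction
# axis. The index is the ratio of fitted correlation peak amplitudes:
# P1 = C12/A2 (fraction of protein 1 in proximity to protein 2) and
# P2 = C12/A1. A value of 0 reads as no proximity, 1 as perfect proximity,
# and intermediate values as the fraction of one protein population in
# close proximity to the other.

#' Junction straightness score
#'
#' Maximum perpendicular deviation of the trace vertices from the
#' end-to-end chord, divided by the chord length. 0 for a straight trace;
#' a semicircular arc scores 0.5. Junctions analyzed in planar orientation
#' are excluded when the score exceeds a threshold (default 0.05).
#'
#' @param trace a [junction_trace()] (or an n x 2 point matrix).
#' @return dimensionless score >= 0.
#' @export
junction_straightness <- function(trace) {
  pts <- if (inherits(trace, "junction_trace")) trace$points else as.matrix(trace)
  if (nrow(pts) < 2) stopf("trace needs >= 2 points")
  chord <- pts[nrow(pts), ] - pts[1, ]
  len <- vnorm(chord)
  if (len == 0) stopf("zero chord length: trace endpoints coincide")
  u <- chord / len
  rel <- sweep(pts, 2, pts[1, ])
  dev <- abs(rel[, 1] * u[2] - rel[, 2] * u[1])   # |cross(rel, u)|
  max(dev) / len
}

#' Extract a straightened junction band
#'
#' Resamples both channels on a regular grid hugging the junction: columns
#' at arc-length steps of one pixel along the trace, rows at one-pixel
#' steps across, centered per column either on the TJ reference (the
#' sub-sample maximum of the reference channel along the local
#' perpendicular) or on the trace itself. Row count is
#' `2*floor(width/(2*pixel_size)) + 1` (odd; center row = reference).
#' Columns whose samples leave the image interior are dropped and counted.
#'
#' @param pair an [image_pair()].
#' @param trace a [junction_trace()].
#' @param width band width across the junction, nm (default 400).
#' @param center_on `"reference"` (default; per-column TJ peak of
#'   `channel_ref`) or `"trace"` (geometric trace position; use for
#'   two-protein pairs with no TJ channel).
#' @param ref_half_length half-length (nm) of the per-column search profile
#'   for the TJ reference.
#' @param straightness_threshold when non-NULL and the pair is planar, the
#'   trace must pass [junction_straightness()] at this threshold.
#' @return a `junction_band`: list with matrices `chan1`, `chan2`
#'   (rows = across-junction, cols = along-junction), `width`, `pixel_size`,
#'   `id`, `n_dropped`.
#' @export
extract_band <- function(pair, trace, width = 400,
                         center_on = c("reference", "trace"),
                         ref_half_length = 300,
                         straightness_threshold = 0.05) {
  center_on <- match.arg(center_on)
  px <- pair$pixel_size
  if (!is.null(straightness_threshold) && pair$orientation == "planar") {
    sc <- junction_straightness(trace)
    if (sc > straightness_threshold)
      stopf("junction fails straightness filter: score %.3f > %.3f",
            sc, straightness_threshold)
  }
  rs <- polyline_resample(trace$points, 1)         # column per pixel of arc
  k <- floor(width / (2 * px))
  row_off <- (-k:k) * px                           # nm across the junction
  nr <- nrow(pair$channel_ref); nc <- ncol(pair$channel_ref)
  n_cols <- nrow(rs$positions)
  chan1 <- matrix(NA_real_, 2 * k + 1, n_cols)
  chan2 <- matrix(NA_real_, 2 * k + 1, n_cols)
  keep <- logical(n_cols)
  search <- seq(-ref_half_length, ref_half_length, by = px / 2)
  for (j in seq_len(n_cols)) {
    d <- perp2(rs$tangents[j, ])
    c0 <- rs$positions[j, ]
    if (center_on == "reference") {
      xs <- c0[1] + d[1] * search / px; ys <- c0[2] + d[2] * search / px
      if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)) next
      prof <- bilinear_sample(pair$channel_ref, xs, ys)
      if (diff(range(prof)) == 0) next
      ref_nm <- planar_reference(prof, search)
      c0 <- c0 + d * ref_nm / px
    }
    xs <- c0[1] + d[1] * row_off / px; ys <- c0[2] + d[2] * row_off / px
    if (any(xs < 0 | xs > nc - 1 | ys < 0 | ys > nr - 1)) next
    chan1[, j] <- bilinear_sample(pair$channel_ref, xs, ys)
    chan2[, j] <- bilinear_sample(pair$channel_target, xs, ys)
    keep[j] <- TRUE
  }
  if (!any(keep)) stopf("band entirely outside the image interior")
  structure(list(chan1 = chan1[, keep, drop = FALSE],
                 chan2 = chan2[, keep, drop = FALSE],
                 width = width, pixel_size = px, id = pair$id,
                 n_dropped = sum(!keep)),
            class = "junction_band")
}

#' Concatenate junction bands
#'
#' Places bands side by side along the junction axis and records which
#' source band each column belongs to, so that correlation lags never pair
#' pixels across a seam.
#'
#' @param bands list of `junction_band` objects with identical row count
#'   and pixel size.
#' @return a `band_composite`: list with `chan1`, `chan2`, `band_id`
#'   (integer per column), `pixel_size`, `total_length_nm`.
#' @export
concatenate_bands <- function(bands) {
  if (!length(bands)) stopf("no bands to concatenate")
  nr <- vapply(bands, function(b) nrow(b$chan1), 0L)
  pxs <- vapply(bands, `[[`, 0, "pixel_size")
  if (length(unique(nr)) != 1 || length(unique(pxs)) != 1)
    stopf("bands have heterogeneous shapes or pixel sizes")
  structure(list(
    chan1 = do.call(cbind, lapply(bands, `[[`, "chan1")),
    chan2 = do.call(cbind, lapply(bands, `[[`, "chan2")),
    band_id = rep(seq_along(bands), vapply(bands, function(b) ncol(b$chan1), 0L)),
    pixel_size = pxs[1],
    total_length_nm = sum(vapply(bands, function(b) ncol(b$chan1), 0L)) * pxs[1]),
    class = "band_composite")
}

#' Correlation function along the junction axis
#'
#' For each column lag `delta`, the normalized correlation coefficient
#' between `chanA(x, y)` and `chanB(x + delta, y)` over all pixel pairs
#' whose two columns fall in the same source band. Per band and lag, pixels
#' are standardized by the mean and SD of the overlapping support (Pearson
#' on the overlap); bands are pooled weighted by their pair counts, which
#' makes the composite value the pair-count-weighted mean of per-band
#' correlations. Non-circular.
#'
#' @param chanA,chanB matrices (rows x columns), same shape.
#' @param band_id integer vector, source band per column; NULL = one band.
#' @param max_lag maximum |lag| in columns (px); default half the shortest
#'   band length.
#' @return a `correlation_curve`: list with `lags` (px) and `values`.
#' @export
correlation_function <- function(chanA, chanB, band_id = NULL, max_lag = NULL) {
  if (!all(dim(chanA) == dim(chanB))) stopf("channel shapes differ")
  if (is.null(band_id)) band_id <- rep(1L, ncol(chanA))
  ids <- unique(band_id)
  lens <- vapply(ids, function(b) sum(band_id == b), 0L)
  if (is.null(max_lag)) max_lag <- max(1L, floor(min(lens) / 2))
  if (max_lag >= min(lens))
    stopf("max_lag (%d) must be smaller than the shortest band (%d columns)",
          max_lag, min(lens))
  for (b in ids) {
    if (stats::sd(chanA[, band_id == b]) == 0 || stats::sd(chanB[, band_id == b]) == 0)
      stopf("zero variance: a channel is constant over band %s", b)
  }
  lags <- -max_lag:max_lag
  values <- numeric(length(lags))
  for (li in seq_along(lags)) {
    d <- lags[li]
    num <- 0; den <- 0
    for (b in ids) {
      cols <- which(band_id == b)
      n <- length(cols)
      if (abs(d) >= n) next
      ia <- if (d >= 0) cols[1:(n - d)] else cols[(1 - d):n]
      ib <- if (d >= 0) cols[(1 + d):n] else cols[1:(n + d)]
      va <- as.vector(chanA[, ia]); vb <- as.vector(chanB[, ib])
      sa <- stats::sd(va); sb <- stats::sd(vb)
      if (sa == 0 || sb == 0) next
      r <- stats::cor(va, vb)
      npairs <- length(va)
      num <- num + npairs * r; den <- den + npairs
    }
    values[li] <- if (den > 0) num / den else NA_real_
  }
  structure(list(lags = lags, values = values), class = "correlation_curve")
}

#' Central peak amplitude of a correlation curve
#'
#' Least-squares fit of `baseline + h * exp(-lag^2 / (2 sigma^2))` over
#' `|lag| <= fit_window`, scanning sigma (golden-section refined) with the
#' linear parameters solved exactly at each sigma. Returns the fitted peak
#' height `h` above baseline. Falls back to `value(0) - median(values
#' beyond the decorrelation window)` if the fit degenerates. Negative
#' amplitudes are floored at 0 with a warning.
#'
#' @param curve a `correlation_curve`.
#' @param psf_fwhm_px PSF FWHM in pixels (sets the default windows).
#' @param fit_window half-width of the fit support in lags (default 5 x
#'   PSF FWHM).
#' @param decor_window fallback baseline excludes `|lag| <=` this (default
#'   3 x PSF FWHM).
#' @param exclude_zero_lag drop lag 0 from the fit support; used uniformly
#'   on auto- and cross-correlations to reject the shot-noise self-
#'   correlation spike that Poisson noise adds at zero lag.
#' @return non-negative amplitude (dimensionless).
#' @export
peak_amplitude <- function(curve, psf_fwhm_px = 4,
                           fit_window = 5 * psf_fwhm_px,
                           decor_window = 3 * psf_fwhm_px,
                           exclude_zero_lag = FALSE) {
  if (any(!is.finite(curve$values)))
    stopf("correlation curve contains non-finite values")
  sel <- abs(curve$lags) <= fit_window
  if (exclude_zero_lag) sel <- sel & curve$lags != 0
  x <- curve$lags[sel]; y <- curve$values[sel]
  if (length(x) < 4) stopf("curve must span lags beyond the fit window")
  sse_at <- function(sigma) {
    g <- exp(-x^2 / (2 * sigma^2))
    X <- cbind(1, g)
    fit <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(fit)) return(list(sse = Inf, h = 0))
    list(sse = sum(fit$residuals^2), h = unname(fit$coefficients[2]))
  }
  sigmas <- exp(seq(log(0.2), log(max(fit_window, 2)), length.out = 40))
  sses <- vapply(sigmas, function(s) sse_at(s)$sse, 0)
  if (all(!is.finite(sses))) {
    h <- curve$values[curve$lags == 0] -
      stats::median(curve$values[abs(curve$lags) > decor_window])
  } else {
    i <- which.min(sses)
    lo <- sigmas[max(1, i - 1)]; hi <- sigmas[min(length(sigmas), i + 1)]
    opt <- stats::optimize(function(s) sse_at(s)$sse, c(lo, hi))
    h <- sse_at(opt$minimum)$h
    if (!is.finite(h)) {
      h <- curve$values[curve$lags == 0] -
        stats::median(curve$values[abs(curve$lags) > decor_window])
    }
  }
  if (!is.finite(h)) stopf("peak amplitude is non-finite")
  if (h < 0) {
    warning("negative correlation peak amplitude floored at 0", call. = FALSE)
    h <- 0
  }
  h
}

#' Proximity indices from correlation amplitudes
#'
#' `P1 = C12/A2` (fraction of protein 1 in proximity to protein 2) and
#' `P2 = C12/A1`. Raw ratios are reported; no clamping to [0, 1].
#'
#' @param A1,A2 autocorrelation peak amplitudes of channels 1 and 2 (> 0).
#' @param C12 cross-correlation peak amplitude (>= 0).
#' @param n_junctions,total_band_length_nm optional provenance.
#' @return a `proximity_result`: list with `A1`, `A2`, `C12`, `P1`, `P2`,
#'   `n_junctions`, `total_band_length_nm`.
#' @export
proximity_indices <- function(A1, A2, C12, n_junctions = NA_integer_,
                              total_band_length_nm = NA_real_) {
  if (!is_scalar_num(A1) || A1 <= 0 || !is_scalar_num(A2) || A2 <= 0)
    stopf("autocorrelation amplitudes must be > 0")
  if (!is_scalar_num(C12) || C12 < 0) stopf("C12 must be >= 0")
  structure(list(A1 = A1, A2 = A2, C12 = C12,
                 P1 = C12 / A2, P2 = C12 / A1,
                 n_junctions = n_junctions,
                 total_band_length_nm = total_band_length_nm),
            class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> P1 = %.3f, P2 = %.3f (A1 = %.3g, A2 = %.3g, C12 = %.3g; %s junctions)\n",
              x$P1, x$P2, x$A1, x$A2, x$C12,
              ifelse(is.na(x$n_junctions), "?", x$n_junctions)))
  invisible(x)
}

#' Venn fractions of colocalizing / non-colocalizing protein
#'
#' For each protein, the colocalizing fraction is `min(P, 1)` and the
#' non-colocalizing fraction its complement — the absolute representation
#' used alongside the color-coded index.
#'
#' @param result a `proximity_result`.
#' @return list of two length-2 vectors `(colocalizing, non_colocalizing)`.
#' @export
venn_fractions <- function(result) {
  f <- function(p) c(colocalizing = min(p, 1), non_colocalizing = 1 - min(p, 1))
  list(protein1 = f(result$P1), protein2 = f(result$P2))
}

#' Full proximity analysis over a set of junctions
#'
#' Filters planar junctions by straightness, extracts 400-nm bands,
#' concatenates them, computes the two autocorrelations and the
#' cross-correlation along the junction axis, fits peak amplitudes, and
#' forms the indices. `exclude_zero_lag` is applied uniformly to all three
#' curves.
#'
#' @param pairs list of [image_pair()] objects (channel_ref = protein 1,
#'   channel_target = protein 2).
#' @param traces list of [junction_trace()] objects, parallel to `pairs`.
#' @param band_width band width in nm.
#' @param center_on see [extract_band()].
#' @param straightness_threshold planar straightness cut; junctions failing
#'   it are skipped and counted.
#' @param max_lag_nm maximum correlation lag in nm.
#' @param psf_fwhm_nm PSF FWHM in nm (sets peak-fit windows; default 80).
#' @param exclude_zero_lag see [peak_amplitude()]; default TRUE (shot-noise
#'   rejection).
#' @param clamp clamp P1, P2 into [0, 1] for reporting.
#' @return a `proximity_result` with added `curves` (list of the three
#'   `correlation_curve`s), `n_excluded`, and `venn`.
#' @export
ppi_analysis <- function(pairs, traces, band_width = 400,
                         center_on = "reference",
                         straightness_threshold = 0.05,
                         max_lag_nm = 1000,
                         psf_fwhm_nm = 80,
                         exclude_zero_lag = TRUE,
                         clamp = FALSE) {
  if (length(pairs) != length(traces)) stopf("pairs and traces differ in length")
  bands <- list(); n_excluded <- 0L
  for (i in seq_along(pairs)) {
    if (pairs[[i]]$orientation == "planar" &&
        junction_straightness(traces[[i]]) > straightness_threshold) {
      n_excluded <- n_excluded + 1L
      next
    }
    bands[[length(bands) + 1]] <- extract_band(
      pairs[[i]], traces[[i]], width = band_width, center_on = center_on,
      straightness_threshold = NULL)
  }
  if (!length(bands)) stopf("no junction passed the straightness filter")
  comp <- concatenate_bands(bands)
  px <- comp$pixel_size
  max_lag <- min(floor(max_lag_nm / px),
                 min(table(comp$band_id)) - 1L)
  a1c <- correlation_function(comp$chan1, comp$chan1, comp$band_id, max_lag)
  a2c <- correlation_function(comp$chan2, comp$chan2, comp$band_id, max_lag)
  c12c <- correlation_function(comp$chan1, comp$chan2, comp$band_id, max_lag)
  psf_px <- psf_fwhm_nm / px
  amp <- function(cv) peak_amplitude(cv, psf_fwhm_px = psf_px,
                                     exclude_zero_lag = exclude_zero_lag)
  res <- proximity_indices(amp(a1c), amp(a2c), amp(c12c),
                           n_junctions = length(bands),
                           total_band_length_nm = comp$total_length_nm)
  if (clamp) {
    res$P1 <- min(max(res$P1, 0), 1)
    res$P2 <- min(max(res$P2, 0), 1)
  }
  res$curves <- list(A1 = a1c, A2 = a2c, C12 = c12c)
  res$n_excluded <- n_excluded
  res$venn <- venn_fractions(res)
  res
}
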