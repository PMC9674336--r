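# Internal helpers shared across modules.

# FWHM -> Gaussian sigma. 2*sqrt(2*log(2)) = 2.3548...
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, runs `code`, and restores the state,
#' so generators are deterministic without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# unit perpendicular of a 2D vector: rotate +90 degrees (CCW in x-right,
# y-down image coordinates this points to the left of the direction of travel)
perp2 <- function(v) c(-v[2], v[1])

vnorm <- function(v) sqrt(sum(v^2))

# Resample an open polyline (n x 2) at uniform arc-length spacing `step`,
# returning positions, unit tangents (central differences of the polyline)
# and the arc length. Units follow the input units.
polyline_resample <- function(points, step) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("polyline needs >= 2 points")
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) {
    keep <- c(TRUE, seg_len > 0)
    points <- points[keep, , drop = FALSE]
    if (nrow(points) < 2) stopf("polyline degenerate: all points coincide")
    seg <- diff(points)
    seg_len <- sqrt(rowSums(seg^2))
  }
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx[idx >= nrow(points)] <- nrow(points) - 1L
  frac <- (s - cum[idx]) / seg_len[idx]
  pos <- points[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  # tangent: direction of the segment each sample falls on, smoothed by
  # central differences of the resampled path (stable on polyline corners)
  tan_raw <- seg[idx, , drop = FALSE] / seg_len[idx]
  if (length(s) >= 3) {
    d <- rbind(pos[2, ] - pos[1, ],
               pos[3:length(s), , drop = FALSE] - pos[1:(length(s) - 2), , drop = FALSE],
               pos[length(s), ] - pos[length(s) - 1, ])
    nz <- sqrt(rowSums(d^2))
    ok <- nz > 0
    tan_raw[ok, ] <- d[ok, , drop = FALSE] / nz[ok]
  }
  list(positions = pos, tangents = tan_raw, arc = s, length = total)
}

# point on an open polyline at arc-length t, plus unit tangent there
polyline_point_at <- function(points, t) {
  points <- as.matrix(points)
  seg <- diff(points)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  t <- min(max(t, 0), cum[length(cum)])
  i <- findInterval(t, cum, rightmost.closed = TRUE)
  i <- min(i, nrow(points) - 1L)
  u <- seg[i, ] / seg_len[i]
  list(point = points[i, ] + u * (t - cum[i]), tangent = u)
}
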