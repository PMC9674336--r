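# Immunogold particle statistics on electron-tomography projections.
#
# All geometry is 2D (coordinates come from thin tomogram projections).
# Particle positions are referenced to the tight junction (the most apical
# membrane contact point between neighboring cells) and to the apical
# membrane polyline. The antibody-linkage window — gold radius 3 nm to
# ~37 nm of primary + gold-conjugated secondary antibody (plus the size of
# the presumed binding partner) — bounds how far a membrane-anchored
# epitope can displace its gold label.

#' Particle offsets relative to the tight junction
#'
#' Decomposes particle - TJ displacement into a signed apico-basal
#' component (positive apical) and a signed lateral component (positive to
#' the right of the apical axis), plus the Euclidean TJ distance.
#'
#' @param particles n x 2 matrix (x, y) nm (a single point is accepted).
#' @param tj_reference length-2 point, nm.
#' @param apical_axis unit 2-vector.
#' @return data.frame with `ab_offset_nm`, `lateral_offset_nm`,
#'   `tj_distance_nm`.
#' @export
tj_offsets <- function(particles, tj_reference, apical_axis) {
  p <- matrix(as.numeric(particles), ncol = 2)
  if (abs(vnorm(apical_axis) - 1) > 1e-9) stopf("apical_axis must be unit norm")
  d <- sweep(p, 2, as.numeric(tj_reference))
  lat_axis <- c(apical_axis[2], -apical_axis[1])   # right of apical = positive
  ab <- d %*% apical_axis
  lat <- d %*% lat_axis
  data.frame(ab_offset_nm = as.numeric(ab),
             lateral_offset_nm = as.numeric(lat),
             tj_distance_nm = sqrt(rowSums(d^2)))
}

#' Minimum distance from points to a polyline
#'
#' Exact point-to-segment distances (projection clamped to the segment),
#' minimized over segments. Zero-length segments are skipped.
#'
#' @param points n x 2 matrix (or a single length-2 point), nm.
#' @param polyline m x 2 matrix, m >= 2.
#' @return numeric vector of distances, nm.
#' @export
min_distance_to_polyline <- function(points, polyline) {
  p <- matrix(as.numeric(points), ncol = 2)
  poly <- as.matrix(polyline)
  if (nrow(poly) < 2) stopf("polyline needs >= 2 points")
  seg <- diff(poly)
  len2 <- rowSums(seg^2)
  ok <- which(len2 > 0)
  if (!length(ok)) stopf("degenerate polyline: all segments have zero length")
  d2 <- rep(Inf, nrow(p))
  for (i in ok) {
    ax <- poly[i, 1]; ay <- poly[i, 2]
    t <- ((p[, 1] - ax) * seg[i, 1] + (p[, 2] - ay) * seg[i, 2]) / len2[i]
    t <- pmin(pmax(t, 0), 1)
    dx <- p[, 1] - (ax + t * seg[i, 1])
    dy <- p[, 2] - (ay + t * seg[i, 2])
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Even-odd point-in-polygon, boundary-inclusive. Vectorized over points.
point_in_polygon <- function(points, polygon, eps = 1e-9) {
  p <- matrix(as.numeric(points), ncol = 2)
  poly <- as.matrix(polygon)
  n <- nrow(poly)
  inside <- logical(nrow(p))
  on_edge <- logical(nrow(p))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # boundary test: point within eps of segment (i, j)
    sx <- xj - xi; sy <- yj - yi
    l2 <- sx * sx + sy * sy
    if (l2 > 0) {
      t <- pmin(pmax(((p[, 1] - xi) * sx + (p[, 2] - yi) * sy) / l2, 0), 1)
      dx <- p[, 1] - (xi + t * sx); dy <- p[, 2] - (yi + t * sy)
      on_edge <- on_edge | (dx * dx + dy * dy <= eps * eps)
    } else {
      on_edge <- on_edge | ((p[, 1] - xi)^2 + (p[, 2] - yi)^2 <= eps * eps)
    }
    crosses <- ((yi > p[, 2]) != (yj > p[, 2])) &
      (p[, 1] < (xj - xi) * (p[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

# TRUE if any two non-adjacent edges of the polygon properly intersect
polygon_self_intersects <- function(polygon) {
  poly <- as.matrix(polygon)
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  segs <- cbind(poly, poly[c(2:n, 1), ])
  cross_ok <- function(a1, a2, b1, b2) {
    d1 <- (b2[1] - b1[1]) * (a1[2] - b1[2]) - (b2[2] - b1[2]) * (a1[1] - b1[1])
    d2 <- (b2[1] - b1[1]) * (a2[2] - b1[2]) - (b2[2] - b1[2]) * (a2[1] - b1[1])
    d3 <- (a2[1] - a1[1]) * (b1[2] - a1[2]) - (a2[2] - a1[2]) * (b1[1] - a1[1])
    d4 <- (a2[1] - a1[1]) * (b2[2] - a1[2]) - (a2[2] - a1[2]) * (b2[1] - a1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (k in (i + 2):n) {
      if (i == 1 && k == n) next                 # adjacent via wrap-around
      if (cross_ok(segs[i, 1:2], segs[i, 3:4], segs[k, 1:2], segs[k, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Classify particles into apical compartments
#'
#' A particle is labeled `microvilli` when inside any microvillus polygon
#' (even-odd rule, boundary counts as inside), else `membrane_vicinity`
#' when its membrane distance is at most `vicinity_threshold`, else
#' `cytoplasm`.
#'
#' @param particles n x 2 matrix, nm.
#' @param microvilli list of polygon matrices (possibly empty/NULL).
#' @param membrane polyline matrix.
#' @param vicinity_threshold nm (default 38, the antibody-linkage bound).
#' @return factor of labels, levels
#'   `c("microvilli", "membrane_vicinity", "cytoplasm")`.
#' @export
classify_compartment <- function(particles, microvilli, membrane,
                                 vicinity_threshold = 38) {
  p <- matrix(as.numeric(particles), ncol = 2)
  lab <- rep("cytoplasm", nrow(p))
  if (!is.null(microvilli) && length(microvilli)) {
    for (k in seq_along(microvilli)) {
      if (polygon_self_intersects(microvilli[[k]]))
        stopf("microvillus polygon %d is self-intersecting", k)
    }
    in_mv <- Reduce(`|`, lapply(microvilli, function(pg) point_in_polygon(p, pg)))
    lab[in_mv] <- "microvilli"
  } else in_mv <- rep(FALSE, nrow(p))
  md <- min_distance_to_polyline(p, membrane)
  lab[!in_mv & md <= vicinity_threshold] <- "membrane_vicinity"
  factor(lab, levels = c("microvilli", "membrane_vicinity", "cytoplasm"))
}

#' Antibody-linkage compatibility of membrane distances
#'
#' Counts how many particles lie closer to the membrane than the linkage
#' upper bound, and how many fall in the full linkage window
#' `[lower, upper - 1]` (3-37 nm by default: gold radius to primary +
#' gold-conjugated secondary antibody reach).
#'
#' @param membrane_distances numeric vector, nm; non-empty.
#' @param lower window lower bound, nm (default 3).
#' @param upper strict upper bound for the headline fraction, nm (default
#'   38); the window's inclusive upper edge is `upper - 1`.
#' @return list with `n_below_upper` (# distances < upper), `n_total`,
#'   `fraction` (= n_below_upper / n_total), `n_in_window`
#'   (# in [lower, upper - 1]).
#' @export
linkage_fraction <- function(membrane_distances, lower = 3, upper = 38) {
  d <- membrane_distances
  if (!length(d)) stopf("empty distance vector")
  if (lower < 0 || lower >= upper) stopf("need 0 <= lower < upper")
  list(n_below_upper = sum(d < upper),
       n_total = length(d),
       fraction = sum(d < upper) / length(d),
       n_in_window = sum(d >= lower & d <= upper - 1))
}

#' Full immunogold distance report
#'
#' Per-particle TJ offsets, membrane distance, and compartment label, plus
#' summary counts/fractions and the linkage statistic.
#'
#' @param gps a [gold_particle_set()].
#' @param vicinity_threshold nm, compartment rule (default 38).
#' @param lower,upper linkage window, nm (defaults 3 and 38).
#' @return a `distance_report`: list with `per_particle` (data.frame) and
#'   `summary` (compartment counts and fractions, linkage statistic).
#' @export
em_distance_report <- function(gps, vicinity_threshold = 38,
                               lower = 3, upper = 38) {
  p <- as.matrix(gps$particles[, c("x_nm", "y_nm")])
  off <- tj_offsets(p, gps$tj_reference, gps$apical_axis)
  md <- min_distance_to_polyline(p, gps$membrane)
  comp <- classify_compartment(p, gps$microvilli, gps$membrane,
                               vicinity_threshold)
  per <- cbind(data.frame(id = gps$particles$id), off,
               data.frame(membrane_distance_nm = md, compartment = comp))
  counts <- table(comp)
  structure(list(
    per_particle = per,
    summary = list(compartment_counts = as.list(counts),
                   compartment_fractions = as.list(counts / sum(counts)),
                   linkage = linkage_fraction(md, lower, upper))),
    class = "distance_report")
}
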