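# Cluster detection and microvilli-region contingency.
#
# Detects protein clusters as prominent local maxima of the Gaussian-
# smoothed channel and tabulates their centroids against annotated
# microvilli-derived regions (within microvillus / base / between). Region
# polygons are an input annotation; no actin segmentation is attempted.

# separable Gaussian smoothing with reflective padding, sigma in px
gaussian_smooth <- function(image, sigma_px) {
  if (sigma_px <= 0) return(image)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2)); k <- k / sum(k)
  pad_reflect <- function(v, r) c(rev(v[2:(r + 1)]), v, rev(v[(length(v) - r):(length(v) - 1)]))
  conv1 <- function(v) {
    vp <- pad_reflect(v, r)
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  sm <- apply(image, 2, conv1)        # down columns
  t(apply(sm, 1, conv1))              # across rows
}

#' Detect protein clusters in one channel
#'
#' Local maxima of the Gaussian-smoothed image with prominence at least
#' `min_prominence * (max - background)` above background (background =
#' image median). Each above-threshold pixel is assigned to its nearest
#' maximum; the cluster centroid is the intensity-weighted centroid of that
#' support and the equivalent diameter is that of a disk with the support's
#' area. Prominence is relative, so detection is intensity-scale invariant.
#'
#' @param image numeric matrix.
#' @param pixel_size nm per pixel.
#' @param smoothing_sigma smoothing sigma in nm (default: PSF sigma for an
#'   80-nm FWHM).
#' @param min_prominence fraction of (max - background) a maximum must rise
#'   above background (default 0.2).
#' @return a `cluster_set` data.frame: `x_nm`, `y_nm`, `peak_intensity`,
#'   `equiv_diameter_nm`. Constant images give an empty set with a warning.
#' @export
detect_clusters <- function(image, pixel_size,
                            smoothing_sigma = 80 / (2 * sqrt(2 * log(2))),
                            min_prominence = 0.2) {
  if (diff(range(image)) == 0) {
    warning("constant image: no clusters detected", call. = FALSE)
    return(structure(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                peak_intensity = numeric(0),
                                equiv_diameter_nm = numeric(0)),
                     class = c("cluster_set", "data.frame")))
  }
  sm <- gaussian_smooth(image, smoothing_sigma / pixel_size)
  bg <- stats::median(sm)
  thr <- bg + min_prominence * (max(sm) - bg)
  nr <- nrow(sm); nc <- ncol(sm)
  # strict interior 8-neighbor maxima above threshold
  ctr <- sm[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr > thr
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr >= sm[2:(nr - 1) + dr, 2:(nc - 1) + dc])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) {
    warning("no maxima above prominence threshold", call. = FALSE)
    return(structure(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                peak_intensity = numeric(0),
                                equiv_diameter_nm = numeric(0)),
                     class = c("cluster_set", "data.frame")))
  }
  peaks <- data.frame(r = idx[, 1] + 1L, c = idx[, 2] + 1L)
  peaks$val <- sm[cbind(peaks$r, peaks$c)]
  # collapse plateau/adjacent maxima: keep the brightest within 2 smoothing
  # sigmas of an already-kept peak
  peaks <- peaks[order(-peaks$val), ]
  min_d2 <- (2 * smoothing_sigma / pixel_size)^2
  keep <- rep(TRUE, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    if (!keep[i]) next
    if (i < nrow(peaks)) {
      later <- (i + 1):nrow(peaks)
      d2 <- (peaks$r[later] - peaks$r[i])^2 + (peaks$c[later] - peaks$c[i])^2
      keep[later][d2 < min_d2] <- FALSE
    }
  }
  peaks <- peaks[keep, ]
  # support: above-threshold pixels assigned to the nearest kept peak
  sup <- which(sm > thr, arr.ind = TRUE)
  w <- pmax(image[sup] - bg, 0)
  nearest <- max.col(-outer(sup[, 1], peaks$r, `-`)^2 -
                       outer(sup[, 2], peaks$c, `-`)^2, ties.method = "first")
  out <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(k) {
    s <- nearest == k
    ws <- w[s]
    if (sum(ws) == 0) ws <- rep(1, sum(s))
    cx <- sum((sup[s, 2] - 1) * ws) / sum(ws)    # 0-based px -> nm
    cy <- sum((sup[s, 1] - 1) * ws) / sum(ws)
    data.frame(x_nm = cx * pixel_size, y_nm = cy * pixel_size,
               peak_intensity = peaks$val[k],
               equiv_diameter_nm = 2 * sqrt(sum(s) * pixel_size^2 / pi))
  }))
  structure(out, class = c("cluster_set", "data.frame"))
}

#' Region map of microvilli-derived polygons
#'
#' Validates that polygons are simple and mutually non-overlapping and tags
#' each with a region label (conventionally `within_microvillus`, `base`,
#' `between`; labels are free text).
#'
#' @param polygons list of k x 2 matrices, nm.
#' @param labels character vector of tags, one per polygon.
#' @param source description of how the regions were drawn.
#' @return a `region_map`.
#' @export
region_map <- function(polygons, labels, source = "manual annotation") {
  polygons <- lapply(polygons, as.matrix)
  if (length(polygons) != length(labels)) stopf("one label per polygon required")
  if (any(!nzchar(labels))) stopf("every region must be tagged")
  for (k in seq_along(polygons)) {
    if (polygon_self_intersects(polygons[[k]]))
      stopf("region polygon %d is self-intersecting", k)
  }
  # overlap check: any vertex of one polygon strictly inside another
  if (length(polygons) > 1) {
    for (a in seq_along(polygons)) for (b in seq_along(polygons)) {
      if (a == b) next
      inb <- point_in_polygon(polygons[[a]], polygons[[b]], eps = 0)
      # vertices exactly on the shared boundary are tolerated
      strict <- inb & !point_on_boundary(polygons[[a]], polygons[[b]])
      if (any(strict))
        stopf("regions %d and %d overlap", a, b)
    }
  }
  structure(list(polygons = polygons, labels = as.character(labels),
                 source = source),
            class = "region_map")
}

point_on_boundary <- function(points, polygon, eps = 1e-9) {
  p <- matrix(as.numeric(points), ncol = 2)
  poly <- as.matrix(polygon)
  n <- nrow(poly)
  on <- logical(nrow(p))
  j <- n
  for (i in seq_len(n)) {
    sx <- poly[i, 1] - poly[j, 1]; sy <- poly[i, 2] - poly[j, 2]
    l2 <- sx * sx + sy * sy
    if (l2 > 0) {
      t <- pmin(pmax(((p[, 1] - poly[j, 1]) * sx + (p[, 2] - poly[j, 2]) * sy) / l2, 0), 1)
      dx <- p[, 1] - (poly[j, 1] + t * sx); dy <- p[, 2] - (poly[j, 2] + t * sy)
      on <- on | (dx * dx + dy * dy <= eps * eps)
    }
    j <- i
  }
  on
}

#' Protein-by-region contingency table
#'
#' Assigns each cluster centroid to the containing region
#' (boundary-inclusive, even-odd rule) or to `unassigned`, and tabulates
#' counts per protein. Row sums equal the number of clusters per protein.
#'
#' @param clusters_per_protein named list of `cluster_set`s (or data.frames
#'   with `x_nm`, `y_nm`), one per protein.
#' @param regions a [region_map()].
#' @return matrix of counts, rows = proteins, columns = unique region
#'   labels plus `unassigned`.
#' @export
region_contingency <- function(clusters_per_protein, regions) {
  if (!inherits(regions, "region_map")) stopf("regions must be a region_map")
  if (!length(clusters_per_protein) || is.null(names(clusters_per_protein)))
    stopf("clusters_per_protein must be a named list")
  region_labels <- unique(regions$labels)
  cols <- c(region_labels, "unassigned")
  tab <- matrix(0L, length(clusters_per_protein), length(cols),
                dimnames = list(names(clusters_per_protein), cols))
  for (pn in names(clusters_per_protein)) {
    cs <- clusters_per_protein[[pn]]
    if (!nrow(cs)) next
    pts <- as.matrix(cs[, c("x_nm", "y_nm")])
    assigned <- rep("unassigned", nrow(pts))
    for (k in seq_along(regions$polygons)) {
      hit <- point_in_polygon(pts, regions$polygons[[k]])
      assigned[hit & assigned == "unassigned"] <- regions$labels[k]
    }
    t0 <- table(factor(assigned, levels = cols))
    tab[pn, ] <- as.integer(t0)
  }
  tab
}
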