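# Lightweight S3 containers for the pipeline.
#
# Image coordinate convention used throughout: 0-based pixel centers,
# x = column index, y = row index, so the pixel at matrix position
# image[r, c] has center (x, y) = (c - 1, r - 1) in pixel units and
# (c - 1, r - 1) * pixel_size in nm.

#' Two-channel image pair
#'
#' Container for a two-channel 2D grayscale acquisition: a reference channel
#' (tight-junction marker, e.g. ZO-1 or Occludin) and a target channel
#' (polarity protein). For proximity analysis of two polarity proteins the
#' two slots simply hold protein 1 and protein 2.
#'
#' @param channel_ref numeric matrix, reference (TJ marker) channel.
#' @param channel_target numeric matrix, target channel; same dimensions.
#' @param pixel_size pixel size in nm/px, > 0.
#' @param orientation `"planar"` (imaging in the epithelial plane) or
#'   `"apico_basal"` (cryosection along the apico-basal axis).
#' @param id optional identifier.
#' @return an object of class `image_pair`.
#' @export
image_pair <- function(channel_ref, channel_target, pixel_size,
                       orientation = c("planar", "apico_basal"), id = NULL) {
  orientation <- match.arg(orientation)
  if (!is.matrix(channel_ref) || !is.matrix(channel_target))
    stopf("channels must be numeric matrices")
  if (!all(dim(channel_ref) == dim(channel_target)))
    stopf("channel dimensions differ: %dx%d vs %dx%d",
          nrow(channel_ref), ncol(channel_ref),
          nrow(channel_target), ncol(channel_target))
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be a positive scalar (nm/px)")
  structure(list(channel_ref = channel_ref, channel_target = channel_target,
                 pixel_size = pixel_size, orientation = orientation, id = id),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %dx%d px, %.3g nm/px, %s%s\n",
              nrow(x$channel_ref), ncol(x$channel_ref), x$pixel_size,
              x$orientation,
              if (is.null(x$id)) "" else paste0(", id=", x$id)))
  invisible(x)
}

#' Junction trace
#'
#' Ordered sub-pixel polyline marking one junction on an image, in 0-based
#' pixel coordinates (x = column, y = row). Apico-basal images additionally
#' carry the in-plane unit vector pointing apically.
#'
#' @param points n x 2 numeric matrix of (x, y) pixel coordinates, n >= 2,
#'   consecutive points distinct.
#' @param image_id optional id of the image the trace belongs to.
#' @param apical_direction unit 2-vector (required for apico-basal use).
#' @return an object of class `junction_trace`.
#' @export
junction_trace <- function(points, image_id = NULL, apical_direction = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stopf("junction trace needs >= 2 points")
  if (ncol(points) != 2) stopf("trace points must be n x 2 (x, y)")
  if (any(rowSums(diff(points)^2) == 0))
    stopf("consecutive trace points must be distinct")
  if (!is.null(apical_direction)) {
    if (abs(vnorm(apical_direction) - 1) > 1e-6)
      stopf("apical_direction must be a unit vector")
  }
  structure(list(points = points, image_id = image_id,
                 apical_direction = apical_direction),
            class = "junction_trace")
}

#' @export
print.junction_trace <- function(x, ...) {
  cat(sprintf("<junction_trace> %d vertices%s\n", nrow(x$points),
              if (is.null(x$image_id)) "" else paste0(", image ", x$image_id)))
  invisible(x)
}

#' Immunogold particle set
#'
#' Particle coordinates from an electron-tomography projection, with the
#' tight-junction reference point (most apical membrane contact between
#' neighboring cells), the in-plane apical unit vector, the apical membrane
#' polyline, and optional microvilli outline polygons. All coordinates in nm.
#'
#' @param particles data.frame with columns `id`, `x_nm`, `y_nm`.
#' @param tj_reference numeric length-2 (x, y) nm.
#' @param apical_axis unit 2-vector pointing apically.
#' @param membrane m x 2 matrix (nm), apical membrane polyline, m >= 2.
#' @param microvilli optional list of polygon matrices (nm), each k x 2.
#' @return an object of class `gold_particle_set`.
#' @export
gold_particle_set <- function(particles, tj_reference, apical_axis,
                              membrane, microvilli = NULL) {
  need <- c("id", "x_nm", "y_nm")
  if (!all(need %in% names(particles)))
    stopf("particles must have columns: %s", paste(need, collapse = ", "))
  if (abs(vnorm(apical_axis) - 1) > 1e-9)
    stopf("apical_axis must have unit norm (within 1e-9)")
  membrane <- as.matrix(membrane)
  if (nrow(membrane) < 2) stopf("membrane polyline needs >= 2 points")
  if (!is.null(microvilli)) microvilli <- lapply(microvilli, as.matrix)
  structure(list(particles = particles, tj_reference = as.numeric(tj_reference),
                 apical_axis = as.numeric(apical_axis), membrane = membrane,
                 microvilli = microvilli),
            class = "gold_particle_set")
}

#' @export
print.gold_particle_set <- function(x, ...) {
  cat(sprintf("<gold_particle_set> %d particles, membrane %d vertices, %d microvilli polygons\n",
              nrow(x$particles), nrow(x$membrane),
              if (is.null(x$microvilli)) 0L else length(x$microvilli)))
  invisible(x)
}
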