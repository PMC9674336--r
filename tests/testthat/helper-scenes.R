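# Shared fixtures, built in code.

# small fast scene for unit tests
small_params <- function(...) {
  args <- utils::modifyList(list(image_shape = c(128L, 128L), n_clusters = 8L,
                                 offset_perp_sd = 40, seed = 11L), list(...))
  do.call(scene_params, args)
}

# sparse long-junction world used for overlap-fraction recovery: the index
# reads the shared fraction only when non-shared clusters are placed
# independently enough that the generator's exclusion zone does not imprint
# measurable anticorrelation, and the cluster count must be divisible by 4
# so that round(f * n)/n equals f for f in {0.25, 0.5, 0.75} (see the
# methods vignette)
recovery_params <- function(seed, ...) {
  scene_params(image_shape = c(192L, 640L), n_clusters = 8L,
               offset_perp_sd = 80, poisson_noise = TRUE, seed = seed, ...)
}

ppi_on_sims <- function(sims, ...) {
  suppressWarnings(ppi_analysis(lapply(sims, `[[`, "pair"),
                                lapply(sims, `[[`, "trace"),
                                center_on = "trace", ...))
}

# independent point-in-polygon oracle: winding/angle-sum method
pip_angle_sum <- function(pt, poly) {
  v <- sweep(poly, 2, pt)
  r <- sqrt(rowSums(v^2))
  if (any(r < 1e-12)) return(TRUE)            # on a vertex
  n <- nrow(poly)
  a <- atan2(v[, 2], v[, 1])
  da <- diff(c(a, a[1]))
  da <- ifelse(da > pi, da - 2 * pi, ifelse(da < -pi, da + 2 * pi, da))
  # points exactly on an edge give an angle jump of +-pi; treat as inside
  if (any(abs(abs(da) - pi) < 1e-9)) return(TRUE)
  abs(sum(da)) > pi
}

# greedy nearest matching of detections to ground truth (px units)
match_points <- function(truth, detected, max_dist) {
  used <- rep(FALSE, nrow(detected))
  hits <- 0L
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((detected[, 1] - truth[i, 1])^2 + (detected[, 2] - truth[i, 2])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && is.finite(d[j]) && d[j] <= max_dist) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}
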