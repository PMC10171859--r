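# Shared fixtures: tiny volumes and hand-built lesion tracks.

toy_volume <- function(d = c(6, 6, 3), value = 0) array(value, d)

# A lesion track with a prescribed intensity trajectory. Baseline weeks are
# ROI-propagated; detection runs from `onset_idx` while intensity is above
# `present_above`.
make_track <- function(intensity, weeks = seq_along(intensity) - 1,
                       onset_idx = 3, volume_ul = 0.3,
                       terminal_enhancing = FALSE, present_above = 0) {
  n <- length(intensity)
  present <- rep(FALSE, n)
  present[onset_idx:n] <- intensity[onset_idx:n] > present_above
  pts <- data.frame(week = weeks,
                    volume_ul = ifelse(present, volume_ul, 0),
                    mean_norm_intensity = intensity,
                    sd_norm_intensity = 0.005,
                    roi_propagated = !present,
                    enhancing = FALSE)
  pts$enhancing[n] <- terminal_enhancing
  structure(list(track_id = 1L,
                 first_detection_week = weeks[which(present)[1]],
                 points = pts,
                 max_roi = 1:14,
                 terminal_enhancing = terminal_enhancing,
                 events = NULL),
            class = "lesion_track")
}

# Random small label map with a few blobs, for linking oracles.
random_label_map <- function(d = c(8, 8, 4), p = 0.25) {
  m <- array(stats::runif(prod(d)) < p, d)
  remyetrack::label_components_3d(m, connectivity = 26, min_voxels = 1)
}

# Brute-force 3D connected components by repeated flood fill (queue-based),
# independent of the igraph implementation.
flood_fill_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(-1:1, -1:1, -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, d)
  cur <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k] || lab[i, j, k] > 0) next
    cur <- cur + 1L
    queue <- matrix(c(i, j, k), 1)
    lab[i, j, k] <- cur
    while (nrow(queue) > 0) {
      v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- v + as.integer(offs[o, ])
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && lab[w[1], w[2], w[3]] == 0) {
          lab[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  lab
}
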