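#' Convert a voxel count to microliters
#'
#' One voxel at the default 0.15 x 0.15 x 1.0 mm spacing is 0.0225 uL
#' (1 mm^3 = 1 uL).
#'
#' @param count nonnegative voxel count.
#' @param voxel_size_mm voxel spacing in mm.
#' @return volume in uL.
#' @export
voxel_count_to_ul <- function(count, voxel_size_mm = c(0.15, 0.15, 1.0)) {
  if (any(count < 0)) stop("voxel count must be nonnegative")
  count * prod(voxel_size_mm)
}

#' Link lesion components between two consecutive timepoints
#'
#' Components at t+1 are identified with a component at t when they overlap by
#' at least \code{min_overlap_voxels} voxels in 3D. A t+1 component meeting
#' the criterion with several predecessors is linked to the one with maximal
#' overlap (ties broken by the smaller predecessor label); the extra
#' candidates are recorded as merge events. Unlinked t+1 components start new
#' tracks.
#'
#' @param labels_t,labels_t1 aligned integer label arrays from
#'   [segment_lesions()] at timepoints t and t+1.
#' @param min_overlap_voxels minimum 3D overlap (default 4).
#' @return list with \code{links} (data.frame: label_t1, label_t,
#'   overlap_voxels; label_t is NA for new tracks) and \code{merges}
#'   (data.frame of discarded candidate links).
#' @export
link_timepoints <- function(labels_t, labels_t1, min_overlap_voxels = 4) {
  if (!identical(dim(labels_t), dim(labels_t1)))
    stop("label map grids differ in shape")
  labs1 <- sort(unique(labels_t1[labels_t1 > 0]))
  links <- data.frame(label_t1 = integer(0), label_t = integer(0),
                      overlap_voxels = integer(0))
  merges <- links
  if (length(labs1) == 0) return(list(links = links, merges = merges))

  both <- labels_t > 0 & labels_t1 > 0
  ov <- if (any(both)) {
    tab <- table(t1 = labels_t1[both], t0 = labels_t[both])
    as.data.frame(tab, stringsAsFactors = FALSE)
  } else data.frame(t1 = character(0), t0 = character(0), Freq = integer(0))
  ov <- ov[ov$Freq >= min_overlap_voxels, , drop = FALSE]
  ov$t1 <- as.integer(ov$t1); ov$t0 <- as.integer(ov$t0)

  rows <- lapply(labs1, function(b) {
    cand <- ov[ov$t1 == b, , drop = FALSE]
    if (nrow(cand) == 0)
      return(list(link = data.frame(label_t1 = b, label_t = NA_integer_,
                                    overlap_voxels = 0L),
                  merge = NULL))
    cand <- cand[order(-cand$Freq, cand$t0), , drop = FALSE]
    list(link = data.frame(label_t1 = b, label_t = cand$t0[1],
                           overlap_voxels = cand$Freq[1]),
         merge = if (nrow(cand) > 1)
           data.frame(label_t1 = b, label_t = cand$t0[-1],
                      overlap_voxels = cand$Freq[-1]) else NULL)
  })
  links <- do.call(rbind, lapply(rows, `[[`, "link"))
  mg <- Filter(Negate(is.null), lapply(rows, `[[`, "merge"))
  if (length(mg)) merges <- do.call(rbind, mg)
  list(links = links, merges = merges)
}

#' Build per-lesion longitudinal tracks from a study timeline
#'
#' Normalizes every PDw scan to gray matter, segments lesions, chains
#' consecutive-timepoint links (>= \code{min_overlap_voxels} 3D overlap) into
#' tracks, and extracts per-timepoint volume and normalized-intensity
#' statistics. For weeks before first detection and after a lesion
#' disappears, statistics are computed in a fixed ROI equal to the track's
#' maximum lesion extent (the segmented voxel set at the week of maximal
#' volume), propagated unchanged — these points are flagged
#' \code{roi_propagated} and carry volume 0. A track that disappears and
#' later overlaps its own maximum-extent ROI by >= \code{min_overlap_voxels}
#' voxels is re-linked rather than started anew. Per-week enhancement is
#' measured on the T1 subtraction image against non-lesional white matter.
#'
#' @param timeline a \code{study_timeline} (see [simulate_study()]).
#' @param intensity_threshold,min_voxels,connectivity passed to
#'   [segment_lesions()].
#' @param min_overlap_voxels longitudinal linking threshold (default 4).
#' @param k_sigma enhancement threshold in background SD units.
#' @return list of \code{lesion_track} objects; each has \code{track_id},
#'   \code{first_detection_week}, \code{points} (data.frame with one row per
#'   study timepoint: week, volume_ul, mean_norm_intensity,
#'   sd_norm_intensity, roi_propagated, enhancing), \code{max_roi} (voxel
#'   indices), \code{terminal_enhancing}, and \code{events}.
#' @export
build_tracks <- function(timeline, intensity_threshold = 0.80, min_voxels = 4,
                         connectivity = 26, min_overlap_voxels = 4, k_sigma = 3) {
  weeks <- timeline$weeks
  nt <- length(weeks)
  vv <- prod(timeline$voxel_size_mm)
  need <- c("PDw", "T1w_pre", "T1w_post")
  for (ct in need) {
    have <- !vapply(timeline$volumes[[ct]], is.null, logical(1))
    if (is.null(timeline$volumes[[ct]]) || !all(have))
      stop("missing ", ct, " volume at week ",
           weeks[which(!have)[1]])
  }

  pdw_norm <- lapply(seq_len(nt), function(ti)
    normalize_to_gm(timeline$volumes$PDw[[ti]], timeline$gm_mask))
  label_maps <- lapply(pdw_norm, segment_lesions,
                       wm_mask = timeline$wm_mask,
                       intensity_threshold = intensity_threshold,
                       min_voxels = min_voxels, connectivity = connectivity)

  # chain links; track state: voxels at last seen week, per-week voxel sets
  tracks <- list()        # each: list(voxels_by_week = list, last_seen, events)
  active <- integer(0)    # track index by current label at previous timepoint
  events <- data.frame(week = numeric(0), type = character(0),
                       track_id = integer(0), detail = character(0))
  dormant <- integer(0)   # track indices with no current component

  for (ti in seq_len(nt)) {
    lm <- label_maps[[ti]]
    labs <- sort(unique(lm[lm > 0]))
    new_active <- integer(0)
    if (ti == 1) {
      linkinfo <- list(links = data.frame(label_t1 = labs,
                                          label_t = rep(NA_integer_, length(labs)),
                                          overlap_voxels = rep(0L, length(labs))),
                       merges = data.frame())
    } else {
      linkinfo <- link_timepoints(label_maps[[ti - 1]], lm, min_overlap_voxels)
    }
    claimed <- integer(0)  # track ids already extended this week (splits)
    if (length(labs)) for (r in seq_len(nrow(linkinfo$links))) {
      b <- linkinfo$links$label_t1[r]
      a <- linkinfo$links$label_t[r]
      vox <- which(lm == b)
      tid <- NA_integer_
      if (!is.na(a) && !is.na(active[as.character(a)])) {
        tid <- active[[as.character(a)]]
        if (tid %in% claimed) {        # split: larger overlap kept the track
          events <- rbind(events, data.frame(week = weeks[ti], type = "split",
                                             track_id = tid, detail = paste0("label ", b)))
          tid <- NA_integer_
        }
      }
      if (is.na(tid) && length(dormant)) {
        # reappearance: match against dormant tracks' max-extent ROI
        ovl <- vapply(dormant, function(k)
          length(intersect(vox, track_max_roi(tracks[[k]]))), integer(1))
        ok <- which(ovl >= min_overlap_voxels)
        if (length(ok)) {
          pick <- ok[order(-ovl[ok], dormant[ok])][1]
          tid <- dormant[pick]
          dormant <- setdiff(dormant, tid)
          events <- rbind(events, data.frame(week = weeks[ti], type = "relink",
                                             track_id = tid, detail = paste0("label ", b)))
        }
      }
      if (is.na(tid)) {
        tracks[[length(tracks) + 1]] <- list(voxels_by_week = vector("list", nt))
        tid <- length(tracks)
      }
      tracks[[tid]]$voxels_by_week[[ti]] <- vox
      claimed <- c(claimed, tid)
      new_active[as.character(b)] <- tid
    }
    if (nrow(linkinfo$merges) > 0) for (r in seq_len(nrow(linkinfo$merges))) {
      a <- linkinfo$merges$label_t[r]
      if (!is.na(active[as.character(a)]))
        events <- rbind(events, data.frame(week = weeks[ti], type = "merge",
                                           track_id = active[[as.character(a)]],
                                           detail = paste0("into label ",
                                                           linkinfo$merges$label_t1[r])))
    }
    lost <- setdiff(unname(active), claimed)
    dormant <- unique(c(dormant, lost))
    active <- new_active
  }

  # assemble tracks with ROI propagation and enhancement
  subs <- lapply(seq_len(nt), function(ti)
    t1_subtraction(timeline$volumes$T1w_pre[[ti]],
                   timeline$volumes$T1w_post[[ti]]))
  all_rois <- unique(unlist(lapply(tracks, track_max_roi)))
  bg_mask <- timeline$wm_mask
  bg_mask[all_rois] <- FALSE

  out <- vector("list", length(tracks))
  for (k in seq_along(tracks)) {
    tr <- tracks[[k]]
    present <- which(!vapply(tr$voxels_by_week, is.null, logical(1)))
    max_roi <- track_max_roi(tr)
    pts <- data.frame(week = weeks, volume_ul = 0,
                      mean_norm_intensity = NA_real_, sd_norm_intensity = NA_real_,
                      roi_propagated = TRUE, enhancing = NA)
    for (ti in seq_len(nt)) {
      vox <- tr$voxels_by_week[[ti]]
      prop <- is.null(vox)
      roi <- if (prop) max_roi else vox
      vals <- pdw_norm[[ti]][roi]
      pts$mean_norm_intensity[ti] <- mean(vals)
      pts$sd_norm_intensity[ti] <- stats::sd(vals)
      pts$roi_propagated[ti] <- prop
      pts$volume_ul[ti] <- if (prop) 0 else length(vox) * vv
      pts$enhancing[ti] <- detect_enhancement(subs[[ti]],
                                              mask_from_idx(roi, dim(bg_mask)),
                                              bg_mask, k_sigma)$enhancing
    }
    ev <- events[events$track_id == k, , drop = FALSE]
    out[[k]] <- structure(list(track_id = k,
                               first_detection_week = weeks[min(present)],
                               points = pts,
                               max_roi = max_roi,
                               voxels_by_week = tr$voxels_by_week,
                               terminal_enhancing = pts$enhancing[nt],
                               events = ev),
                          class = "lesion_track")
  }
  out
}

track_max_roi <- function(tr) {
  sizes <- vapply(tr$voxels_by_week,
                  function(v) if (is.null(v)) 0L else length(v), integer(1))
  tr$voxels_by_week[[which.max(sizes)]]
}

mask_from_idx <- function(idx, d) {
  m <- array(FALSE, d)
  m[idx] <- TRUE
  m
}

#' Tidy per-track per-week table
#'
#' @param tracks list of \code{lesion_track}.
#' @param subject_id subject label for the first column.
#' @return data.frame: subject, track_id, week, volume_ul,
#'   mean_norm_intensity, sd_norm_intensity, roi_propagated, enhancing.
#' @export
tracks_to_table <- function(tracks, subject_id = "S1") {
  do.call(rbind, lapply(tracks, function(tr)
    cbind(subject = subject_id, track_id = tr$track_id, tr$points)))
}

#' @export
print.lesion_track <- function(x, ...) {
  cat("lesion_track", x$track_id, "- first detected week",
      x$first_detection_week, "; peak",
      signif(max(x$points$volume_ul), 3), "uL;",
      if (isTRUE(x$terminal_enhancing)) "enhancing" else "not enhancing",
      "at terminal scan\n")
  invisible(x)
}
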