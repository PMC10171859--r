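#' Classification rule configuration
#'
#' Operationalizes the qualitative rater criteria. A timepoint is
#' "hyperintense" when its mean normalized intensity exceeds the pre-lesion
#' baseline mean by more than \code{max(min_hyper_margin,
#' isointensity_k_sigma * baseline SD)}; "isointense" is its negation.
#'
#' @param isointensity_k_sigma baseline-SD multiplier (default 2).
#' @param min_hyper_margin floor on the hyperintensity margin, normalized
#'   units (default 0.05).
#' @param size_rule_threshold_ul peak-volume cutoff for the size rule
#'   (default 0.5 uL, inclusive).
#' @return list of class \code{classification_rule_config}.
#' @export
classification_rule_config <- function(isointensity_k_sigma = 2,
                                       min_hyper_margin = 0.05,
                                       size_rule_threshold_ul = 0.5) {
  stopifnot(isointensity_k_sigma > 0, min_hyper_margin > 0,
            size_rule_threshold_ul > 0)
  structure(list(isointensity_k_sigma = isointensity_k_sigma,
                 min_hyper_margin = min_hyper_margin,
                 size_rule_threshold_ul = size_rule_threshold_ul),
            class = "classification_rule_config")
}

track_hyper_flags <- function(track, cfg) {
  pts <- track$points
  base_idx <- which(pts$roi_propagated & pts$week < track$first_detection_week)
  if (length(base_idx) < 2)
    stop("track ", track$track_id,
         ": fewer than 2 pre-lesion baseline points; cannot estimate baseline")
  mu_b <- mean(pts$mean_norm_intensity[base_idx])
  sd_b <- stats::sd(pts$mean_norm_intensity[base_idx])
  margin <- max(cfg$min_hyper_margin, cfg$isointensity_k_sigma * sd_b)
  list(hyper = pts$mean_norm_intensity > mu_b + margin,
       mu_b = mu_b, sd_b = sd_b, margin = margin)
}

#' Classify a lesion track into the three MRI categories
#'
#' Rules, evaluated in order against the terminal scan:
#' \enumerate{
#'   \item hyperintense at terminal and enhancing -> \code{early_active};
#'   \item hyperintense at terminal, not enhancing ->
#'     \code{chronic_demyelinated};
#'   \item hyperintense at some earlier scan, isointense at terminal, not
#'     enhancing -> \code{remyelinated}.
#' }
#' Enhancement takes precedence: a terminal-enhancing hyperintense track is
#' early active even if shrinking.
#'
#' @param track a \code{lesion_track} from [build_tracks()].
#' @param cfg a [classification_rule_config()].
#' @return one of \code{"early_active"}, \code{"chronic_demyelinated"},
#'   \code{"remyelinated"}.
#' @export
classify_track <- function(track, cfg = classification_rule_config()) {
  hf <- track_hyper_flags(track, cfg)
  hyper <- hf$hyper
  if (!any(hyper, na.rm = TRUE))
    stop("track ", track$track_id,
         " is never hyperintense at any timepoint: not a lesion track")
  nt <- length(hyper)
  term_hyper <- isTRUE(hyper[nt])
  term_enh <- isTRUE(track$terminal_enhancing)
  if (term_hyper && term_enh) return("early_active")
  if (term_hyper) return("chronic_demyelinated")
  if (any(hyper[-nt], na.rm = TRUE) && !term_enh) return("remyelinated")
  stop("track ", track$track_id,
       " hyperintense only at an enhancing terminal scan; cannot categorize")
}

#' Peak-size rule: is remyelination possible for this track?
#'
#' Lesions whose peak volume on PDw exceeds ~0.5 uL do not return to
#' isointensity; the boundary is inclusive (a peak of exactly 0.5 uL still
#' counts as remyelination-possible).
#'
#' @param track a \code{lesion_track}.
#' @param threshold_ul peak-volume cutoff (default 0.5 uL).
#' @return TRUE iff the maximum volume over non-propagated points is
#'   <= \code{threshold_ul}.
#' @export
predict_by_peak_size <- function(track, threshold_ul = 0.5) {
  obs <- track$points[!track$points$roi_propagated, , drop = FALSE]
  if (nrow(obs) == 0) stop("track ", track$track_id, ": all points ROI-propagated")
  max(obs$volume_ul) <= threshold_ul
}

#' Estimate the demyelination/remyelination window of a remyelinated track
#'
#' The demyelination start is the first hyperintense scan; remyelination
#' start is the scan of maximal mean normalized intensity; the plateau is the
#' first subsequent scan that is isointense and remains so for every later
#' non-propagated point. The remyelination duration is plateau minus
#' remyelination start.
#'
#' @param track a \code{lesion_track}.
#' @param cfg a [classification_rule_config()].
#' @return list(demyel_start_week, remyel_start_week, plateau_week,
#'   remyelination_duration_weeks), or NULL when the track is not
#'   remyelinated or never plateaus at isointensity.
#' @export
estimate_remyelination_window <- function(track, cfg = classification_rule_config()) {
  cl <- tryCatch(classify_track(track, cfg), error = function(e) NA_character_)
  if (!identical(cl, "remyelinated")) return(NULL)
  hf <- track_hyper_flags(track, cfg)
  pts <- track$points
  hyper <- hf$hyper
  demyel_start <- pts$week[which(hyper)[1]]
  peak_idx <- which.max(pts$mean_norm_intensity)
  remyel_start <- pts$week[peak_idx]
  nt <- nrow(pts)
  if (peak_idx >= nt) return(NULL)
  plateau_idx <- NA_integer_
  for (ti in seq(peak_idx + 1, nt)) {
    later <- seq(ti, nt)
    ok_later <- !hyper[later] | pts$roi_propagated[later]
    if (!hyper[ti] && all(ok_later)) { plateau_idx <- ti; break }
  }
  if (is.na(plateau_idx)) return(NULL)
  plateau_week <- pts$week[plateau_idx]
  list(demyel_start_week = demyel_start,
       remyel_start_week = remyel_start,
       plateau_week = plateau_week,
       remyelination_duration_weeks = plateau_week - remyel_start)
}

#' Classify all tracks of a study
#'
#' Tracks that cannot be categorized — e.g. split fragments whose pre-lesion
#' baseline is contaminated by the parent lesion, or tracks that are never
#' hyperintense — get category NA with the reason in \code{note} instead of
#' aborting the batch.
#'
#' @param tracks list of \code{lesion_track}.
#' @param cfg a [classification_rule_config()].
#' @return data.frame: track_id, category, peak_volume_ul,
#'   size_rule_prediction, first_detection_week, the estimated window weeks
#'   (NA for non-remyelinated tracks), and note.
#' @export
classify_tracks <- function(tracks, cfg = classification_rule_config()) {
  rows <- lapply(tracks, function(tr) {
    note <- NA_character_
    cat_ <- tryCatch(classify_track(tr, cfg),
                     error = function(e) { note <<- conditionMessage(e); NA_character_ })
    w <- if (is.na(cat_)) NULL else estimate_remyelination_window(tr, cfg)
    obs <- tr$points[!tr$points$roi_propagated, , drop = FALSE]
    data.frame(track_id = tr$track_id,
               category = cat_,
               peak_volume_ul = max(obs$volume_ul),
               size_rule_prediction = predict_by_peak_size(tr, cfg$size_rule_threshold_ul),
               first_detection_week = tr$first_detection_week,
               demyel_start_week = if (is.null(w)) NA_real_ else w$demyel_start_week,
               remyel_start_week = if (is.null(w)) NA_real_ else w$remyel_start_week,
               plateau_week = if (is.null(w)) NA_real_ else w$plateau_week,
               remyelination_duration_weeks =
                 if (is.null(w)) NA_real_ else w$remyelination_duration_weeks,
               note = note)
  })
  do.call(rbind, rows)
}
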