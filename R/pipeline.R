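#' Run the full MRI analysis chain on one study
#'
#' Normalize -> segment -> track -> classify on a \code{study_timeline};
#' returns the tracks, the per-track classification table and the tidy
#' trajectory table.
#'
#' @param timeline a \code{study_timeline}.
#' @param rule_cfg a [classification_rule_config()].
#' @param ... segmentation/tracking options passed to [build_tracks()].
#' @return list(tracks, labels, trajectories).
#' @export
analyze_study <- function(timeline, rule_cfg = classification_rule_config(), ...) {
  tracks <- build_tracks(timeline, ...)
  labels <- if (length(tracks)) classify_tracks(tracks, rule_cfg) else
    data.frame(track_id = integer(0), category = character(0))
  list(tracks = tracks, labels = labels,
       trajectories = if (length(tracks))
         tracks_to_table(tracks, timeline$subject_id) else NULL)
}

#' Match detected tracks to ground-truth lesions
#'
#' A track matches the ground-truth lesion whose center voxel lies inside the
#' track's maximum-extent ROI (synthetic lesions are disjoint, so the match
#' is unambiguous).
#'
#' When several tracks claim the same lesion (a split fragment alongside the
#' main track), the one with the larger maximum extent keeps the match.
#'
#' @param tracks list of \code{lesion_track}.
#' @param lesions ground-truth list from [simulate_study()].
#' @param grid_shape voxel grid dimensions.
#' @return data.frame: track_id, lesion_id (NA when unmatched).
#' @export
match_tracks_to_truth <- function(tracks, lesions, grid_shape) {
  centers <- vapply(lesions, function(L)
    L$center_voxel[1] + grid_shape[1] * ((L$center_voxel[2] - 1) +
                                         grid_shape[2] * (L$center_voxel[3] - 1)),
    numeric(1))
  rows <- lapply(tracks, function(tr) {
    hit <- which(centers %in% tr$max_roi)
    data.frame(track_id = tr$track_id,
               lesion_id = if (length(hit) == 1) lesions[[hit]]$lesion_id
                           else NA_integer_,
               roi_voxels = length(tr$max_roi))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$lesion_id, -out$roi_voxels), , drop = FALSE]
  dup <- duplicated(out$lesion_id) & !is.na(out$lesion_id)
  out$lesion_id[dup] <- NA_integer_
  out[order(out$track_id), c("track_id", "lesion_id")]
}

#' Simulate and analyze a multi-subject cohort
#'
#' Runs [simulate_study()] and [analyze_study()] for \code{n_subjects}
#' studies (seeds derived from \code{config$seed}) and assembles a
#' lesion-level table joining the MRI classification to the generator ground
#' truth, including terminal histology rendered and re-quantified through the
#' stain pipeline.
#'
#' @param n_subjects number of studies.
#' @param config base [simulation_config()]; per-subject seeds are
#'   \code{config$seed + subject index}.
#' @param rule_cfg a [classification_rule_config()].
#' @param quantify_histology render + quantify stain images per lesion and
#'   classify histologically (slower); otherwise histology columns are NA.
#' @return data.frame, one row per ground-truth lesion: subject, lesion_id,
#'   true_class, mri_category (NA if the lesion was never detected),
#'   peak_volume_ul (detected), true_peak_volume_ul, size_rule_prediction,
#'   estimated/true remyelination windows, lesion_age_weeks, opc_count,
#'   histo_category, histo_discordant.
#' @export
simulate_cohort <- function(n_subjects, config = simulation_config(),
                            rule_cfg = classification_rule_config(),
                            quantify_histology = FALSE) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    cfg <- config
    cfg$seed <- config$seed + s
    study <- simulate_study(cfg, subject_id = sprintf("S%02d", s))
    res <- analyze_study(study$timeline, rule_cfg)
    mt <- match_tracks_to_truth(res$tracks, study$lesions, cfg$grid_shape)
    for (L in study$lesions) {
      tid <- mt$track_id[match(L$lesion_id, mt$lesion_id)]
      lab <- if (!is.na(tid)) res$labels[res$labels$track_id == tid, ] else NULL
      hcat <- NA_character_; hdis <- NA; hm <- NULL
      if (quantify_histology) {
        stains <- render_histology(L$histo_truth,
                                   seed = cfg$seed * 1000L + L$lesion_id)
        hm <- quantify_stains(stains)
        hc <- classify_histology(hm, hm$iba1_density)
        hcat <- hc$category; hdis <- hc$discordant
      }
      rows[[length(rows) + 1]] <- data.frame(
        subject = study$timeline$subject_id,
        lesion_id = L$lesion_id,
        true_class = L$true_class,
        mri_category = if (is.null(lab)) NA_character_ else lab$category,
        peak_volume_ul = if (is.null(lab)) NA_real_ else lab$peak_volume_ul,
        true_peak_volume_ul = L$peak_volume_ul,
        size_rule_prediction = if (is.null(lab)) NA else lab$size_rule_prediction,
        first_detection_week = if (is.null(lab)) NA_real_ else lab$first_detection_week,
        onset_week = L$onset_week,
        est_remyel_duration_weeks =
          if (is.null(lab)) NA_real_ else lab$remyelination_duration_weeks,
        true_remyel_duration_weeks = L$remyelination_duration_weeks,
        lesion_age_weeks = L$lesion_age_weeks,
        opc_count = L$histo_truth$opc_count,
        plp_unstained_pct = L$histo_truth$plp_unstained_pct,
        histo_category = hcat,
        histo_discordant = hdis)
    }
  }
  do.call(rbind, rows)
}

#' Classification accuracy against generator ground truth
#'
#' @param cohort table from [simulate_cohort()].
#' @return fraction of lesions whose MRI category equals the true class
#'   (an undetected lesion counts as an error).
#' @export
classification_accuracy <- function(cohort) {
  mean(!is.na(cohort$mri_category) & cohort$mri_category == cohort$true_class)
}

#' Run the end-to-end pipeline from a configuration and write all artifacts
#'
#' Simulates a study (or reads one from \code{input_dir}), writes the
#' volumes, runs segmentation/tracking/classification, renders and
#' quantifies terminal histology, computes the radiological-pathological
#' concordance report, and writes every intermediate table. The run is fully
#' reproducible from the configuration seed.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (created if needed).
#' @param input_dir optional directory with a previously written study (see
#'   [write_study()]); when given, simulation is skipped.
#' @param rule_cfg a [classification_rule_config()].
#' @param write_volumes write per-timepoint NIfTI volumes (slow; default
#'   FALSE keeps runs light).
#' @return invisible list of output paths and the in-memory report.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         input_dir = NULL,
                         rule_cfg = classification_rule_config(),
                         write_volumes = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(input_dir)) {
    if (!dir.exists(input_dir)) stop("input directory not found: ", input_dir)
    study <- read_study(input_dir)
  } else {
    study <- simulate_study(config)
  }
  if (write_volumes) write_study(study, file.path(out_dir, "study"))

  res <- analyze_study(study$timeline, rule_cfg)
  mt <- match_tracks_to_truth(res$tracks, study$lesions, dim(study$timeline$gm_mask))

  lesion_rows <- lapply(study$lesions, function(L) {
    tid <- mt$track_id[match(L$lesion_id, mt$lesion_id)]
    lab <- if (!is.na(tid)) res$labels[res$labels$track_id == tid, ] else NULL
    stains <- render_histology(L$histo_truth,
                               seed = config$seed * 1000L + L$lesion_id)
    hm <- quantify_stains(stains)
    hc <- classify_histology(hm, hm$iba1_density)
    data.frame(subject = study$timeline$subject_id, lesion_id = L$lesion_id,
               true_class = L$true_class,
               mri_category = if (is.null(lab)) NA_character_ else lab$category,
               histo_category = hc$category,
               histo_discordant = hc$discordant,
               plp_unstained_pct = hm$plp_unstained_pct,
               lfb_unstained_pct = hm$lfb_unstained_pct,
               oligo_count = hm$oligo_count, opc_count = hm$opc_count)
  })
  lesion_tab <- do.call(rbind, lesion_rows)

  # concordance of MRI against generator truth (binary remyelination)
  truth_tab <- data.frame(mri_category = lesion_tab$mri_category,
                          histo_category = lesion_tab$true_class)
  cm <- binarize_and_tabulate(truth_tab)
  report <- list(confusion_matrix = unclass(cm)[c("tp", "fn", "fp", "tn")],
                 concordance = tryCatch(concordance_summary(cm),
                                        error = function(e) conditionMessage(e)),
                 n_tracks = length(res$tracks),
                 n_lesions_truth = length(study$lesions))

  paths <- list(
    trajectories = file.path(out_dir, "trajectories.csv"),
    labels = file.path(out_dir, "labels.csv"),
    lesions = file.path(out_dir, "lesions.csv"),
    report = file.path(out_dir, "report.json"))
  if (!is.null(res$trajectories))
    utils::write.csv(res$trajectories, paths$trajectories, row.names = FALSE)
  utils::write.csv(res$labels, paths$labels, row.names = FALSE)
  utils::write.csv(lesion_tab, paths$lesions, row.names = FALSE)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, report = report, lesions = lesion_tab,
                 labels = res$labels))
}
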