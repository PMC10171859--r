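#' Write / read a volume as NIfTI
#'
#' Round trip preserves the voxel array and spacing.
#'
#' @param data 3D numeric array.
#' @param path output .nii / .nii.gz path.
#' @param voxel_size_mm voxel spacing, mm.
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, voxel_size_mm = c(0.15, 0.15, 1.0)) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @return \code{read_volume}: list(data, voxel_size_mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)),
       voxel_size_mm = RNifti::pixdim(img)[seq_len(3)])
}

#' Write a simulated study to disk
#'
#' One NIfTI per contrast per timepoint (filenames carry the subject ID and
#' week index), uint8 GM/WM masks, a JSON ground-truth manifest and a CSV
#' lesion table.
#'
#' @param study a \code{synthetic_study} from [simulate_study()].
#' @param dir output directory.
#' @return invisible vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tl <- study$timeline
  vs <- tl$voxel_size_mm
  paths <- character(0)
  for (ct in names(tl$volumes)) for (ti in seq_along(tl$weeks)) {
    p <- file.path(dir, sprintf("%s_week%03d_%s.nii.gz", tl$subject_id,
                                as.integer(tl$weeks[ti]), ct))
    write_volume(tl$volumes[[ct]][[ti]], p, vs)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, paste0(tl$subject_id, "_gm_mask.nii.gz"))
  write_volume(array(as.integer(tl$gm_mask), dim(tl$gm_mask)), pm, vs)
  pw <- file.path(dir, paste0(tl$subject_id, "_wm_mask.nii.gz"))
  write_volume(array(as.integer(tl$wm_mask), dim(tl$wm_mask)), pw, vs)

  manifest <- list(subject_id = tl$subject_id, weeks = tl$weeks,
                   voxel_size_mm = vs, wm_baseline = tl$wm_baseline,
                   contrasts = names(tl$volumes),
                   config = unclass(study$config),
                   lesions = lapply(study$lesions, function(L)
                     L[setdiff(names(L), "histo_truth")]),
                   histo_truth = lapply(study$lesions, `[[`, "histo_truth"))
  pj <- file.path(dir, paste0(tl$subject_id, "_truth.json"))
  jsonlite::write_json(manifest, pj, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  lesion_csv <- do.call(rbind, lapply(study$lesions, function(L)
    data.frame(subject = tl$subject_id, lesion_id = L$lesion_id,
               true_class = L$true_class, onset_week = L$onset_week,
               peak_volume_ul = L$peak_volume_ul,
               remyelination_duration_weeks = L$remyelination_duration_weeks,
               lesion_age_weeks = L$lesion_age_weeks,
               opc_count = L$histo_truth$opc_count)))
  pc <- file.path(dir, paste0(tl$subject_id, "_lesions.csv"))
  if (!is.null(lesion_csv)) utils::write.csv(lesion_csv, pc, row.names = FALSE)
  invisible(c(paths, pm, pw, pj, pc))
}

#' Read a study previously written by [write_study()]
#'
#' @param dir study directory.
#' @return a \code{synthetic_study} (timeline + ground-truth lesions).
#' @export
read_study <- function(dir) {
  mf <- list.files(dir, pattern = "_truth\\.json$", full.names = TRUE)
  if (length(mf) != 1) stop("expected one *_truth.json manifest in ", dir)
  manifest <- jsonlite::read_json(mf[1], simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sid <- manifest$subject_id
  weeks <- unlist(manifest$weeks)
  vols <- lapply(manifest$contrasts, function(ct) {
    lapply(seq_along(weeks), function(ti) {
      p <- file.path(dir, sprintf("%s_week%03d_%s.nii.gz", sid,
                                  as.integer(weeks[ti]), ct))
      if (!file.exists(p)) stop("missing volume file: ", p)
      read_volume(p)$data
    })
  })
  names(vols) <- unlist(manifest$contrasts)
  gm <- read_volume(file.path(dir, paste0(sid, "_gm_mask.nii.gz")))$data
  wm <- read_volume(file.path(dir, paste0(sid, "_wm_mask.nii.gz")))$data
  lesions <- lapply(seq_along(manifest$lesions), function(i) {
    L <- manifest$lesions[[i]]
    L$histo_truth <- manifest$histo_truth[[i]]
    for (f in c("onset_week", "peak_volume_ul", "remyelination_duration_weeks",
                "lesion_age_weeks"))
      L[[f]] <- if (is.null(L[[f]])) NA_real_ else as.numeric(L[[f]])
    L$center_voxel <- unlist(L$center_voxel)
    L
  })
  timeline <- structure(list(subject_id = sid, weeks = weeks, volumes = vols,
                             gm_mask = gm != 0, wm_mask = wm != 0,
                             voxel_size_mm = unlist(manifest$voxel_size_mm),
                             wm_baseline = manifest$wm_baseline),
                        class = "study_timeline")
  structure(list(timeline = timeline, lesions = lesions,
                 config = manifest$config), class = "synthetic_study")
}

#' Write / read a stain image set as PNG files
#'
#' One grayscale PNG per channel, values clipped to [0, 1]; the exact zeros
#' encoding unstained pixels survive the round trip unchanged.
#'
#' @param stains a \code{stain_image_set}.
#' @param dir output directory.
#' @param prefix filename prefix.
#' @return invisible vector of paths.
#' @export
write_stains <- function(stains, dir, prefix = "lesion") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stains$channels), function(ch) {
    p <- file.path(dir, sprintf("%s_%s.png", prefix, ch))
    img <- stains$channels[[ch]]
    img[img < 0] <- 0; img[img > 1] <- 1
    png::writePNG(img, p)
    p
  }, character(1))
  meta <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(list(pixel_size_um = stains$pixel_size_um,
                            lesion_center_px = stains$lesion_center_px,
                            channels = names(stains$channels)),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta))
}

#' @rdname write_stains
#' @export
read_stains <- function(dir, prefix = "lesion") {
  meta_p <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(meta_p)) stop("stain metadata not found: ", meta_p)
  meta <- jsonlite::read_json(meta_p, simplifyVector = TRUE)
  channels <- lapply(meta$channels, function(ch) {
    p <- file.path(dir, sprintf("%s_%s.png", prefix, ch))
    if (!file.exists(p)) stop("missing stain channel file: ", p)
    png::readPNG(p)
  })
  names(channels) <- meta$channels
  structure(list(channels = channels, pixel_size_um = meta$pixel_size_um,
                 lesion_center_px = meta$lesion_center_px),
            class = "stain_image_set")
}

#' Read a lesion label table with schema validation
#'
#' @param path CSV path.
#' @param required column names that must be present.
#' @return data.frame.
#' @export
read_label_table <- function(path, required = c("subject", "lesion_id",
                                                "mri_category")) {
  if (!file.exists(path)) stop("label table not found: ", path)
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(tb))
  if (length(missing))
    stop("label table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  tb
}
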