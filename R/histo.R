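#' Percentage of unstained (null) pixels in an ROI
#'
#' Unstained tissue is encoded by exactly-zero pixels; the statistic is
#' \code{100 * n_null / n_total} over the ROI, the standard thresholding
#' readout for demyelinated area on PLP/LFB sections.
#'
#' @param channel 2D numeric matrix (one stain channel).
#' @param roi logical matrix of the same shape, or NULL for the whole image.
#' @return percentage in [0, 100].
#' @export
quantify_unstained <- function(channel, roi = NULL) {
  roi <- roi_or_full(roi, dim(channel))
  n <- sum(roi)
  if (n == 0) stop("ROI is empty")
  100 * sum(channel[roi] == 0) / n
}

#' Count mature oligodendrocytes and OPC on an ASPA/Olig2 double stain
#'
#' Both channels are binarized at \code{positivity_threshold}; connected
#' components of Olig2-positive pixels inside the ROI are cells. A cell whose
#' pixels are at least 50% ASPA-positive is a mature oligodendrocyte
#' (ASPA+/Olig2+); otherwise it is an oligodendrocyte precursor
#' (ASPA-/Olig2+).
#'
#' @param aspa,olig2 aligned 2D numeric matrices.
#' @param roi logical matrix or NULL for the whole image.
#' @param positivity_threshold binarization cutoff; must lie within the
#'   Olig2 channel's range.
#' @param aspa_overlap_frac fraction of a cell's pixels that must be
#'   ASPA-positive to call it mature (default 0.5).
#' @return list(oligo_count, opc_count).
#' @export
count_cells <- function(aspa, olig2, roi = NULL, positivity_threshold = 0.5,
                        aspa_overlap_frac = 0.5) {
  if (!identical(dim(aspa), dim(olig2))) stop("ASPA and Olig2 grids differ in shape")
  lo <- min(0, min(olig2)); hi <- max(1, max(olig2))
  if (positivity_threshold < lo || positivity_threshold > hi)
    stop("positivity_threshold ", positivity_threshold,
         " lies outside the channel intensity range [",
         signif(lo, 3), ", ", signif(hi, 3), "]")
  roi <- roi_or_full(roi, dim(aspa))
  olig2_pos <- (olig2 >= positivity_threshold) & roi
  aspa_pos <- aspa >= positivity_threshold
  lab <- EBImage::bwlabel(olig2_pos)
  ncell <- max(lab)
  if (ncell == 0) return(list(oligo_count = 0L, opc_count = 0L))
  frac <- vapply(seq_len(ncell), function(k) mean(aspa_pos[lab == k]), numeric(1))
  oligo <- sum(frac >= aspa_overlap_frac)
  list(oligo_count = as.integer(oligo), opc_count = as.integer(ncell - oligo))
}

#' Thresholds for histological lesion categorization
#'
#' @param remyel_max_unstained_pct maximum PLP unstained area for a
#'   remyelinated call (default 6, "less than 6% of unstained area").
#' @param oligo_min minimum mature-oligodendrocyte count for a remyelinated
#'   call (default 6, above the chronic-class mean of the generator).
#' @param iba1_inflammation_cutoff Iba1 positive-pixel fraction marking
#'   prominent inflammatory infiltration (default 0.3).
#' @param lfb_demyelinated_pct LFB unstained area above which a PLP-called
#'   remyelinated lesion is flagged discordant (default 20).
#' @return named list.
#' @export
histo_thresholds <- function(remyel_max_unstained_pct = 6, oligo_min = 6,
                             iba1_inflammation_cutoff = 0.3,
                             lfb_demyelinated_pct = 20) {
  list(remyel_max_unstained_pct = remyel_max_unstained_pct,
       oligo_min = oligo_min,
       iba1_inflammation_cutoff = iba1_inflammation_cutoff,
       lfb_demyelinated_pct = lfb_demyelinated_pct)
}

#' Assign the histological lesion category from quantified metrics
#'
#' Remyelinated iff PLP unstained area <= \code{remyel_max_unstained_pct} and
#' the mature-oligodendrocyte count >= \code{oligo_min}; otherwise early
#' active iff the Iba1 density marks prominent infiltration, else chronic (at
#' least partially) demyelinated. A lesion remyelinated on PLP but
#' demyelinated on LFB (> \code{lfb_demyelinated_pct}) is classified by PLP
#' and flagged discordant.
#'
#' @param metrics list with \code{plp_unstained_pct}, \code{lfb_unstained_pct},
#'   \code{oligo_count} (e.g. from [quantify_unstained()]/[count_cells()]).
#' @param iba1_density Iba1 positive-pixel fraction in the ROI.
#' @param thresholds see [histo_thresholds()].
#' @return list(category, discordant).
#' @export
classify_histology <- function(metrics, iba1_density,
                               thresholds = histo_thresholds()) {
  th <- thresholds
  remyel <- metrics$plp_unstained_pct <= th$remyel_max_unstained_pct &&
    metrics$oligo_count >= th$oligo_min
  if (remyel) {
    discordant <- metrics$lfb_unstained_pct > th$lfb_demyelinated_pct
    return(list(category = "remyelinated", discordant = discordant))
  }
  cat_ <- if (iba1_density >= th$iba1_inflammation_cutoff) "early_active"
          else "chronic_demyelinated"
  list(category = cat_, discordant = FALSE)
}

#' Iba1 positive-pixel density in an ROI
#'
#' @param iba1 2D numeric matrix.
#' @param roi logical matrix or NULL for the whole image.
#' @param positivity_threshold binarization cutoff (default 0.5).
#' @return fraction of ROI pixels above threshold.
#' @export
iba1_density <- function(iba1, roi = NULL, positivity_threshold = 0.5) {
  roi <- roi_or_full(roi, dim(iba1))
  if (!any(roi)) stop("ROI is empty")
  mean(iba1[roi] >= positivity_threshold)
}

#' Square analysis ROI centered on the lesion core
#'
#' By default \code{roi_spec} is interpreted as the side length of a square
#' in micrometers (a 1500 um square covers even the largest lesion); set
#' \code{spec_is_area = TRUE} for the literal reading where \code{roi_spec}
#' is the area in um^2 (1500 um^2 gives a ~38.7 um side). The region is
#' clipped to the image with a warning.
#'
#' @param center_px (row, col) pixel center.
#' @param image_dim image dimensions (rows, cols).
#' @param pixel_size_um pixel size in micrometers.
#' @param roi_spec side length in um (default 1500), or area in um^2 when
#'   \code{spec_is_area}.
#' @param spec_is_area interpret \code{roi_spec} as an area.
#' @return logical matrix marking the ROI.
#' @export
roi_from_center <- function(center_px, image_dim, pixel_size_um,
                            roi_spec = 1500, spec_is_area = FALSE) {
  stopifnot(pixel_size_um > 0, roi_spec > 0)
  if (any(center_px < 1) || any(center_px > image_dim))
    stop("ROI center lies outside the image")
  side_um <- if (spec_is_area) sqrt(roi_spec) else roi_spec
  half <- (side_um / pixel_size_um) / 2
  r0 <- max(1, ceiling(center_px[1] - half)); r1 <- min(image_dim[1], floor(center_px[1] + half))
  c0 <- max(1, ceiling(center_px[2] - half)); c1 <- min(image_dim[2], floor(center_px[2] + half))
  if (r1 < r0 || c1 < c0) stop("ROI degenerate after clipping to the image")
  if (center_px[1] - half < 0.5 || center_px[1] + half > image_dim[1] + 0.5 ||
      center_px[2] - half < 0.5 || center_px[2] + half > image_dim[2] + 0.5)
    warning("ROI clipped at the image boundary; region smaller than nominal")
  roi <- matrix(FALSE, image_dim[1], image_dim[2])
  roi[r0:r1, c0:c1] <- TRUE
  roi
}

#' Quantify a full stain image set
#'
#' Applies [quantify_unstained()], [count_cells()] and [iba1_density()] to a
#' \code{stain_image_set} (see [render_histology()]) over an ROI centered on
#' the lesion core.
#'
#' @param stains a \code{stain_image_set}.
#' @param roi logical matrix; NULL quantifies the whole image.
#' @param positivity_threshold for the cell channels and Iba1.
#' @return list of class \code{histo_metrics}: plp_unstained_pct,
#'   lfb_unstained_pct, oligo_count, opc_count, iba1_density, roi_area_um2.
#' @export
quantify_stains <- function(stains, roi = NULL, positivity_threshold = 0.5) {
  ch <- stains$channels
  roi <- roi_or_full(roi, dim(ch$PLP))
  cc <- count_cells(ch$ASPA, ch$Olig2, roi, positivity_threshold)
  structure(list(plp_unstained_pct = quantify_unstained(ch$PLP, roi),
                 lfb_unstained_pct = quantify_unstained(ch$LFB, roi),
                 oligo_count = cc$oligo_count,
                 opc_count = cc$opc_count,
                 iba1_density = iba1_density(ch$Iba1, roi, positivity_threshold),
                 roi_area_um2 = sum(roi) * stains$pixel_size_um^2),
            class = "histo_metrics")
}

roi_or_full <- function(roi, d) {
  if (is.null(roi)) return(matrix(TRUE, d[1], d[2]))
  if (!identical(dim(roi), as.integer(d)) && !identical(dim(roi), d))
    stop("ROI shape does not match the image")
  roi != 0
}
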