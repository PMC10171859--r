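#' Configuration for the synthetic longitudinal MRI study generator
#'
#' Defaults describe the study conditions the generator emulates: weekly
#' scanning of a marmoset EAE brain with focal white-matter lesions whose
#' normalized PDw intensity rises from the normal-appearing white matter
#' (NAWM) band (0.65--0.75) to hyperintensity over a 4--7 week demyelination
#' phase and, for the remyelinating class only, returns to baseline over a
#' 4--9 week remyelination phase. Class proportions default to the cohort
#' totals observed on MRI (30% early active / 25% chronic demyelinated /
#' 45% remyelinated). Remyelinating lesions are constrained to peak volumes
#' at or below 0.5 uL; the other classes may exceed it.
#'
#' @param grid_shape integer 3-vector of voxels per axis.
#' @param voxel_size_mm voxel spacing in mm; defaults give 0.0225 uL/voxel.
#' @param n_timepoints number of weekly scans (>= 2 pre-lesion baselines are
#'   always reserved at the start).
#' @param scan_interval_weeks spacing between scans in weeks.
#' @param n_lesions number of lesions to place.
#' @param class_proportions probabilities over (early_active,
#'   chronic_demyelinated, remyelinated); must sum to 1.
#' @param nawm_intensity_band normalized NAWM intensity range.
#' @param lesion_peak_intensity_range normalized peak intensity range.
#' @param onset_intensity normalized intensity at the scan where a lesion
#'   first appears (above the default segmentation threshold of 0.80, so a
#'   lesion is detectable from its onset scan).
#' @param demyelination_duration_weeks_range weeks from onset to peak.
#' @param remyelination_duration_weeks_range weeks from peak back to baseline
#'   (remyelinated class only).
#' @param peak_volume_ul_range log-uniform range of peak lesion volumes, uL.
#'   The lower default (0.1 uL) sits just above the 4-voxel detection floor
#'   (0.09 uL at default spacing) so every simulated lesion is detectable.
#' @param enhancement_probability probability that a newly detected lesion
#'   shows gadolinium enhancement at first detection (82% reported).
#' @param enhancement_offset added to post-gadolinium T1 signal inside an
#'   enhancing lesion, normalized units.
#' @param noise_sd SD of additive Gaussian noise, normalized units.
#' @param seed integer RNG seed.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(grid_shape = c(64L, 64L, 24L),
                              voxel_size_mm = c(0.15, 0.15, 1.0),
                              n_timepoints = 30L,
                              scan_interval_weeks = 1.0,
                              n_lesions = 8L,
                              class_proportions = c(early_active = 0.30,
                                                    chronic_demyelinated = 0.25,
                                                    remyelinated = 0.45),
                              nawm_intensity_band = c(0.65, 0.75),
                              lesion_peak_intensity_range = c(0.85, 1.00),
                              onset_intensity = 0.82,
                              demyelination_duration_weeks_range = c(4, 7),
                              remyelination_duration_weeks_range = c(4, 9),
                              peak_volume_ul_range = c(0.1, 3.0),
                              enhancement_probability = 0.82,
                              enhancement_offset = 0.2,
                              noise_sd = 0.01,
                              seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_timepoints = as.integer(n_timepoints),
              scan_interval_weeks = scan_interval_weeks,
              n_lesions = as.integer(n_lesions),
              class_proportions = class_proportions,
              nawm_intensity_band = nawm_intensity_band,
              lesion_peak_intensity_range = lesion_peak_intensity_range,
              onset_intensity = onset_intensity,
              demyelination_duration_weeks_range = demyelination_duration_weeks_range,
              remyelination_duration_weeks_range = remyelination_duration_weeks_range,
              peak_volume_ul_range = peak_volume_ul_range,
              enhancement_probability = enhancement_probability,
              enhancement_offset = enhancement_offset,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape >= 8),
            length(cfg$voxel_size_mm) == 3, all(cfg$voxel_size_mm > 0),
            cfg$n_timepoints >= 4, cfg$scan_interval_weeks > 0,
            cfg$n_lesions >= 0,
            length(cfg$class_proportions) == 3, all(cfg$class_proportions >= 0),
            all(diff(cfg$nawm_intensity_band) > 0),
            all(diff(cfg$lesion_peak_intensity_range) > 0),
            all(cfg$demyelination_duration_weeks_range > 0),
            all(cfg$remyelination_duration_weeks_range > 0),
            all(cfg$peak_volume_ul_range > 0),
            cfg$enhancement_probability >= 0, cfg$enhancement_probability <= 1,
            cfg$noise_sd >= 0)
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  invisible(cfg)
}

#' Per-voxel volume in microliters
#' @param voxel_size_mm voxel spacing in mm.
#' @return scalar uL (1 mm^3 = 1 uL).
#' @export
voxel_volume_ul <- function(voxel_size_mm) prod(voxel_size_mm)

lesion_classes <- c("early_active", "chronic_demyelinated", "remyelinated")

#' Simulate a serial multicontrast MRI study with known lesion ground truth
#'
#' Generates a weekly multicontrast study (PDw, T1w pre/post gadolinium,
#' MT-on/MT-off) on a shared grid with GM and WM reference masks. Each lesion
#' is an axis-aligned ellipsoid with mild per-axis jitter whose normalized PDw
#' intensity follows: NAWM baseline, linear rise from \code{onset_intensity}
#' to a peak over the demyelination duration, then (remyelinated class only) a
#' concave decay back to baseline that reaches it exactly at the end of the
#' remyelination window. Volume grows to the peak volume during
#' demyelination. The raw PDw scale varies per week so gray-matter
#' normalization is a real processing step; T1 and MT contrasts are emitted on
#' the normalized scale. Post-gadolinium T1 carries a fixed enhancement offset
#' inside enhancing lesions; enhancement occurs at first detection with
#' probability \code{enhancement_probability}, may persist one extra scan, and
#' early-active lesions always enhance at the terminal scan while the other
#' classes never do.
#'
#' @param config a [simulation_config()].
#' @param subject_id label carried into filenames and output tables.
#' @return list of class \code{synthetic_study} with elements
#'   \code{timeline} (a \code{study_timeline}: subject_id, weeks, volumes by
#'   contrast, gm_mask, wm_mask, voxel_size_mm) and \code{lesions} (list of
#'   ground-truth lesion records).
#' @export
simulate_study <- function(config = simulation_config(), subject_id = "S1") {
  validate_simulation_config(config)
  set.seed(config$seed)
  d <- config$grid_shape
  vv <- voxel_volume_ul(config$voxel_size_mm)
  nt <- config$n_timepoints
  weeks <- (seq_len(nt) - 1) * config$scan_interval_weeks

  masks <- make_brain_masks(d)
  wm_baseline <- stats::runif(1, config$nawm_intensity_band[1] + 0.01,
                              config$nawm_intensity_band[2] - 0.01)

  lesions <- place_lesions(config, masks, wm_baseline)

  # normalized-scale anatomical template
  base <- array(0.1, d)
  base[masks$gm] <- 1.0
  base[masks$wm] <- wm_baseline

  t1_base <- array(0.2, d)
  t1_base[masks$gm] <- 1.0
  t1_base[masks$wm] <- 1.15

  mtr_map <- array(0.05, d)
  mtr_map[masks$gm] <- 0.30
  mtr_map[masks$wm] <- 0.40

  contrasts <- c("PDw", "T1w_pre", "T1w_post", "MT_off", "MT_on")
  vols <- lapply(contrasts, function(x) vector("list", nt))
  names(vols) <- contrasts
  pdw_scales <- stats::runif(nt, 150, 250)

  for (ti in seq_len(nt)) {
    pd <- base
    t1pre <- t1_base
    t1post <- t1_base
    mtr_t <- mtr_map
    for (L in lesions) {
      st <- lesion_state(L, weeks[ti], wm_baseline, config)
      if (is.null(st)) next
      pd[st$voxels] <- st$intensity
      t1pre[st$voxels] <- 1.05
      if (ti %in% L$enhancement_scan_idx)
        t1post[st$voxels] <- 1.05 + config$enhancement_offset
      else
        t1post[st$voxels] <- 1.05
      mtr_t[st$voxels] <- 0.40 * (1 - 0.6 * st$severity)
    }
    nz <- function(x) if (config$noise_sd > 0)
      x + array(stats::rnorm(length(x), 0, config$noise_sd), dim(x)) else x
    vols$PDw[[ti]] <- nz(pd) * pdw_scales[ti]
    vols$T1w_pre[[ti]] <- nz(t1pre)
    vols$T1w_post[[ti]] <- nz(t1post)
    m0 <- pd + 0.3  # MT-off shares PDw-like contrast on a slightly offset scale
    vols$MT_off[[ti]] <- nz(m0)
    vols$MT_on[[ti]] <- nz(m0 * (1 - mtr_t))
  }

  timeline <- structure(list(subject_id = subject_id,
                             weeks = weeks,
                             volumes = vols,
                             gm_mask = masks$gm,
                             wm_mask = masks$wm,
                             voxel_size_mm = config$voxel_size_mm,
                             wm_baseline = wm_baseline),
                        class = "study_timeline")
  truth <- lapply(lesions, function(L) {
    list(lesion_id = L$lesion_id,
         true_class = L$true_class,
         onset_week = weeks[L$onset_idx],
         peak_volume_ul = L$peak_volume_ul,
         demyelination_duration_weeks = L$demyel_dur,
         remyelination_onset_week =
           if (L$true_class == "remyelinated") weeks[L$onset_idx] + L$demyel_dur else NA_real_,
         remyelination_duration_weeks =
           if (L$true_class == "remyelinated") L$remyel_dur else NA_real_,
         center_voxel = L$center,
         enhancement_weeks = weeks[L$enhancement_scan_idx],
         lesion_age_weeks = weeks[nt] - weeks[L$onset_idx],
         histo_truth = L$histo_truth)
  })
  structure(list(timeline = timeline, lesions = truth, config = config),
            class = "synthetic_study")
}

#' @export
print.study_timeline <- function(x, ...) {
  cat("study_timeline", x$subject_id, "-", length(x$weeks), "weekly scans,",
      "grid", paste(dim(x$gm_mask), collapse = "x"), "\n")
  invisible(x)
}

# Brain geometry: nested boxes; GM shell around a central WM block.
make_brain_masks <- function(d) {
  brain <- array(FALSE, d)
  gmlo <- pmax(2, round(d * 0.08)); gmhi <- pmin(d - 1, round(d * 0.92))
  brain[gmlo[1]:gmhi[1], gmlo[2]:gmhi[2], gmlo[3]:gmhi[3]] <- TRUE
  wm <- array(FALSE, d)
  wmlo <- round(d * 0.22); wmhi <- round(d * 0.78)
  wm[wmlo[1]:wmhi[1], wmlo[2]:wmhi[2], wmlo[3]:wmhi[3]] <- TRUE
  list(gm = brain & !wm, wm = wm, wm_bounds = rbind(wmlo, wmhi))
}

# Sample ground-truth lesions: class, timing, geometry, enhancement, histology.
place_lesions <- function(config, masks, wm_baseline) {
  n <- config$n_lesions
  if (n == 0) return(list())
  d <- config$grid_shape
  vv <- voxel_volume_ul(config$voxel_size_mm)
  nt <- config$n_timepoints
  cls <- sample(lesion_classes, n, replace = TRUE, prob = config$class_proportions)

  occupied <- array(FALSE, d)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cls[i]
    # durations are drawn on the scan grid: weekly sampling cannot resolve
    # sub-interval phase lengths, so the generated truth is commensurate
    # with what the trajectory estimator can observe
    grid_draw <- function(rng) {
      cand <- seq(rng[1], rng[2], by = config$scan_interval_weeks)
      if (length(cand) == 0) cand <- rng[1]
      if (length(cand) == 1) cand else sample(cand, 1)
    }
    dd <- grid_draw(config$demyelination_duration_weeks_range)
    rd <- grid_draw(config$remyelination_duration_weeks_range)
    pk_rng <- config$peak_volume_ul_range
    if (ci == "remyelinated") pk_rng[2] <- min(pk_rng[2], 0.5)
    peak_ul <- exp(stats::runif(1, log(pk_rng[1]), log(pk_rng[2])))
    peak_int <- stats::runif(1, config$lesion_peak_intensity_range[1],
                             config$lesion_peak_intensity_range[2])

    iv <- config$scan_interval_weeks
    # onset scan index: >= 3 leaves two clean baseline scans; class-specific
    # upper bound guarantees the trajectory completes where the class needs it
    last_ok <- switch(ci,
      remyelinated = nt - ceiling((dd + rd) / iv),
      chronic_demyelinated = nt - ceiling(dd / iv) - 1,
      early_active = nt - 2)
    if (last_ok < 3)
      stop("study too short for a ", ci, " lesion (lesion ", i,
           "): increase n_timepoints")
    first_ok <- if (ci == "early_active") max(3, nt - 9) else 3
    onset_idx <- sample(seq(first_ok, last_ok), 1)

    geo <- NULL
    for (try in 1:200) {
      cand <- sample_lesion_geometry(peak_ul, vv, d, masks, occupied)
      if (!is.null(cand)) { geo <- cand; break }
    }
    if (is.null(geo))
      stop("could not place lesion ", i, " without collision; grid too crowded")
    occupied[geo$moat] <- TRUE

    enh <- integer(0)
    if (stats::runif(1) < config$enhancement_probability) {
      enh <- onset_idx
      if (stats::runif(1) < 0.5 && onset_idx + 1 <= nt) enh <- c(enh, onset_idx + 1)
    }
    if (ci == "early_active") enh <- sort(unique(c(enh, onset_idx, nt)))
    else enh <- enh[enh < nt]  # never enhancing at the terminal scan

    out[[i]] <- list(lesion_id = i, true_class = ci,
                     onset_idx = onset_idx,
                     demyel_dur = dd, remyel_dur = rd,
                     peak_volume_ul = length(geo$peak_voxels) * vv,
                     target_peak_ul = peak_ul,
                     peak_intensity = peak_int,
                     center = geo$center,
                     semi_axes = geo$semi_axes,
                     peak_voxels = geo$peak_voxels,
                     enhancement_scan_idx = enh,
                     histo_truth = NULL)
  }
  ages <- vapply(out, function(L) (nt - L$onset_idx) * config$scan_interval_weeks,
                 numeric(1))
  for (i in seq_len(n))
    out[[i]]$histo_truth <- sample_histo_truth(out[[i]]$true_class, ages[i])
  out
}

# Ellipsoid with mild per-axis jitter, voxelized at peak size; NULL on collision.
sample_lesion_geometry <- function(peak_ul, vv, d, masks, occupied) {
  n_pk <- max(peak_ul / vv, 4.5)
  cz <- max(0.55, min(2.5, 0.35 * n_pk^(1/3)))
  rho <- sqrt(3 * n_pk / (4 * pi * cz))
  jit <- exp(stats::runif(2, -0.15, 0.15))
  ax <- c(rho * jit[1], rho / jit[1] * jit[2], cz)

  lo <- masks$wm_bounds[1, ]; hi <- masks$wm_bounds[2, ]
  marg <- ceiling(ax) + 1
  if (any(hi - lo < 2 * marg)) return(NULL)
  center <- c(sample(seq(lo[1] + marg[1], hi[1] - marg[1]), 1),
              sample(seq(lo[2] + marg[2], hi[2] - marg[2]), 1),
              sample(seq(lo[3] + marg[3], hi[3] - marg[3]), 1))

  vox <- ellipsoid_voxels(center, ax, d)
  for (k in 1:20) {            # guarantee the 4-voxel detection floor
    if (length(vox) >= 4) break
    ax <- ax * 1.08
    vox <- ellipsoid_voxels(center, ax, d)
  }
  if (length(vox) < 4) return(NULL)
  # keep a 1-voxel moat between lesions so components never touch
  dil <- ellipsoid_voxels(center, ax + 1.2, d)
  if (any(occupied[dil])) return(NULL)
  if (!all(masks$wm[vox])) return(NULL)
  list(center = center, semi_axes = ax, peak_voxels = vox, moat = dil)
}

# linear voxel indices inside an axis-aligned ellipsoid (voxel units)
ellipsoid_voxels <- function(center, semi_axes, d) {
  r <- ceiling(semi_axes)
  xs <- max(1, center[1] - r[1]):min(d[1], center[1] + r[1])
  ys <- max(1, center[2] - r[2]):min(d[2], center[2] + r[2])
  zs <- max(1, center[3] - r[3]):min(d[3], center[3] + r[3])
  g <- expand.grid(x = xs, y = ys, z = zs)
  u <- ((g$x - center[1]) / semi_axes[1])^2 +
       ((g$y - center[2]) / semi_axes[2])^2 +
       ((g$z - center[3]) / semi_axes[3])^2
  keep <- g[u <= 1, , drop = FALSE]
  sort((keep$x) + d[1] * ((keep$y - 1) + d[2] * (keep$z - 1)))
}

# Lesion appearance at a given scan week: voxel set, intensity, severity.
# Returns NULL before onset. severity in [0,1] scales the MTR drop.
lesion_state <- function(L, week, wm_baseline, config) {
  onset_week <- (L$onset_idx - 1) * config$scan_interval_weeks
  if (week < onset_week) return(NULL)
  k <- week - onset_week
  dd <- L$demyel_dur
  vv <- voxel_volume_ul(config$voxel_size_mm)
  v0 <- max(5 * vv, 0.25 * L$peak_volume_ul)

  if (k <= dd) {
    frac <- k / dd
    vol <- v0 + (L$peak_volume_ul - v0) * frac
    intensity <- config$onset_intensity +
      (L$peak_intensity - config$onset_intensity) * frac
  } else {
    vol <- L$peak_volume_ul
    if (L$true_class == "remyelinated") {
      u <- (k - dd) / L$remyel_dur
      intensity <- if (u >= 1) wm_baseline
        else wm_baseline + (L$peak_intensity - wm_baseline) * (1 - u)^0.25
    } else intensity <- L$peak_intensity
  }
  s <- (vol / L$peak_volume_ul)^(1/3)
  vox <- if (s >= 1) L$peak_voxels
         else ellipsoid_voxels(L$center, L$semi_axes * s, config$grid_shape)
  if (length(vox) == 0) vox <- L$center[1] +
    config$grid_shape[1] * ((L$center[2] - 1) + config$grid_shape[2] * (L$center[3] - 1))
  sev <- max(0, min(1, (intensity - wm_baseline) /
                       (L$peak_intensity - wm_baseline)))
  list(voxels = vox, intensity = intensity, severity = sev)
}

# Class-conditional terminal histology. Percent-unstained moments follow the
# reported group statistics (PLP 58/38/4.5 +/- 25/25/1.1; LFB 63/43/15 +/-
# 26/26/25; NAWM 2.6 +/- 0.3 PLP, 3.0 +/- 0.4 LFB). Cell-count and Iba1
# distributions reproduce the reported qualitative ordering (see vignette).
sample_histo_truth <- function(true_class, lesion_age_weeks) {
  par <- switch(true_class,
    early_active = list(plp = c(58, 25), lfb = c(63, 26), oligo = c(4, 2),
                        opc = 10, iba1 = c(0.45, 0.08)),
    chronic_demyelinated = list(plp = c(38, 25), lfb = c(43, 26), oligo = c(3, 1.5),
                                opc = 2, iba1 = c(0.15, 0.05)),
    remyelinated = list(plp = c(4.5, 1.1), lfb = c(15, 25), oligo = c(12, 3),
                        opc = 4, iba1 = c(0.08, 0.03)),
    nawm = list(plp = c(2.6, 0.3), lfb = c(3.0, 0.4), oligo = c(18, 3),
                opc = 3, iba1 = c(0.05, 0.02)))
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  list(plp_unstained_pct = clamp(stats::rnorm(1, par$plp[1], par$plp[2]), 0, 100),
       lfb_unstained_pct = clamp(stats::rnorm(1, par$lfb[1], par$lfb[2]), 0, 100),
       oligo_count = max(0L, as.integer(round(stats::rnorm(1, par$oligo[1], par$oligo[2])))),
       opc_count = max(0L, as.integer(round(
         par$opc - 0.12 * lesion_age_weeks + stats::rnorm(1, 0, 1.5)))),
       iba1_density = clamp(stats::rnorm(1, par$iba1[1], par$iba1[2]), 0, 1))
}

#' Sample a terminal histology ground truth for a lesion class
#'
#' Draws percent-unstained PLP/LFB, mature oligodendrocyte (ASPA+/Olig2+) and
#' OPC (ASPA-/Olig2+) counts, and an Iba1 positive-pixel density from the
#' class-conditional distributions used by [simulate_study()]. OPC counts
#' decline with lesion age (older lesions carry fewer precursors).
#'
#' @param true_class one of \code{early_active}, \code{chronic_demyelinated},
#'   \code{remyelinated}, \code{nawm}.
#' @param lesion_age_weeks lesion age at sacrifice, weeks.
#' @param seed optional RNG seed.
#' @return list: \code{plp_unstained_pct}, \code{lfb_unstained_pct},
#'   \code{oligo_count}, \code{opc_count}, \code{iba1_density}.
#' @export
histo_truth <- function(true_class, lesion_age_weeks = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(true_class %in% c(lesion_classes, "nawm"))
  sample_histo_truth(true_class, lesion_age_weeks)
}

#' Render synthetic stain images matching a histology ground truth
#'
#' Produces 2D stain channels (PLP, LFB, Iba1, ASPA, Olig2) over a square
#' region of interest such that the quantification functions recover the
#' truth: the fraction of null (exactly zero) pixels in PLP/LFB equals the
#' unstained percentage to within pixel rounding, Iba1 positive-pixel
#' fraction equals \code{iba1_density}, and the ASPA/Olig2 channels contain
#' disc-shaped cell marks with exactly \code{oligo_count} double-positive and
#' \code{opc_count} Olig2-only cells (cells never touch, so connected
#' component counting is exact).
#'
#' @param truth list as returned by [histo_truth()].
#' @param roi_um side of the square ROI in micrometers.
#' @param pixel_size_um pixel size in micrometers.
#' @param seed RNG seed.
#' @param cell_radius_px disc radius of a rendered cell, pixels.
#' @return object of class \code{stain_image_set}: list with \code{channels}
#'   (named list of 2D matrices in [0,1]), \code{pixel_size_um},
#'   \code{lesion_center_px}.
#' @export
render_histology <- function(truth, roi_um = 1500, pixel_size_um = 5,
                             seed = 1L, cell_radius_px = 3L) {
  stopifnot(roi_um > 0, pixel_size_um > 0)
  set.seed(seed)
  n <- max(8L, as.integer(round(roi_um / pixel_size_um)))
  npx <- n * n

  stained_channel <- function(unstained_pct) {
    ch <- matrix(stats::runif(npx, 0.55, 0.95), n, n)
    k <- round(unstained_pct / 100 * npx)
    if (k > 0) ch[sample.int(npx, k)] <- 0
    ch
  }
  plp <- stained_channel(truth$plp_unstained_pct)
  lfb <- stained_channel(truth$lfb_unstained_pct)

  iba1 <- matrix(stats::runif(npx, 0, 0.2), n, n)
  ki <- round(truth$iba1_density * npx)
  if (ki > 0) iba1[sample.int(npx, ki)] <- stats::runif(ki, 0.7, 1)

  # cells on a jittered grid with guaranteed separation
  r <- as.integer(cell_radius_px)
  pitch <- 2L * r + 3L
  n_cells <- truth$oligo_count + truth$opc_count
  gx <- seq(r + 2L, n - r - 1L, by = pitch)
  gy <- seq(r + 2L, n - r - 1L, by = pitch)
  sites <- as.matrix(expand.grid(gx, gy))
  if (n_cells > nrow(sites))
    stop("requested ", n_cells, " cells but only ", nrow(sites),
         " can be packed in a ", n, "x", n, " image")
  aspa <- matrix(stats::runif(npx, 0, 0.2), n, n)
  olig2 <- matrix(stats::runif(npx, 0, 0.2), n, n)
  if (n_cells > 0) {
    pick <- sites[sample.int(nrow(sites), n_cells), , drop = FALSE]
    is_oligo <- rep(c(TRUE, FALSE), c(truth$oligo_count, truth$opc_count))
    is_oligo <- sample(is_oligo)
    dx <- as.matrix(expand.grid(-r:r, -r:r))
    dx <- dx[rowSums(dx^2) <= r^2, , drop = FALSE]
    for (ci in seq_len(n_cells)) {
      px <- cbind(pick[ci, 1] + dx[, 1], pick[ci, 2] + dx[, 2])
      olig2[px] <- stats::runif(nrow(px), 0.75, 1)
      if (is_oligo[ci]) aspa[px] <- stats::runif(nrow(px), 0.75, 1)
    }
  }
  structure(list(channels = list(PLP = plp, LFB = lfb, Iba1 = iba1,
                                 ASPA = aspa, Olig2 = olig2),
                 pixel_size_um = pixel_size_um,
                 lesion_center_px = c((n + 1) / 2, (n + 1) / 2)),
            class = "stain_image_set")
}
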