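#' Normalize a PDw volume to gray-matter signal intensity
#'
#' Rescales a proton density-weighted volume so that mean signal over the
#' gray-matter mask equals 1, the reference scale on which normal-appearing
#' white matter falls in the 0.65--0.75 band and demyelinated lesions are
#' hyperintense.
#'
#' @param pdw 3D numeric array, raw PDw intensities.
#' @param gm_mask logical (or 0/1) array of the same shape marking gray matter.
#' @return Numeric array of the same shape, GM mean = 1.
#' @export
normalize_to_gm <- function(pdw, gm_mask) {
  gm_mask <- as_mask(gm_mask, dim(pdw), "gm_mask")
  if (!any(gm_mask)) stop("gm_mask is empty")
  m <- mean(pdw[gm_mask])
  if (!is.finite(m) || m <= 0) stop("gray-matter mean intensity must be positive, got ", m)
  pdw / m
}

#' Magnetization transfer ratio map
#'
#' Voxelwise MTR = (M0 - MSAT) / M0 from the MT-off (M0) and MT-on (MSAT)
#' acquisitions. Voxels with |M0| <= eps are set to NA (division guard).
#'
#' @param m0 3D numeric array, acquisition without the MT pre-pulse.
#' @param msat 3D numeric array, acquisition with the MT pre-pulse.
#' @param eps positive guard on the denominator.
#' @return Numeric array of MTR values, NA where |M0| <= eps.
#' @export
compute_mtr <- function(m0, msat, eps = 1e-8) {
  if (!identical(dim(m0), dim(msat))) stop("M0 and MSAT grids differ in shape")
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  mtr <- (m0 - msat) / m0
  mtr[abs(m0) <= eps] <- NA_real_
  mtr
}

#' T1 subtraction image
#'
#' Voxelwise subtraction of the pre-gadolinium from the post-gadolinium
#' T1-weighted volume; enhancing tissue appears as positive signal.
#'
#' @param pre,post aligned 3D numeric arrays (T1w before/after contrast).
#' @return post - pre.
#' @export
t1_subtraction <- function(pre, post) {
  if (!identical(dim(pre), dim(post))) stop("pre and post T1 grids differ in shape")
  post - pre
}

#' Detect gadolinium enhancement in a lesion ROI
#'
#' A lesion is called enhancing when its mean T1 subtraction signal exceeds the
#' background mean by more than \code{k_sigma} background standard deviations.
#'
#' @param subtraction 3D numeric array from [t1_subtraction()].
#' @param lesion_mask logical array, the lesion ROI.
#' @param background_mask logical array of reference (non-lesion) tissue.
#' @param k_sigma threshold in background SD units (default 3).
#' @return list with \code{enhancing} (logical) and \code{mean_enhancement}.
#' @export
detect_enhancement <- function(subtraction, lesion_mask, background_mask, k_sigma = 3) {
  lesion_mask <- as_mask(lesion_mask, dim(subtraction), "lesion_mask")
  background_mask <- as_mask(background_mask, dim(subtraction), "background_mask")
  if (!any(lesion_mask)) stop("lesion_mask is empty")
  if (!any(background_mask)) stop("background_mask is empty")
  mu <- mean(subtraction[lesion_mask])
  bg <- subtraction[background_mask]
  thr <- mean(bg) + k_sigma * stats::sd(bg)
  if (is.na(thr)) thr <- mean(bg)  # single-voxel background: SD undefined
  list(enhancing = mu > thr, mean_enhancement = mu)
}

#' Segment hyperintense white-matter lesions on a normalized PDw volume
#'
#' Thresholds the GM-normalized PDw volume inside the white-matter mask and
#' extracts connected components; components smaller than \code{min_voxels}
#' are discarded (lesions below 4 voxels are considered below the detection
#' threshold). Components are relabeled 1..n by decreasing size, ties broken
#' by lexicographic centroid, so labeling is deterministic.
#'
#' @param pdw_norm GM-normalized PDw array (see [normalize_to_gm()]).
#' @param wm_mask logical array restricting the search to white matter.
#' @param intensity_threshold normalized-intensity cutoff (default 0.80, above
#'   the 0.65--0.75 normal-appearing white matter band).
#' @param min_voxels minimum component size kept (default 4).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param gm_mask optional; when given, a warning is raised if the GM mean of
#'   \code{pdw_norm} deviates from 1 by more than 0.05 (input probably not
#'   normalized).
#' @return integer array of the same shape: 0 background, labels 1..n.
#' @export
segment_lesions <- function(pdw_norm, wm_mask, intensity_threshold = 0.80,
                            min_voxels = 4, connectivity = 26, gm_mask = NULL) {
  wm_mask <- as_mask(wm_mask, dim(pdw_norm), "wm_mask")
  if (min_voxels < 1) stop("min_voxels must be >= 1")
  if (!is.null(gm_mask)) {
    gm_mask <- as_mask(gm_mask, dim(pdw_norm), "gm_mask")
    gmean <- mean(pdw_norm[gm_mask])
    if (abs(gmean - 1) > 0.05)
      warning("gray-matter mean is ", signif(gmean, 4),
              "; input does not look GM-normalized")
  }
  fg <- wm_mask & (pdw_norm > intensity_threshold)
  fg[is.na(fg)] <- FALSE
  label_components_3d(fg, connectivity = connectivity, min_voxels = min_voxels)
}

#' Label connected components of a 3D mask
#'
#' Connected-component labeling under 6/18/26-connectivity, with a minimum
#' component size filter and deterministic relabeling (descending size, then
#' lexicographic centroid).
#'
#' @param mask logical 3D array.
#' @param connectivity 6, 18 or 26.
#' @param min_voxels components with fewer voxels are removed.
#' @return integer array; 0 outside components.
#' @export
label_components_3d <- function(mask, connectivity = 26, min_voxels = 1) {
  stopifnot(connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3D array")
  labels <- array(0L, d)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)

  co <- arrayInd(idx, d)
  key <- function(ijk) (ijk[, 1] - 1) + d[1] * ((ijk[, 2] - 1) + d[2] * (ijk[, 3] - 1))
  pos <- key(co)

  offs <- neighbor_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- co
    nb[, 1] <- nb[, 1] + offs[o, 1]
    nb[, 2] <- nb[, 2] + offs[o, 2]
    nb[, 3] <- nb[, 3] + offs[o, 3]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
          nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    hit <- match(key(nb[ok, , drop = FALSE]), pos)
    src <- which(ok)[!is.na(hit)]
    dst <- hit[!is.na(hit)]
    if (length(src)) edges[[o]] <- cbind(src, dst)
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership

  # size filter + deterministic relabeling
  sizes <- tabulate(comp)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0) return(labels)
  cent <- t(vapply(keep, function(k) colMeans(co[comp == k, , drop = FALSE]),
                   numeric(3)))
  ord <- order(-sizes[keep], cent[, 1], cent[, 2], cent[, 3])
  newlab <- integer(length(sizes))
  newlab[keep[ord]] <- seq_along(ord)
  lab <- newlab[comp]
  sel <- lab > 0
  labels[idx[sel]] <- lab[sel]
  labels
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  man <- rowSums(abs(g))
  sel <- switch(as.character(connectivity),
                "6" = man == 1, "18" = man <= 2, "26" = rep(TRUE, nrow(g)))
  g[sel, , drop = FALSE]
}

# Coerce numeric/integer/logical arrays to a logical mask of the expected shape.
as_mask <- function(x, dims, what) {
  if (!identical(dim(x), as.integer(dims)) && !identical(dim(x), dims))
    stop(what, " shape does not match the volume grid")
  x <- x != 0
  x[is.na(x)] <- FALSE
  x
}
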