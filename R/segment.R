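#' Segmentation configuration
#'
#' @param threshold_mode `"global_otsu"` (used for the sphere benchmark) or
#'   `"local_adaptive"` (Table-style sensitivity-factor thresholding used
#'   for embryo stacks).
#' @param sensitivity_factor scalar in `[0,1]`; larger marks more voxels as
#'   foreground (only used by the local adaptive mode).
#' @param local_window odd integer triple, neighbourhood of the local mean.
#'   The default (31, 31, 7) exceeds one nucleus diameter so a nucleus does
#'   not suppress its own threshold.
#' @param min_nuclei_volume components smaller than this many voxels are
#'   discarded from the initial mask.
#' @param nuclei_seed_dilation radius (voxels) of the Euclidean ball used
#'   to dilate and merge nearby local maxima into single markers.
#' @param maxima_window half-width of the cubic window in which a marker
#'   voxel must be a strict maximum.
#' @param min_marker_response noise tolerance of the maxima detector: a
#'   marker voxel must reach this fraction of the maximum-response peak.
#'   Raw regional maxima are fragile under noise -- every super-threshold
#'   background blob owns one -- so, as with h-maxima-style detectors, low
#'   maxima are discarded. 0 disables the filter.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_mode = c("global_otsu",
                                                   "local_adaptive"),
                                sensitivity_factor = 0.5,
                                local_window = c(31L, 31L, 7L),
                                min_nuclei_volume = 20L,
                                nuclei_seed_dilation = 3,
                                maxima_window = 3L,
                                min_marker_response = 0.4) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(sensitivity_factor >= 0, sensitivity_factor <= 1,
            min_nuclei_volume >= 0, nuclei_seed_dilation >= 0,
            maxima_window >= 1, min_marker_response >= 0,
            min_marker_response <= 1)
  structure(list(threshold_mode = threshold_mode,
                 sensitivity_factor = sensitivity_factor,
                 local_window = as.integer(local_window),
                 min_nuclei_volume = as.integer(min_nuclei_volume),
                 nuclei_seed_dilation = nuclei_seed_dilation,
                 maxima_window = as.integer(maxima_window),
                 min_marker_response = min_marker_response),
            class = "segmentation_config")
}

#' Local adaptive threshold
#'
#' Per voxel, `T_local = mean_local * (1 - sensitivity_factor)` where
#' `mean_local` is the mean intensity in the centred neighbourhood
#' (replicate-padded at the borders); a voxel is foreground iff its
#' intensity strictly exceeds its threshold.
#'
#' @param vol numeric 3D array.
#' @param sensitivity_factor scalar in `[0,1]`.
#' @param local_window odd integer triple.
#' @return integer 3D array (1 = foreground).
#' @export
local_adaptive_threshold <- function(vol, sensitivity_factor = 0.5,
                                     local_window = c(31L, 31L, 7L)) {
  assert_volume(vol)
  w <- as.integer(local_window)
  if (any(w %% 2L == 0L)) stop("local_window must be odd in each axis",
                               call. = FALSE)
  d <- dim(vol)
  r <- (w - 1L) %/% 2L
  cx <- pmin(pmax(seq(1 - r[1], d[1] + r[1]), 1L), d[1])
  cy <- pmin(pmax(seq(1 - r[2], d[2] + r[2]), 1L), d[2])
  cz <- pmin(pmax(seq(1 - r[3], d[3] + r[3]), 1L), d[3])
  padded <- vol[cx, cy, cz]
  lm <- array(patch_sums_integral(padded, w) / prod(w), dim = d)
  out <- array(0L, dim = d)
  out[vol > lm * (1 - sensitivity_factor)] <- 1L
  out
}

#' Global Otsu threshold
#'
#' Single threshold maximizing the between-class variance of the 256-bin
#' intensity histogram; foreground is strictly above the threshold.
#'
#' @param vol numeric 3D array with at least two distinct values.
#' @return integer 3D array (1 = foreground) with attribute `threshold`.
#' @export
global_otsu_threshold <- function(vol) {
  assert_volume(vol)
  rng <- range(vol)
  if (rng[1] == rng[2])
    stop("volume is constant; Otsu threshold undefined", call. = FALSE)
  thr <- otsu_threshold_value(as.numeric(vol), 256L)
  out <- array(0L, dim = dim(vol))
  out[vol > thr] <- 1L
  attr(out, "threshold") <- thr
  out
}

# Otsu on an nbins histogram via cumulative moments; returns the threshold
# value (upper edge of the chosen bin).
otsu_threshold_value <- function(x, nbins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L),
              nbins)
  cnt <- tabulate(bin, nbins)
  p <- cnt / sum(cnt)
  centers <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[nbins]
  t_cand <- seq_len(nbins - 1L)
  w0c <- w0[t_cand]
  varb <- (mu_t * w0c - mu[t_cand])^2 / (w0c * (1 - w0c))
  varb[!is.finite(varb)] <- -Inf
  best <- which.max(varb)
  edges[best + 1L]
}

#' Remove small foreground components
#'
#' Connected components (26-connectivity) of the binary mask smaller than
#' `min_nuclei_volume` voxels are discarded -- the denoised background can
#' still contain specks well below the smallest credible nucleus.
#'
#' @param mask integer/logical 3D array (nonzero = foreground).
#' @param min_nuclei_volume minimum component size in voxels.
#' @return integer binary 3D array.
#' @export
filter_min_volume <- function(mask, min_nuclei_volume) {
  stopifnot(length(dim(mask)) == 3L)
  if (min_nuclei_volume <= 0) {
    out <- array(as.integer(mask != 0), dim = dim(mask))
    return(out)
  }
  lab <- cpp_label3d(as.integer(mask != 0), as.integer(dim(mask)))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_nuclei_volume)
  out <- array(0L, dim = dim(mask))
  out[lab %in% keep & lab > 0] <- 1L
  out
}

#' Detect watershed markers from the maximum-response image
#'
#' Strict local maxima of the maximum-response image within a cubic window
#' (half-width `maxima_window`; equal-valued plateaus keep their smallest
#' linear-index voxel) are kept only inside the segmentation mask, then
#' dilated by a Euclidean ball of radius `nuclei_seed_dilation`; dilations
#' that overlap merge into a single marker, which is what prevents several
#' maxima inside one nucleus from over-segmenting it.
#'
#' @param max_resp numeric 3D array (see [max_response()]).
#' @param mask binary 3D array (initial segmentation mask).
#' @param cfg a [segmentation_config()].
#' @return object of class `marker_set`: `markers` (labelled 3D array),
#'   `centers` (0-based centroids) and `n`.
#' @export
detect_markers <- function(max_resp, mask, cfg = segmentation_config()) {
  assert_volume(max_resp, "max_resp")
  if (!identical(dim(max_resp), dim(mask)))
    stop("max_resp and mask have different shapes", call. = FALSE)
  d <- as.integer(dim(max_resp))
  idx <- cpp_local_maxima(max_resp, d, cfg$maxima_window)
  idx <- idx[mask[idx] != 0]
  if (cfg$min_marker_response > 0 && length(idx)) {
    floor_val <- cfg$min_marker_response * max(max_resp[mask != 0])
    idx <- idx[max_resp[idx] >= floor_val]
  }
  if (length(idx) == 0) {
    return(structure(list(markers = array(0L, dim = d),
                          centers = matrix(numeric(0), 0, 3,
                                           dimnames = list(NULL,
                                                           c("x", "y", "z"))),
                          n = 0L), class = "marker_set"))
  }
  dil <- cpp_dilate_points(d, as.integer(idx), cfg$nuclei_seed_dilation)
  lab <- array(cpp_label3d(dil, d), dim = d)
  lab[mask == 0] <- 0L  # markers never extend outside the mask
  ids <- sort(unique(lab[lab > 0]))
  relab <- array(0L, dim = d)
  centers <- matrix(NA_real_, length(ids), 3,
                    dimnames = list(NULL, c("x", "y", "z")))
  for (t in seq_along(ids)) {
    w <- which(lab == ids[t])
    relab[w] <- t
    centers[t, ] <- colMeans(arrayInd(w, d) - 1L)
  }
  structure(list(markers = relab, centers = centers, n = length(ids)),
            class = "marker_set")
}

#' 3D marker-controlled watershed
#'
#' Floods the masked denoised image from the marker components, descending
#' from bright to dim (elevation is `max - intensity` inside the mask);
#' voxels keep the label of the flood that reaches them first, so implicit
#' dams are built where floods from different markers meet. Background
#' (mask zero) is never labelled, and each output label contains exactly
#' one marker component.
#'
#' @param denoised numeric 3D array.
#' @param mask binary 3D array.
#' @param markers a `marker_set` (or labelled 3D array).
#' @return integer labelled 3D array.
#' @export
watershed_segment <- function(denoised, mask, markers) {
  assert_volume(denoised, "denoised")
  mk <- if (inherits(markers, "marker_set")) markers$markers else markers
  if (!identical(dim(denoised), dim(mask)) ||
      !identical(dim(denoised), dim(mk)))
    stop("denoised, mask and markers must share one shape", call. = FALSE)
  d <- as.integer(dim(denoised))
  masked <- denoised
  masked[mask == 0] <- 0
  elev <- max(masked) - masked
  lab <- cpp_watershed(as.numeric(elev), as.integer(mask != 0),
                       as.integer(mk), d)
  array(lab, dim = d)
}

#' Full denoising + segmentation pipeline
#'
#' Orchestrates: K-SVD denoising, detection map, maximum response, initial
#' threshold (global Otsu or local adaptive on the denoised volume),
#' minimum-volume filtering, marker detection and marker-controlled
#' watershed. Deterministic given the learning-config seed.
#'
#' @param vol raw numeric 3D array.
#' @param psz a [patch_spec()].
#' @param learning a [learning_config()].
#' @param seg a [segmentation_config()].
#' @param lambda blending weight of [denoise_volume()].
#' @param mean_nucleus_volume optional prior mean nucleus volume (voxels);
#'   when supplied, a patch volume outside 25--100% of it triggers a
#'   guideline warning (robust detection wants the patch inside that band).
#' @param keep_intermediates keep the denoised volume, detection map,
#'   maximum response and mask in the result.
#' @return object of class `nuclei_segmentation`: `labels`, `markers`,
#'   `centroids` (data.frame id, x, y, z, volume_voxels; 0-based), `n`,
#'   `dict`, `objective_trace`, configs, and intermediates if requested.
#' @export
segment_pipeline <- function(vol, psz = patch_spec(),
                             learning = learning_config(),
                             seg = segmentation_config(), lambda = 0,
                             mean_nucleus_volume = NULL,
                             keep_intermediates = FALSE) {
  psz <- patch_spec(psz)
  guideline <- NULL
  if (!is.null(mean_nucleus_volume)) {
    guideline <- patch_size_guideline(psz, mean_nucleus_volume)
    if (!guideline$in_band)
      warning(sprintf(
        "patch volume %d voxels is %.0f%% of the mean nucleus volume; robust detection wants 25--100%%",
        patch_dim(psz), 100 * guideline$fraction), call. = FALSE)
  }
  den <- denoise_volume(vol, psz, learning, lambda = lambda)
  dm <- detection_map(den)
  mr <- max_response(den$denoised, dm)
  mask <- switch(seg$threshold_mode,
                 global_otsu = global_otsu_threshold(den$denoised),
                 local_adaptive = local_adaptive_threshold(
                   den$denoised, seg$sensitivity_factor, seg$local_window))
  mask <- filter_min_volume(mask, seg$min_nuclei_volume)
  mk <- detect_markers(mr, mask, seg)
  labels <- watershed_segment(den$denoised, mask, mk)
  cent <- label_centroids(labels)
  out <- list(labels = labels, markers = mk, centroids = cent,
              n = nrow(cent), dict = den$dict,
              objective_trace = den$objective_trace, psz = psz,
              learning = learning, seg = seg, lambda = lambda,
              guideline = guideline)
  if (keep_intermediates) {
    out$denoised <- den$denoised
    out$detection_map <- dm
    out$max_response <- mr
    out$mask <- mask
    out$scores <- den$scores
  }
  structure(out, class = "nuclei_segmentation")
}

#' Centroid table of a label volume
#'
#' @param labels integer 3D array.
#' @return data.frame with id, x, y, z (0-based voxel centroids) and
#'   volume_voxels.
#' @export
label_centroids <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  out <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                    z = numeric(0), volume_voxels = integer(0))
  for (t in seq_along(ids)) {
    w <- which(labels == ids[t])
    sub <- arrayInd(w, dim(labels)) - 1L
    out[t, ] <- list(as.integer(ids[t]), mean(sub[, 1]), mean(sub[, 2]),
                     mean(sub[, 3]), length(w))
  }
  out
}

#' Patch-size guideline check
#'
#' Robust detection wants the patch volume between 25% and 100% of the
#' mean nucleus volume: much smaller patches under-constrain the sparse
#' code at low SNR (spurious detections), much larger ones straddle
#' neighbouring nuclei (missed detections).
#'
#' @param psz a [patch_spec()].
#' @param mean_nucleus_volume mean nucleus volume in voxels.
#' @return list with `fraction` (patch volume / mean nucleus volume) and
#'   `in_band`.
#' @export
patch_size_guideline <- function(psz, mean_nucleus_volume) {
  f <- patch_dim(patch_spec(psz)) / mean_nucleus_volume
  list(fraction = f, in_band = f >= 0.25 && f <= 1)
}
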