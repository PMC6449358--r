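#' Read a multi-page TIFF z-stack
#'
#' Pages become z-slices in page order; intensities are preserved exactly
#' (integer stacks are read as integer counts, float stacks as-is).
#' Multi-channel / RGB input is rejected.
#'
#' @param path path to a single-channel multi-page TIFF.
#' @return numeric 3D array (X, Y, Z) with attributes `bits_per_sample`.
#' @export
read_volume <- function(path) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side))
    jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  scaled <- identical(meta$encoding, "scaled32")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = !scaled, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop("multi-channel / RGB TIFF input is not supported", call. = FALSE)
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) !identical(dim(p), d1), logical(1))))
    stop("TIFF pages have inconsistent sizes", call. = FALSE)
  vol <- array(0, dim = c(d1[2], d1[1], length(pages)))
  for (k in seq_along(pages)) vol[, , k] <- t(pages[[k]])
  if (scaled) {
    # undo the affine intensity map of scaled 32-bit storage
    vol <- vol * (meta$hi - meta$lo) + meta$lo
  }
  vol
}

#' Write a volume as a multi-page TIFF
#'
#' `uint8`/`uint16` store rounded nonnegative integers losslessly up to
#' their ranges; `float32` stores arbitrary intensities (required for
#' calibrated noisy volumes whose values go below zero).
#'
#' @param vol numeric 3D array (X, Y, Z).
#' @param path output path.
#' @param dtype one of "float32", "uint16", "uint8".
#' @return the path, invisibly.
#' @export
write_volume <- function(vol, path, dtype = c("float32", "uint16", "uint8")) {
  assert_volume(vol)
  dtype <- match.arg(dtype)
  d <- dim(vol)
  pages <- vector("list", d[3])
  if (dtype == "float32") {
    # arbitrary intensities (incl. negatives) as range-scaled 32-bit
    # samples plus a JSON sidecar holding the affine intensity map
    lo <- min(vol)
    hi <- max(vol)
    den <- if (hi > lo) hi - lo else 1
    for (k in seq_len(d[3])) pages[[k]] <- t((vol[, , k] - lo) / den)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(list(encoding = "scaled32", lo = lo, hi = hi),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  } else {
    mx <- if (dtype == "uint16") 65535 else 255
    if (min(vol) < 0 || max(vol) > mx)
      stop(sprintf("values outside [0, %d]; use dtype = 'float32'", mx),
           call. = FALSE)
    for (k in seq_len(d[3])) pages[[k]] <- t(round(vol[, , k])) / mx
    tiff::writeTIFF(pages, path,
                    bits.per.sample = if (dtype == "uint16") 16L else 8L,
                    reduce = FALSE)
  }
  invisible(path)
}

#' Write a label volume (16-bit, promoted to float when overflowing)
#'
#' @param labels integer 3D array.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) {
    warning("more than 65535 labels; writing 32-bit float label TIFF")
    return(write_volume(labels * 1.0, path, dtype = "float32"))
  }
  write_volume(labels * 1.0, path, dtype = "uint16")
}

#' Read a label volume written by [write_labels()]
#' @param path path to the label TIFF.
#' @return integer 3D array.
#' @export
read_labels <- function(path) {
  v <- read_volume(path)
  array(as.integer(round(v)), dim = dim(v))
}

#' Write / read an object-centroid CSV
#'
#' Columns id, x, y, z, volume_voxels; coordinates are 0-based voxel
#' positions (x, y, z with z the TIFF page index), stated in a header
#' comment.
#'
#' @param x a `nuclei_gt`, a `nuclei_segmentation` or a centroid
#'   data.frame.
#' @param path output path.
#' @return the path (write) or a data.frame (read).
#' @export
write_centroids_csv <- function(x, path) {
  df <- if (inherits(x, "nuclei_gt")) {
    data.frame(id = x$ids, x = x$centroids[, 1], y = x$centroids[, 2],
               z = x$centroids[, 3], volume_voxels = x$volumes)
  } else if (inherits(x, "nuclei_segmentation")) {
    x$centroids
  } else {
    x
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# 0-based voxel coordinates (x,y,z); z = TIFF page index",
             con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids_csv
#' @export
read_centroids_csv <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Run the full workflow from a configuration
#'
#' Configuration keys mirror the parameter-table names: `patch_size`,
#' `dictionary_size`, `iterations`, `sparsity`, `threshold_mode`,
#' `sensitivity_factor`, `min_nuclei_volume`, `nuclei_seed_dilation`, plus
#' `input` (TIFF path) or `simulate` (list with `snr_db`, optional `shape`,
#' `radii` ignored in favour of the default layout), optional `ground_truth`
#' (label TIFF or centroid CSV), `seed`, `lambda`, `outdir`. Writes the
#' segmentation outputs and a JSON run manifest sufficient to reproduce the
#' run, and returns the manifest invisibly.
#'
#' @param config named list or path to a YAML file.
#' @return manifest list, invisibly.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  req <- c("patch_size")
  miss <- setdiff(req, names(config))
  if (length(miss))
    stop("missing required config key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cfg <- modifyList(list(dictionary_size = 64L, iterations = 15L,
                         sparsity = 3L, threshold_mode = "global_otsu",
                         sensitivity_factor = 0.5,
                         min_nuclei_volume = 20L, nuclei_seed_dilation = 3,
                         maxima_window = 3L, seed = 1L, lambda = 0,
                         max_train = 20000L, outdir = "."), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(parameters = cfg[c("patch_size", "dictionary_size",
                                      "iterations", "sparsity",
                                      "threshold_mode", "sensitivity_factor",
                                      "min_nuclei_volume",
                                      "nuclei_seed_dilation", "maxima_window",
                                      "seed", "lambda", "max_train")],
                   version = as.character(utils::packageVersion("sparsenuclei")),
                   stages = list())
  t_all <- proc.time()[3]
  gt <- NULL
  if (!is.null(cfg$simulate)) {
    t0 <- proc.time()[3]
    suite <- make_benchmark_suite(seed = cfg$seed,
                                  snr_db = cfg$simulate$snr_db[1])
    vol <- suite[[1]]$volume
    gt <- suite[[1]]$gt
    manifest$input <- list(simulated = TRUE,
                           snr_db = cfg$simulate$snr_db[1],
                           snr_measured = suite[[1]]$snr_measured)
    manifest$stages$simulate <- list(seconds = proc.time()[3] - t0)
  } else {
    if (is.null(cfg$input)) stop("config needs `input` or `simulate`",
                                 call. = FALSE)
    vol <- read_volume(cfg$input)
    manifest$input <- list(path = cfg$input, shape = dim(vol))
    if (!is.null(cfg$ground_truth)) {
      gt <- if (grepl("\\.csv$", cfg$ground_truth))
        read_centroids_csv(cfg$ground_truth)
      else ground_truth_from_labels(read_labels(cfg$ground_truth))
    }
  }
  t0 <- proc.time()[3]
  res <- segment_pipeline(
    vol, psz = patch_spec(cfg$patch_size),
    learning = learning_config(K = cfg$dictionary_size, L = cfg$sparsity,
                               n_iter = cfg$iterations, seed = cfg$seed,
                               max_train = cfg$max_train),
    seg = segmentation_config(threshold_mode = cfg$threshold_mode,
                              sensitivity_factor = cfg$sensitivity_factor,
                              min_nuclei_volume = cfg$min_nuclei_volume,
                              nuclei_seed_dilation = cfg$nuclei_seed_dilation,
                              maxima_window = cfg$maxima_window),
    lambda = cfg$lambda, keep_intermediates = isTRUE(cfg$save_intermediates))
  manifest$stages$segment <- list(seconds = proc.time()[3] - t0,
                                  objects = res$n)
  write_labels(res$labels, file.path(cfg$outdir, "labels.tif"))
  write_centroids_csv(res, file.path(cfg$outdir, "centroids.csv"))
  if (isTRUE(cfg$save_intermediates)) {
    write_volume(res$denoised, file.path(cfg$outdir, "denoised.tif"),
                 dtype = "float32")
    write_volume(res$detection_map$map,
                 file.path(cfg$outdir, "detection_map.tif"),
                 dtype = "float32")
    write_volume(res$max_response,
                 file.path(cfg$outdir, "max_response.tif"),
                 dtype = "float32")
  }
  if (!is.null(gt)) {
    t0 <- proc.time()[3]
    ev <- if (inherits(gt, "nuclei_gt")) evaluate_segmentation(res, gt)
    else evaluate_segmentation(res, gt, gate_radius = cfg$gate_radius %||%
                                 mean((3 * gt$volume_voxels / (4 * pi))^(1 / 3)))
    report <- ev[c("TP", "FN", "FP", "recall", "precision", "f_measure",
                   "jaccard_mean", "gate_radius")]
    jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    manifest$stages$evaluate <- c(list(seconds = proc.time()[3] - t0),
                                  report)
  }
  manifest$total_seconds <- proc.time()[3] - t_all
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
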