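#' Specify a 3D patch size
#'
#' Patches are small (typically anisotropic) boxes, in-plane size `n_xy`
#' and axial depth `n_z` voxels, matching the anisotropy of confocal
#' stacks. A patch should hold a substantial fraction of one nucleus: the
#' working band is 25--100% of the mean nucleus volume.
#'
#' @param size integer triple (Nx, Ny, Mz); or give `n_xy`/`n_z`.
#' @param n_xy in-plane size (used when `size` is missing).
#' @param n_z axial size.
#' @return integer triple of class `patch_spec`.
#' @export
patch_spec <- function(size = NULL, n_xy = 15L, n_z = 5L) {
  if (is.null(size)) size <- c(n_xy, n_xy, n_z)
  size <- as.integer(size)
  stopifnot(length(size) == 3L, size[1] >= 2L, size[2] >= 2L, size[3] >= 1L)
  structure(size, class = "patch_spec")
}

patch_dim <- function(psz) prod(as.integer(psz))

# Full-grid patch origins (0-based corners) in raster order, x fastest.
patch_origins <- function(dims, psz) {
  nd <- dims - as.integer(psz) + 1L
  if (any(nd < 1L))
    stop("patch is larger than the volume in at least one axis",
         call. = FALSE)
  g <- expand.grid(x = 0:(nd[1] - 1L), y = 0:(nd[2] - 1L),
                   z = 0:(nd[3] - 1L), KEEP.OUT.ATTRS = FALSE)
  as.matrix(g)
}

#' Extract all overlapping patches with unit stride
#'
#' Enumerates every fully interior patch in deterministic raster order
#' (x fastest, then y, then z). With `materialize = FALSE` the (n x m)
#' patch matrix is not built; columns are extracted on demand through
#' [patch_data()], which keeps full-volume processing within memory while
#' behaving exactly like the materialized set.
#'
#' @param vol numeric 3D array.
#' @param psz a [patch_spec()].
#' @param materialize build the dense patch matrix now?
#' @return object of class `patch_set` with fields `origins` (m x 3,
#'   0-based), `psz`, `shape`, and `data` (n x m matrix or NULL).
#' @export
extract_patches <- function(vol, psz, materialize = TRUE) {
  assert_volume(vol)
  psz <- patch_spec(psz)
  origins <- patch_origins(dim(vol), psz)
  ps <- structure(list(origins = origins, psz = psz, shape = dim(vol),
                       data = NULL, vol = vol),
                  class = "patch_set")
  if (materialize) {
    ps$data <- cpp_extract_patches(vol, dim(vol), as.integer(psz),
                                   origins_int(origins))
    ps$vol <- NULL
  }
  ps
}

origins_int <- function(origins) {
  storage.mode(origins) <- "integer"
  origins
}

#' Number of patches in a patch set
#' @param ps a `patch_set`.
#' @return integer patch count m.
#' @export
n_patches <- function(ps) nrow(ps$origins)

#' Retrieve (a subset of) the vectorized patches
#'
#' @param ps a `patch_set`.
#' @param cols optional column indices; default all.
#' @return numeric matrix with one vectorized patch per column.
#' @export
patch_data <- function(ps, cols = NULL) {
  if (!is.null(ps$data))
    return(if (is.null(cols)) ps$data else ps$data[, cols, drop = FALSE])
  org <- if (is.null(cols)) ps$origins else ps$origins[cols, , drop = FALSE]
  cpp_extract_patches(ps$vol, ps$shape, as.integer(ps$psz), origins_int(org))
}

#' Per-patch intensity sums and their global average
#'
#' The per-patch sums and their mean feed the dictionary initialization:
#' only patches whose summed intensity exceeds the global average are
#' eligible as initial atoms, which biases the initial dictionary towards
#' nucleus-containing patches.
#'
#' @param ps a `patch_set`.
#' @return list with `per_patch_sums` (length m) and `global_average`.
#' @export
mean_patch_intensity <- function(ps) {
  stopifnot(inherits(ps, "patch_set"), n_patches(ps) >= 1)
  if (!is.null(ps$data)) {
    s <- colSums(ps$data)
  } else {
    s <- patch_sums_integral(ps$vol, as.integer(ps$psz))
  }
  list(per_patch_sums = as.numeric(s), global_average = mean(s))
}

# Per-patch sums for the full raster grid via a 3D summed-area table.
patch_sums_integral <- function(vol, psz) {
  d <- dim(vol)
  ii <- vol
  ii <- apply(ii, c(2, 3), cumsum)
  dim(ii) <- d
  ii <- aperm(apply(ii, c(1, 3), cumsum), c(2, 1, 3))
  ii <- aperm(apply(ii, c(1, 2), cumsum), c(2, 3, 1))
  pad <- array(0, d + 1L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- ii
  nd <- d - psz + 1L
  x0 <- 1:nd[1]; y0 <- 1:nd[2]; z0 <- 1:nd[3]
  x1 <- x0 + psz[1]; y1 <- y0 + psz[2]; z1 <- z0 + psz[3]
  s <- pad[x1, y1, z1] - pad[x0, y1, z1] - pad[x1, y0, z1] - pad[x1, y1, z0] +
    pad[x0, y0, z1] + pad[x0, y1, z0] + pad[x1, y0, z0] - pad[x0, y0, z0]
  as.numeric(s)
}

#' Reassemble a volume from per-patch reconstructions
#'
#' Each voxel becomes the unweighted average of all patch reconstructions
#' covering it; `coverage` counts the contributors. With full unit-stride
#' interior extraction every voxel is covered at least once; for subsampled
#' patch sets uncovered voxels fall back to `fallback` (e.g. the raw
#' volume) and are flagged by `coverage == 0`.
#'
#' @param ps_recon a `patch_set` whose `data` holds reconstructed patches
#'   (or a list with `data`, `origins`, `psz`).
#' @param shape integer triple of the output volume.
#' @param fallback optional volume supplying uncovered voxels.
#' @return list with `volume` and `coverage` (both 3D arrays).
#' @export
reassemble_patches <- function(ps_recon, shape, fallback = NULL) {
  data <- if (!is.null(ps_recon$data)) ps_recon$data else patch_data(ps_recon)
  org <- ps_recon$origins
  psz <- as.integer(ps_recon$psz)
  shape <- as.integer(shape)
  if (any(org < 0) || any(t(org) + psz > shape))
    stop("patch origins inconsistent with target shape", call. = FALSE)
  acc <- cpp_accumulate_patches(data, origins_int(org), psz, shape)
  cov <- array(acc$coverage, dim = shape)
  out <- array(acc$sum, dim = shape)
  hit <- cov > 0
  out[hit] <- out[hit] / cov[hit]
  if (any(!hit)) {
    if (!is.null(fallback)) out[!hit] <- fallback[!hit] else out[!hit] <- 0
  }
  list(volume = out, coverage = cov)
}
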