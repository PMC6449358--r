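#' Denoise a volume by sparse patch reconstruction
#'
#' Learns (or reuses) a patch dictionary, OMP-encodes every unit-stride
#' patch of the volume and averages the overlapping reconstructions. The
#' output solves, voxel-wise, the blending problem
#' `argmin_X lambda ||X - Y||^2 + sum_i ||R_i X - D alpha_i||^2`, whose
#' closed form is `X = (lambda Y + sum_i R_i' D alpha_i) / (lambda + c)`
#' with `c` the per-voxel patch coverage. `lambda = 0` (the default) gives
#' the pure sparse reconstruction; `lambda -> Inf` returns the input.
#' The result is clipped to the intensity range of the input.
#'
#' @param vol numeric 3D array (the noisy volume `Y`).
#' @param psz a [patch_spec()].
#' @param cfg a [learning_config()].
#' @param lambda nonnegative blending weight towards the raw input.
#' @param dict optional pre-learned `nuclei_dictionary` (skips learning).
#' @param keep_code return the full sparse code (needed only if the caller
#'   wants per-patch coefficient access; per-patch scores are always kept).
#' @param chunk number of patches encoded per block.
#' @return list of class `denoise_result`: `denoised`, `dict`,
#'   `objective_trace`, `scores` (per-patch sums of |alpha|), `origins`,
#'   `coverage`, `psz` and (optionally) `code`.
#' @export
denoise_volume <- function(vol, psz = patch_spec(), cfg = learning_config(),
                           lambda = 0, dict = NULL, keep_code = FALSE,
                           chunk = 4096L) {
  assert_volume(vol)
  psz <- patch_spec(psz)
  stopifnot(lambda >= 0)
  trace <- NULL
  if (is.null(dict)) {
    ps <- extract_patches(vol, psz, materialize = FALSE)
    fit <- ksvd_learn(ps, cfg)
    dict <- fit$dict
    trace <- fit$objective_trace
  }
  stopifnot(dict$n == patch_dim(psz))
  enc <- cpp_encode_volume(vol, dim(vol), as.integer(psz), dict$atoms,
                           cfg$L, cfg$tol, as.integer(chunk), keep_code)
  cov <- array(enc$coverage, dim = dim(vol))
  if (is.infinite(lambda)) {
    X <- vol
  } else {
    X <- array((lambda * vol + enc$sum) / (lambda + cov), dim = dim(vol))
  }
  rng <- range(vol)
  X[X < rng[1]] <- rng[1]
  X[X > rng[2]] <- rng[2]
  origins <- patch_origins(dim(vol), psz)
  code <- NULL
  if (keep_code) {
    m <- nrow(origins)
    code <- code_from_triplets(list(i = enc$i, j = enc$j, x = enc$x,
                                    residual = NULL, score = enc$score),
                               dict$K, m, cfg$L)
  }
  structure(list(denoised = X, dict = dict, objective_trace = trace,
                 scores = as.numeric(enc$score), origins = origins,
                 coverage = cov, psz = psz, lambda = lambda, code = code),
            class = "denoise_result")
}

#' Build the nuclei detection map from sparse-code scores
#'
#' Each patch contributes the sum of the absolute values of its sparse
#' coefficients; every voxel averages the contributions of all patches
#' covering it and the result is divided by its global maximum, giving a
#' probability-like map in `[0, 1]` that peaks near nucleus centres
#' (bright structured patches need large coefficients, background patches
#' need almost none).
#'
#' @param scores per-patch coefficient-magnitude sums, or a `sparse_code`
#'   (column sums of `|alpha|` are used), or a `denoise_result`.
#' @param origins m x 3 matrix of 0-based patch origins (taken from
#'   `scores` when it is a `denoise_result`).
#' @param shape output volume shape.
#' @param psz the [patch_spec()] used at extraction.
#' @return object of class `detection_map`: `map` (3D array in `[0,1]`),
#'   `normalizer` (the global maximum `C`) and `degenerate` (TRUE when all
#'   coefficients were zero).
#' @export
detection_map <- function(scores, origins = NULL, shape = NULL, psz = NULL) {
  if (inherits(scores, "denoise_result")) {
    origins <- scores$origins
    shape <- dim(scores$denoised)
    psz <- scores$psz
    scores <- scores$scores
  } else if (inherits(scores, "sparse_code")) {
    scores <- Matrix::colSums(abs(scores$coeffs))
  }
  stopifnot(!is.null(origins), !is.null(shape), !is.null(psz))
  acc <- cpp_accumulate_scalar(as.numeric(scores), origins_int(origins),
                               as.integer(patch_spec(psz)),
                               as.integer(shape))
  cov <- acc$coverage
  s <- acc$sum
  hit <- cov > 0
  s[hit] <- s[hit] / cov[hit]
  C <- max(s)
  degenerate <- !(C > 0)
  if (!degenerate) s <- s / C
  structure(list(map = array(s, dim = shape), normalizer = C,
                 degenerate = degenerate),
            class = "detection_map")
}

#' Maximum-response image
#'
#' Voxel-wise product of the denoised volume and the detection map; the
#' surface whose local maxima seed the watershed.
#'
#' @param denoised numeric 3D array.
#' @param dm a [detection_map()] (or a plain array in `[0,1]`).
#' @return numeric 3D array.
#' @export
max_response <- function(denoised, dm) {
  assert_volume(denoised, "denoised")
  m <- if (inherits(dm, "detection_map")) dm$map else dm
  if (!identical(dim(denoised), dim(m)))
    stop("denoised volume and detection map have different shapes",
         call. = FALSE)
  denoised * m
}
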