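#' @export
print.sphere_phantom_spec <- function(x, ...) {
  cat(sprintf("sphere phantom %d x %d x %d, %d sphere(s), background %g\n",
              x$shape[1], x$shape[2], x$shape[3], nrow(x$spheres),
              x$background_level))
  invisible(x)
}

#' @export
print.nuclei_gt <- function(x, ...) {
  cat(sprintf("ground truth: %d object(s), %s voxels\n", length(x$ids),
              paste(x$volumes, collapse = "/")))
  invisible(x)
}

#' @export
print.nuclei_dictionary <- function(x, ...) {
  cat(sprintf("dictionary: %d atoms of dimension %d (unit-norm)\n",
              x$K, x$n))
  invisible(x)
}

#' @export
print.sparse_code <- function(x, ...) {
  cat(sprintf("sparse code: %d x %d, %d nonzeros (L = %d)\n",
              nrow(x$coeffs), ncol(x$coeffs), Matrix::nnzero(x$coeffs),
              x$L))
  invisible(x)
}

#' @export
print.nuclei_segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d object(s); patch %s, K = %d, L = %d\n",
              x$n, paste(x$psz, collapse = "x"), x$learning$K,
              x$learning$L))
  if (x$n > 0) print(x$centroids)
  invisible(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("TP %d  FN %d  FP %d\n", x$TP, x$FN, x$FP))
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf("recall %s%%  precision %s%%  F %s%%", fmt(x$recall),
              fmt(x$precision), fmt(x$f_measure)))
  if (!is.null(x$jaccard_mean) && !is.na(x$jaccard_mean))
    cat(sprintf("  mean Jaccard %.3f", x$jaccard_mean))
  cat("\n")
  invisible(x)
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("marker set: %d component(s)\n", x$n))
  invisible(x)
}
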