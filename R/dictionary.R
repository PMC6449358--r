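#' Dictionary-learning configuration
#'
#' Defaults follow the all-dataset setting used throughout: `K = 64` atoms,
#' sparsity `L = 3`, `n_iter = 15` update iterations. `max_train` caps the
#' number of (seeded, uniformly subsampled) training patches handed to the
#' learning loop; encoding for reconstruction always uses all patches.
#'
#' @param K number of dictionary atoms.
#' @param L sparsity level (maximum atoms per patch).
#' @param n_iter number of K-SVD iterations.
#' @param seed integer seed (initial atom draw + training subsample).
#' @param max_train training-set cap in patches.
#' @param tol relative OMP residual tolerance (stop when the residual falls
#'   below `tol * ||y||`).
#' @return object of class `learning_config`.
#' @export
learning_config <- function(K = 64L, L = 3L, n_iter = 15L, seed = 1L,
                            max_train = 20000L, tol = 1e-6,
                            train_pool = c("uniform", "bright")) {
  K <- as.integer(K); L <- as.integer(L); n_iter <- as.integer(n_iter)
  train_pool <- match.arg(train_pool)
  stopifnot(L >= 1L, K >= L, n_iter >= 1L, max_train >= 1L, tol >= 0)
  structure(list(K = K, L = L, n_iter = n_iter, seed = as.integer(seed),
                 max_train = as.integer(max_train), tol = tol,
                 train_pool = train_pool),
            class = "learning_config")
}

new_dictionary <- function(atoms, provenance = list()) {
  structure(list(atoms = atoms, K = ncol(atoms), n = nrow(atoms),
                 provenance = provenance),
            class = "nuclei_dictionary")
}

#' Initialize a dictionary from bright patches
#'
#' Atoms are drawn uniformly at random (seeded) from the patches whose
#' summed intensity strictly exceeds the global average patch intensity --
#' this biases the initial dictionary towards nucleus-containing patches.
#' If fewer than `K` patches qualify, the top-`K` patches by intensity sum
#' are used instead (with a warning). Every atom is scaled to unit
#' Euclidean norm.
#'
#' @param ps a `patch_set`.
#' @param cfg a [learning_config()].
#' @return a `nuclei_dictionary` with `K` unit-norm atoms.
#' @export
init_dictionary <- function(ps, cfg) {
  stopifnot(inherits(ps, "patch_set"), inherits(cfg, "learning_config"))
  mi <- mean_patch_intensity(ps)
  sums <- mi$per_patch_sums
  eligible <- which(sums > mi$global_average)
  if (length(eligible) >= cfg$K) {
    sel <- with_seed(cfg$seed, sample(eligible, cfg$K))
  } else {
    warning(sprintf(
      "only %d patches exceed the average intensity; using top-%d by sum",
      length(eligible), cfg$K))
    sel <- order(sums, decreasing = TRUE)[seq_len(min(cfg$K, length(sums)))]
  }
  atoms <- patch_data(ps, sel)
  nrm <- sqrt(colSums(atoms^2))
  bad <- nrm == 0
  if (any(bad)) {
    # replace zero-norm picks by the largest-sum patches not yet selected
    pool <- setdiff(order(sums, decreasing = TRUE), sel)
    repl <- pool[seq_len(sum(bad))]
    atoms[, bad] <- patch_data(ps, repl)
    sel[bad] <- repl
    nrm <- sqrt(colSums(atoms^2))
    if (any(nrm == 0)) stop("cannot build a dictionary from an all-zero volume",
                            call. = FALSE)
  }
  atoms <- sweep(atoms, 2, nrm, "/")
  new_dictionary(atoms, provenance = list(seed = cfg$seed,
                                          source_indices = sel))
}

code_from_triplets <- function(tri, K, m, L) {
  coeffs <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                 dims = c(K, m))
  structure(list(coeffs = coeffs, L = L, residual = tri$residual,
                 score = tri$score), class = "sparse_code")
}

#' Sparse-code signals against a dictionary with OMP
#'
#' Orthogonal matching pursuit per signal: greedily add the atom with the
#' largest absolute correlation with the current residual (ties broken
#' towards the lowest atom index), refit all selected coefficients by least
#' squares, and stop after `L` atoms or once the residual norm drops below
#' `tol * ||y||`. The refit leaves the residual orthogonal to the span of
#' the selected atoms. Zero signals get an empty support.
#'
#' @param dict a `nuclei_dictionary` (unit-norm atoms).
#' @param signals a `patch_set` or a numeric matrix with one signal per
#'   column.
#' @param L sparsity level.
#' @param tol relative residual tolerance.
#' @return object of class `sparse_code`: `coeffs` (sparse K x m matrix),
#'   `residual` (per-signal residual norms) and `score` (per-signal sums of
#'   absolute coefficients, the detection-map ingredient).
#' @export
omp_encode <- function(dict, signals, L, tol = 1e-6) {
  stopifnot(inherits(dict, "nuclei_dictionary"))
  Y <- if (inherits(signals, "patch_set")) patch_data(signals) else
    as.matrix(signals)
  stopifnot(nrow(Y) == dict$n)
  tri <- cpp_batch_omp(dict$atoms, Y, as.integer(L), tol,
                       integer(0), integer(0), numeric(0))
  code_from_triplets(tri, dict$K, ncol(Y), L)
}

#' One K-SVD dictionary-update pass
#'
#' Updates atoms one at a time: for atom k, the residual matrix restricted
#' to the signals using that atom (with atom k's own contribution added
#' back) is approximated by its leading singular pair, which becomes the
#' new atom and its coefficient row. The SVD sign ambiguity is resolved by
#' forcing a nonnegative sum on each updated atom. Atoms used by no signal
#' are replaced by the currently worst-represented signal (normalized).
#'
#' @param dict a `nuclei_dictionary`.
#' @param signals numeric matrix (one signal per column).
#' @param code a `sparse_code` consistent with `dict` and `signals`.
#' @return list with the updated `dict` and `code`.
#' @export
ksvd_update <- function(dict, signals, code) {
  stopifnot(inherits(dict, "nuclei_dictionary"),
            inherits(code, "sparse_code"))
  tri <- code_triplets(code)
  upd <- cpp_ksvd_update(dict$atoms, signals, tri$i, tri$j, tri$x,
                         30L, 1e-7)
  coeffs <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = upd$x,
                                 dims = dim(code$coeffs))
  new_code <- structure(list(coeffs = coeffs, L = code$L,
                             residual = code$residual,
                             score = Matrix::colSums(abs(coeffs))),
                        class = "sparse_code")
  list(dict = new_dictionary(upd$D, dict$provenance), code = new_code)
}

# column-sorted triplets of a sparse_code
code_triplets <- function(code) {
  tri <- Matrix::summary(code$coeffs)
  ord <- order(tri$j, tri$i)
  list(i = as.integer(tri$i[ord]), j = as.integer(tri$j[ord]),
       x = as.numeric(tri$x[ord]))
}

#' Learn a dictionary by K-SVD
#'
#' Alternates OMP sparse coding of the (possibly subsampled) training
#' patches with atom-by-atom K-SVD updates for `cfg$n_iter` iterations.
#' After each re-encode, any training signal whose fresh greedy code is
#' worse than its previous code (under the current dictionary) keeps the
#' previous code, which makes the recorded objective non-increasing by
#' construction. `objective_trace` holds the Frobenius residual
#' `||Y - D alpha||_F` after each iteration.
#'
#' @param ps a `patch_set` (or numeric signal matrix).
#' @param cfg a [learning_config()].
#' @return list with `dict`, `objective_trace`, the final training `code`
#'   and `train_idx` (indices of the training subsample).
#' @export
ksvd_learn <- function(ps, cfg) {
  stopifnot(inherits(cfg, "learning_config"))
  if (is.matrix(ps)) {
    m_all <- ncol(ps)
    get_cols <- function(idx) ps[, idx, drop = FALSE]
    sums <- colSums(ps)
    ps_obj <- NULL
  } else {
    stopifnot(inherits(ps, "patch_set"))
    m_all <- n_patches(ps)
    get_cols <- function(idx) patch_data(ps, idx)
    sums <- mean_patch_intensity(ps)$per_patch_sums
    ps_obj <- ps
  }
  if (m_all > cfg$max_train) {
    if (identical(cfg$train_pool, "bright")) {
      # draw training patches preferentially from the above-average pool
      pool <- which(sums > mean(sums))
      train_idx <- if (length(pool) >= cfg$max_train) {
        sort(with_seed(cfg$seed + 1L, sample(pool, cfg$max_train)))
      } else {
        extra <- with_seed(cfg$seed + 1L,
                           sample(setdiff(seq_len(m_all), pool),
                                  cfg$max_train - length(pool)))
        sort(c(pool, extra))
      }
    } else {
      train_idx <- sort(with_seed(cfg$seed + 1L,
                                  sample.int(m_all, cfg$max_train)))
    }
  } else {
    train_idx <- seq_len(m_all)
  }
  Y <- get_cols(train_idx)
  if (cfg$L >= nrow(Y))
    stop("sparsity L must be smaller than the patch dimension n",
         call. = FALSE)
  dict <- if (is.matrix(ps)) {
    init_dictionary_matrix(ps, cfg)
  } else {
    init_dictionary(ps_obj, cfg)
  }
  trace <- numeric(cfg$n_iter)
  old <- list(i = integer(0), j = integer(0), x = numeric(0))
  code <- NULL
  for (it in seq_len(cfg$n_iter)) {
    tri <- cpp_batch_omp(dict$atoms, Y, cfg$L, cfg$tol,
                         old$i, old$j, old$x)
    code <- code_from_triplets(tri, dict$K, ncol(Y), cfg$L)
    trace[it] <- sqrt(sum(tri$residual^2))
    upd <- ksvd_update(dict, Y, code)
    dict <- upd$dict
    code <- upd$code
    tri2 <- Matrix::summary(code$coeffs)
    ord <- order(tri2$j, tri2$i)
    old <- list(i = as.integer(tri2$i[ord]), j = as.integer(tri2$j[ord]),
                x = as.numeric(tri2$x[ord]))
  }
  list(dict = dict, objective_trace = trace, code = code,
       train_idx = train_idx)
}

# init_dictionary for a raw signal matrix (same rule as for patch sets).
init_dictionary_matrix <- function(Y, cfg) {
  sums <- colSums(Y)
  eligible <- which(sums > mean(sums))
  if (length(eligible) >= cfg$K) {
    sel <- with_seed(cfg$seed, sample(eligible, cfg$K))
  } else {
    warning(sprintf(
      "only %d signals exceed the average intensity; using top-%d by sum",
      length(eligible), cfg$K))
    sel <- order(sums, decreasing = TRUE)[seq_len(min(cfg$K, ncol(Y)))]
  }
  atoms <- Y[, sel, drop = FALSE]
  nrm <- sqrt(colSums(atoms^2))
  bad <- nrm == 0
  if (any(bad)) {
    pool <- setdiff(order(sums, decreasing = TRUE), sel)
    repl <- pool[seq_len(sum(bad))]
    atoms[, bad] <- Y[, repl, drop = FALSE]
    nrm <- sqrt(colSums(atoms^2))
    if (any(nrm == 0)) stop("cannot build a dictionary from all-zero signals",
                            call. = FALSE)
  }
  atoms <- sweep(atoms, 2, nrm, "/")
  new_dictionary(atoms, provenance = list(seed = cfg$seed,
                                          source_indices = sel))
}

#' Serialize / load a learned dictionary
#'
#' The atom matrix goes to a flat little-endian binary of doubles and the
#' metadata (dimensions, seed) to a JSON sidecar, so a dictionary learned
#' on one time point can be reused across a sequence.
#'
#' @param dict a `nuclei_dictionary`.
#' @param prefix output path prefix; writes `<prefix>.bin` + `<prefix>.json`.
#' @return `write_dictionary` returns the prefix invisibly; `read_dictionary`
#'   returns the dictionary.
#' @export
write_dictionary <- function(dict, prefix) {
  stopifnot(inherits(dict, "nuclei_dictionary"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(dict$atoms), con, size = 8, endian = "little")
  meta <- list(n = dict$n, K = dict$K, provenance = dict$provenance)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = meta$n * meta$K, size = 8,
                  endian = "little")
  new_dictionary(matrix(vals, meta$n, meta$K), provenance = meta$provenance)
}
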