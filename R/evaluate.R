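#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Kuhn-Munkres with row/column potentials, O(n^3). Rows are assigned to
#' columns minimizing the total cost; the matrix may be rectangular
#' (rows <= cols after internal padding). Entries of `Inf` are forbidden.
#'
#' @param cost numeric cost matrix.
#' @return integer vector: for each row, the assigned column (NA when a
#'   row could only be assigned to a forbidden entry).
#' @export
solve_assignment <- function(cost) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  n <- max(n1, n2)
  big <- 0
  fin <- cost[is.finite(cost)]
  if (length(fin)) big <- sum(abs(fin)) + 1
  big <- max(big, 1)
  C <- matrix(big, n, n)
  C[seq_len(n1), seq_len(n2)] <- ifelse(is.finite(cost), cost, big)
  # potentials method (1-based translation of the classic implementation)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)  # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- C[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j + 1] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- rep(NA_integer_, n1)
  for (j in seq_len(n)) {
    r <- p[j + 1]
    if (r >= 1 && r <= n1 && j <= n2 && is.finite(cost[r, j]))
      assign[r] <- j
  }
  assign
}

#' Match ground-truth and segmented centroids
#'
#' Builds the bipartite distance matrix, forbids pairs farther apart than
#' `gate_radius`, and solves the minimum-total-distance one-to-one
#' assignment with the Hungarian algorithm. Matched pairs are true
#' positives; leftover ground-truth objects are false negatives and
#' leftover segmented objects false positives.
#'
#' @param gt_centroids numeric matrix (rows = objects, columns x, y, z) or
#'   a `nuclei_gt`.
#' @param seg_centroids numeric matrix, or the centroid data.frame of a
#'   `nuclei_segmentation`.
#' @param gate_radius maximum centre distance of a valid match.
#' @return object of class `match_result`: `pairs` (data.frame gt_id,
#'   seg_id, distance), `unmatched_gt`, `unmatched_seg`, `TP`, `FN`, `FP`.
#' @export
match_centroids <- function(gt_centroids, seg_centroids, gate_radius) {
  stopifnot(gate_radius > 0)
  G <- centroid_matrix(gt_centroids)
  S <- centroid_matrix(seg_centroids)
  gt_ids <- attr(G, "ids")
  seg_ids <- attr(S, "ids")
  ng <- nrow(G)
  ns <- nrow(S)
  pairs <- data.frame(gt_id = integer(0), seg_id = integer(0),
                      distance = numeric(0))
  if (ng > 0 && ns > 0) {
    dmat <- sqrt(outer(rowSums(G^2), rowSums(S^2), `+`) - 2 * G %*% t(S))
    dmat[!is.finite(dmat)] <- 0
    dmat[dmat < 0] <- 0
    cost <- dmat
    cost[cost > gate_radius] <- Inf
    asg <- solve_assignment(cost)
    for (i in seq_len(ng)) {
      j <- asg[i]
      if (!is.na(j))
        pairs[nrow(pairs) + 1, ] <- list(gt_ids[i], seg_ids[j], dmat[i, j])
    }
  }
  structure(list(pairs = pairs,
                 unmatched_gt = setdiff(gt_ids, pairs$gt_id),
                 unmatched_seg = setdiff(seg_ids, pairs$seg_id),
                 TP = nrow(pairs),
                 FN = ng - nrow(pairs),
                 FP = ns - nrow(pairs)),
            class = "match_result")
}

centroid_matrix <- function(x) {
  if (inherits(x, "nuclei_gt")) {
    m <- x$centroids
    ids <- x$ids
  } else if (is.data.frame(x)) {
    m <- as.matrix(x[, c("x", "y", "z")])
    ids <- if ("id" %in% names(x)) x$id else seq_len(nrow(x))
  } else {
    m <- as.matrix(x)
    ids <- seq_len(nrow(m))
  }
  if (ncol(m) != 3) stop("centroids must have three columns", call. = FALSE)
  attr(m, "ids") <- as.integer(ids)
  m
}

#' Detection metrics from a match result
#'
#' Recall = 100 TP/(TP+FN), precision = 100 TP/(TP+FP), F-measure their
#' harmonic mean. Ratios with a zero denominator are reported as `NA`
#' (absent), never as zero.
#'
#' @param mr a `match_result` (or a list with TP, FN, FP counts).
#' @return object of class `eval_report` with TP, FN, FP, recall,
#'   precision, f_measure (percent).
#' @export
detection_metrics <- function(mr) {
  TP <- mr$TP
  FN <- mr$FN
  FP <- mr$FP
  recall <- if (TP + FN > 0) 100 * TP / (TP + FN) else NA_real_
  precision <- if (TP + FP > 0) 100 * TP / (TP + FP) else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  structure(list(TP = TP, FN = FN, FP = FP, recall = recall,
                 precision = precision, f_measure = f),
            class = "eval_report")
}

#' Matched-pair Jaccard indices
#'
#' For every matched (ground truth, segmentation) pair the Jaccard index
#' `|A ∩ B| / |A ∪ B|` over voxel sets, and the mean over matched
#' pairs only.
#'
#' @param seg integer labelled 3D array.
#' @param gt integer labelled 3D array (same shape).
#' @param mr a `match_result` whose ids refer to `gt` and `seg` labels.
#' @return list with `per_pair` (data.frame gt_id, seg_id, jaccard) and
#'   `mean`.
#' @export
jaccard_segmentation <- function(seg, gt, mr) {
  if (!identical(dim(seg), dim(gt)))
    stop("segmentation and ground truth have different shapes",
         call. = FALSE)
  pp <- mr$pairs
  res <- numeric(nrow(pp))
  for (t in seq_len(nrow(pp))) {
    A <- gt == pp$gt_id[t]
    B <- seg == pp$seg_id[t]
    inter <- sum(A & B)
    res[t] <- inter / (sum(A) + sum(B) - inter)
  }
  list(per_pair = cbind(pp[, c("gt_id", "seg_id")], jaccard = res),
       mean = if (length(res)) mean(res) else NA_real_)
}

#' Evaluate a segmentation against ground truth
#'
#' Hungarian centroid matching (gate defaulting to the mean ground-truth
#' equivalent-sphere radius -- scale-free and dataset independent),
#' detection metrics and, when a ground-truth label volume is available,
#' matched-pair Jaccard. For centroid-only ground truth the Jaccard part
#' is skipped.
#'
#' @param seg a `nuclei_segmentation`, or a labelled 3D array, or a
#'   centroid table.
#' @param gt a `nuclei_gt` or a centroid matrix/data.frame.
#' @param gate_radius optional gate; default mean equivalent-sphere radius
#'   of the ground-truth objects (requires volumes in `gt`).
#' @return `eval_report` augmented with `jaccard_mean`, `per_pair_jaccard`
#'   and the `match` object.
#' @export
evaluate_segmentation <- function(seg, gt, gate_radius = NULL) {
  seg_labels <- NULL
  if (inherits(seg, "nuclei_segmentation")) {
    seg_cent <- seg$centroids
    seg_labels <- seg$labels
  } else if (is.array(seg) && length(dim(seg)) == 3L) {
    seg_cent <- label_centroids(seg)
    seg_labels <- seg
  } else {
    seg_cent <- seg
  }
  gt_labels <- if (inherits(gt, "nuclei_gt")) gt$labels else NULL
  if (is.null(gate_radius)) {
    if (!inherits(gt, "nuclei_gt"))
      stop("gate_radius must be given for centroid-only ground truth",
           call. = FALSE)
    gate_radius <- mean((3 * gt$volumes / (4 * pi))^(1 / 3))
  }
  mr <- match_centroids(gt, seg_cent, gate_radius)
  rep <- detection_metrics(mr)
  rep$gate_radius <- gate_radius
  rep$match <- mr
  if (!is.null(gt_labels) && !is.null(seg_labels)) {
    jc <- jaccard_segmentation(seg_labels, gt_labels, mr)
    rep$jaccard_mean <- jc$mean
    rep$per_pair_jaccard <- jc$per_pair
  } else {
    rep$jaccard_mean <- NA_real_
    rep$per_pair_jaccard <- NULL
  }
  rep
}

#' Coefficient-of-variation parameter sweep
#'
#' Measures parameter sensitivity the way the benchmark study does: one
#' parameter axis is varied at a time with all others fixed at the base
#' configuration; each run's F-measure against ground truth is recorded;
#' per noise level the CV (100 * population sd / mean) is taken across the
#' axis values, and finally averaged over levels. F-measure is the
#' response variable. Identical configurations reached from different
#' axes are computed once (cached within the call).
#'
#' @param suite a benchmark suite from [make_benchmark_suite()].
#' @param base list of base pipeline arguments: `psz`, `K`, `L`, `n_iter`,
#'   `seed`, `max_train`, `seg`, `lambda`.
#' @param axes named list of axes to sweep; supported names `patch_size`
#'   (list of patch specs), `dictionary_size`, `sparsity`, `iterations`
#'   (numeric vectors).
#' @param verbose print one line per run.
#' @return data.frame (parameter, snr_db, cv_percent) with attribute
#'   `runs` (the per-run F-measure table) and attribute `summary`
#'   (parameter, mean_cv_percent averaged over noise levels).
#' @export
parameter_cv_sweep <- function(suite,
                               base = list(psz = patch_spec(),
                                           K = 64L, L = 3L, n_iter = 15L,
                                           seed = 1L, max_train = 20000L,
                                           seg = segmentation_config(),
                                           lambda = 0),
                               axes = list(
                                 patch_size = list(c(5, 5, 5), c(10, 10, 5),
                                                   c(15, 15, 5),
                                                   c(20, 20, 5)),
                                 dictionary_size = c(64, 128, 256, 512),
                                 sparsity = c(3, 6, 9),
                                 iterations = c(5, 10, 15, 20, 25, 30)),
                               verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  run_one <- function(level, psz, K, L, n_iter) {
    key <- paste(level, paste(psz, collapse = "x"), K, L, n_iter, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    lv <- suite[[level]]
    cfg <- learning_config(K = K, L = L, n_iter = n_iter, seed = base$seed,
                           max_train = base$max_train)
    res <- segment_pipeline(lv$volume, psz = psz, learning = cfg,
                            seg = base$seg, lambda = base$lambda)
    ev <- evaluate_segmentation(res, lv$gt)
    f <- if (is.na(ev$f_measure)) 0 else ev$f_measure
    if (verbose)
      message(sprintf("%s patch=%s K=%d L=%d N=%d -> F=%.2f (TP=%d FN=%d FP=%d)",
                      level, paste(psz, collapse = "x"), K, L, n_iter, f,
                      ev$TP, ev$FN, ev$FP))
    cache[[key]] <- f
    f
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  runs <- data.frame(parameter = character(0), snr_db = numeric(0),
                     value = character(0), f_measure = numeric(0))
  out <- data.frame(parameter = character(0), snr_db = numeric(0),
                    cv_percent = numeric(0))
  snrs <- vapply(suite, function(lv) lv$target_snr_db, numeric(1))
  for (ax in names(axes)) {
    for (level in names(suite)) {
      fs <- numeric(0)
      for (val in axes[[ax]]) {
        a <- list(psz = patch_spec(base$psz), K = base$K, L = base$L,
                  n_iter = base$n_iter)
        if (ax == "patch_size") a$psz <- patch_spec(val)
        if (ax == "dictionary_size") a$K <- as.integer(val)
        if (ax == "sparsity") a$L <- as.integer(val)
        if (ax == "iterations") a$n_iter <- as.integer(val)
        f <- run_one(level, a$psz, a$K, a$L, a$n_iter)
        fs <- c(fs, f)
        runs[nrow(runs) + 1, ] <- list(ax, snrs[[level]],
                                       paste(unlist(val), collapse = "x"), f)
      }
      cv <- if (mean(fs) > 0) 100 * pop_sd(fs) / mean(fs) else NA_real_
      out[nrow(out) + 1, ] <- list(ax, snrs[[level]], cv)
    }
  }
  summ <- aggregate(cv_percent ~ parameter, data = out, FUN = mean)
  names(summ)[2] <- "mean_cv_percent"
  attr(out, "runs") <- runs
  attr(out, "summary") <- summ
  out
}
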