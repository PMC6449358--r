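# Independent reference implementations used as oracles. These are written
# as literal transcriptions of the definitions (loops, enumerations) and
# deliberately share no code with the package internals.

# step-by-step greedy OMP: argmax |<residual, atom>|, least-squares refit
ref_omp <- function(D, y, L, tol = 1e-6) {
  support <- integer(0)
  coef <- numeric(0)
  r <- y
  for (step in seq_len(L)) {
    cors <- abs(drop(crossprod(D, r)))
    cors[support] <- -Inf
    j <- which.max(cors)
    if (cors[j] == 0) break
    support <- c(support, j)
    coef <- drop(qr.solve(D[, support, drop = FALSE], y))
    r <- y - D[, support, drop = FALSE] %*% coef
    if (sqrt(sum(r^2)) <= tol * sqrt(sum(y^2))) break
  }
  list(support = support, coef = coef, residual = sqrt(sum(r^2)))
}

# exhaustive minimum assignment over all permutations (n <= 7)
ref_assignment <- function(cost) {
  n1 <- nrow(cost)
  n2 <- ncol(cost)
  stopifnot(n1 <= n2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf
  best_asg <- rep(NA_integer_, n1)
  for (p in perms(seq_len(n2))) {
    sel <- p[seq_len(n1)]
    w <- cost[cbind(seq_len(n1), sel)]
    tot <- sum(ifelse(is.finite(w), w, 1e9))
    if (tot < best) {
      best <- tot
      best_asg <- ifelse(is.finite(w), sel, NA_integer_)
    }
  }
  list(assign = best_asg, cost = best)
}

# exhaustive 256-candidate Otsu scan (two-class variance maximization)
ref_otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  best_t <- NA
  best_v <- -Inf
  for (t in 1:(nbins - 1)) {
    thr <- edges[t + 1]
    lo <- x[x <= thr]
    hi <- x[x > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(x)
    w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v) {
      best_v <- v
      best_t <- thr
    }
  }
  best_t
}

# Jaccard by explicit voxel-coordinate set comparison
ref_jaccard <- function(seg, gt, gt_id, seg_id) {
  a <- which(gt == gt_id)
  b <- which(seg == seg_id)
  length(intersect(a, b)) / length(union(a, b))
}

# brute-force voxel enumeration of a sphere
ref_sphere_count <- function(center, r, shape) {
  cnt <- 0
  for (x in 0:(shape[1] - 1))
    for (y in 0:(shape[2] - 1))
      for (z in 0:(shape[3] - 1))
        if ((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2 <= r^2)
          cnt <- cnt + 1
  cnt
}
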