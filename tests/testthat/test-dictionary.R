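test_that("initial atoms are unit-norm draws from above-average patches", {
  ph <- render_phantom(small_phantom_spec())
  ps <- extract_patches(ph$volume, small_patch())
  cfg <- small_learning()
  dict <- init_dictionary(ps, cfg)
  expect_equal(ncol(dict$atoms), cfg$K)
  expect_equal(sqrt(colSums(dict$atoms^2)), rep(1, cfg$K), tolerance = 1e-12)
  mi <- mean_patch_intensity(ps)
  expect_true(all(mi$per_patch_sums[dict$provenance$source_indices] >
                    mi$global_average))
  # determinism
  dict2 <- init_dictionary(ps, cfg)
  expect_identical(dict$atoms, dict2$atoms)
})

test_that("identical patches trigger the top-K fallback", {
  vol <- array(5, dim = c(8, 8, 4))
  ps <- extract_patches(vol, patch_spec(c(3, 3, 2)))
  expect_warning(dict <- init_dictionary(ps, learning_config(K = 4, L = 2)),
                 "top-4")
  expect_equal(sqrt(colSums(dict$atoms^2)), rep(1, 4), tolerance = 1e-12)
})

test_that("OMP recovers trivial and orthogonal codes exactly", {
  set.seed(3)
  D <- qr.Q(qr(matrix(rnorm(36), 6)))  # orthonormal atoms
  dict <- sparsenuclei:::new_dictionary(D)
  # y equal to an atom
  code <- omp_encode(dict, matrix(D[, 4]), L = 2)
  expect_equal(as.numeric(code$coeffs[, 1]),
               c(0, 0, 0, 1, 0, 0), tolerance = 1e-10)
  expect_lt(code$residual[1], 1e-10)
  # y = 2 d1 + 3 d5 with orthogonal atoms
  y <- 2 * D[, 1] + 3 * D[, 5]
  code <- omp_encode(dict, matrix(y), L = 2)
  expect_equal(as.numeric(code$coeffs[c(1, 5), 1]), c(2, 3),
               tolerance = 1e-10)
  expect_equal(Matrix::nnzero(code$coeffs), 2)
  # zero signal -> empty support
  code0 <- omp_encode(dict, matrix(0, 6, 1), L = 2)
  expect_equal(Matrix::nnzero(code0$coeffs), 0)
})

test_that("OMP matches the step-by-step greedy reference on random cases", {
  set.seed(11)
  for (i in 1:25) {
    D <- matrix(rnorm(6 * 4), 6, 4)
    D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
    y <- rnorm(6)
    ref <- ref_omp(D, y, L = 2)
    code <- omp_encode(sparsenuclei:::new_dictionary(D), matrix(y), L = 2)
    got <- which(code$coeffs[, 1] != 0)
    expect_setequal(got, ref$support)
    expect_equal(code$residual[1], ref$residual, tolerance = 1e-8)
    expect_equal(as.numeric(code$coeffs[ref$support, 1]),
                 as.numeric(ref$coef), tolerance = 1e-8)
  }
})

test_that("OMP residuals are orthogonal to the selected span and shrink", {
  set.seed(4)
  D <- matrix(rnorm(10 * 8), 10, 8)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  dict <- sparsenuclei:::new_dictionary(D)
  y <- rnorm(10)
  r_prev <- sqrt(sum(y^2))
  for (L in 1:4) {
    code <- omp_encode(dict, matrix(y), L = L)
    S <- which(code$coeffs[, 1] != 0)
    r <- y - D[, S, drop = FALSE] %*% as.numeric(code$coeffs[S, 1])
    expect_lt(max(abs(crossprod(D[, S, drop = FALSE], r))), 1e-8)
    expect_lte(code$residual[1], r_prev + 1e-12)
    r_prev <- code$residual[1]
  }
})

test_that("K-SVD atom update reaches the dense-SVD rank-1 optimum", {
  set.seed(8)
  n <- 8; K <- 3; m <- 20
  D <- matrix(rnorm(n * K), n, K)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  dict <- sparsenuclei:::new_dictionary(D)
  Y <- matrix(rnorm(n * m), n, m)
  code <- omp_encode(dict, Y, L = 2)
  upd <- ksvd_update(dict, Y, code)
  expect_equal(sqrt(colSums(upd$dict$atoms^2)), rep(1, K), tolerance = 1e-9)
  # restricted residual of every atom must not exceed the pre-update one
  # and must match the dense-SVD rank-1 optimum
  A_old <- as.matrix(code$coeffs)
  A_new <- as.matrix(upd$code$coeffs)
  for (k in 1:K) {
    users <- which(A_old[k, ] != 0)
    if (!length(users)) next
    Ek <- Y[, users, drop = FALSE] -
      D %*% A_old[, users, drop = FALSE] + outer(D[, k], A_old[k, users])
    pre <- norm(Ek - outer(D[, k], A_old[k, users]), "F")
    # oracle: residual after the optimal rank-1 approximation of Ek
    sv <- svd(Ek)
    opt <- sqrt(max(sum(sv$d^2) - sv$d[1]^2, 0))
    # the update is Gauss-Seidel (atoms before k already moved), so only
    # atom 1 is compared against the oracle computed from the old state
    if (k == 1) {
      post <- norm(Ek - outer(upd$dict$atoms[, 1], A_new[1, users]), "F")
      expect_lte(post, pre + 1e-9)
      expect_equal(post, opt, tolerance = 1e-6)
    }
  }
})

test_that("a single atom with one signal becomes that signal normalized", {
  y <- c(3, 4, 0)
  dict <- sparsenuclei:::new_dictionary(matrix(c(1, 0, 0), 3, 1))
  code <- omp_encode(dict, matrix(y), L = 1)
  upd <- ksvd_update(dict, matrix(y), code)
  expect_equal(as.numeric(upd$dict$atoms), y / 5, tolerance = 1e-9)
})

test_that("the learning objective is non-increasing on any input", {
  set.seed(21)
  Y <- matrix(rnorm(12 * 80, sd = 3) + 2, 12, 80)
  fit <- ksvd_learn(Y, learning_config(K = 6, L = 2, n_iter = 8, seed = 2))
  tr <- fit$objective_trace
  expect_true(all(diff(tr) <= 1e-8 * tr[-length(tr)]))
  ph <- render_phantom(small_phantom_spec())
  ns <- noise_spec(gaussian_sigma = 80, seed = 2)
  noisy <- apply_noise(ph$volume, ns)
  ps <- extract_patches(noisy, small_patch())
  fit2 <- ksvd_learn(ps, small_learning())
  tr2 <- fit2$objective_trace
  expect_true(all(diff(tr2) <= 1e-8 * tr2[-length(tr2)]))
})

test_that("learning on exact sparse mixtures drives the objective near zero", {
  # every signal is an exact 3-sparse mixture of three random incoherent
  # atoms; the learned dictionary must capture their span, after which the
  # OMP refit represents each signal exactly
  for (s in c(33, 71)) {
    set.seed(s)
    n <- 64; K_true <- 3; m <- 150
    D0 <- matrix(rnorm(n * K_true), n, K_true)
    D0 <- sweep(D0, 2, sqrt(colSums(D0^2)), "/")
    Y <- sapply(seq_len(m), function(i) {
      S <- sample(K_true, 3)
      drop(D0[, S] %*% runif(3, 0.5, 2))
    })
    fit <- ksvd_learn(Y, learning_config(K = 6, L = 3, n_iter = 15,
                                         seed = s))
    rel <- (tail(fit$objective_trace, 1))^2 / sum(Y^2)
    expect_lt(rel, 1e-6)
  }
})

test_that("noise-free patches reconstruct better than noisy ones", {
  ph <- render_phantom(small_phantom_spec())
  noisy <- apply_noise(ph$volume, noise_spec(gaussian_sigma = 60, seed = 9))
  cfg <- small_learning()
  ps_clean <- extract_patches(ph$volume, small_patch())
  ps_noisy <- extract_patches(noisy, small_patch())
  fit_clean <- ksvd_learn(ps_clean, cfg)
  fit_noisy <- ksvd_learn(ps_noisy, cfg)
  rel <- function(fit, ps) tail(fit$objective_trace, 1)^2 /
    sum(patch_data(ps, fit$train_idx)^2)
  expect_lt(rel(fit_clean, ps_clean), rel(fit_noisy, ps_noisy))
})

test_that("dictionaries round-trip through serialization", {
  ph <- render_phantom(small_phantom_spec())
  ps <- extract_patches(ph$volume, small_patch())
  dict <- init_dictionary(ps, small_learning())
  pre <- file.path(tempdir(), "dict_test")
  write_dictionary(dict, pre)
  back <- read_dictionary(pre)
  expect_equal(back$atoms, dict$atoms)
  expect_equal(back$K, dict$K)
})
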