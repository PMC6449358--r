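test_that("local adaptive threshold implements the sensitivity rule", {
  # constant neighbourhood mean 100: threshold 50 at sensitivity 0.5
  vol <- array(100, c(9, 9, 5))
  vol[5, 5, 3] <- 60   # above 50 -> foreground despite being dimmest
  mask <- local_adaptive_threshold(vol, 0.5, c(9, 9, 5))
  expect_equal(mask[5, 5, 3], 1L)
  # sensitivity 1: threshold 0, every positive voxel is foreground
  mask1 <- local_adaptive_threshold(vol, 1, c(3, 3, 3))
  expect_true(all(mask1 == 1L))
  # constant volume at sensitivity 0: strict inequality empties the mask
  mask0 <- local_adaptive_threshold(array(7, c(6, 6, 3)), 0, c(3, 3, 1))
  expect_true(all(mask0 == 0L))
  expect_error(local_adaptive_threshold(vol, 0.5, c(4, 3, 3)), "odd")
})

test_that("raising the sensitivity factor never shrinks the foreground", {
  vol <- rand_volume(c(15, 14, 6), seed = 5)
  prev <- -1
  for (sf in c(0, 0.3, 0.6, 1)) {
    m <- local_adaptive_threshold(vol, sf, c(5, 5, 3))
    expect_gte(sum(m), prev)
    prev <- sum(m)
  }
})

test_that("global Otsu separates a two-value volume and matches brute force", {
  vol <- array(10, c(10, 10, 4))
  vol[3:6, 3:6, 2:3] <- 100
  mask <- global_otsu_threshold(vol)
  thr <- attr(mask, "threshold")
  expect_true(thr > 10 && thr < 100)
  expect_identical(mask == 1, vol == 100)
  # brute-force scan oracle on noisy volumes
  for (i in 1:4) {
    v <- rand_volume(c(12, 10, 5), seed = 40 + i)
    v[v > 60] <- v[v > 60] + 150   # make it bimodal
    got <- attr(global_otsu_threshold(v), "threshold")
    expect_equal(got, ref_otsu(as.numeric(v)), tolerance = 1e-9)
  }
  expect_error(global_otsu_threshold(array(3, c(4, 4, 2))), "constant")
})

test_that("Otsu thresholds shift with a constant intensity offset", {
  v <- rand_volume(c(10, 10, 5), seed = 50)
  v[v > 50] <- v[v > 50] + 100
  t1 <- attr(global_otsu_threshold(v), "threshold")
  t2 <- attr(global_otsu_threshold(v + 37), "threshold")
  expect_equal(t2 - t1, 37, tolerance = (max(v) - min(v)) / 256)
})

test_that("minimum-volume filtering drops small components only", {
  mask <- array(0L, c(30, 20, 8))
  mask[2:3, 2:3, 2] <- 1L                      # 8 voxels
  mask[10:14, 10:14, 3] <- 1L                  # 25 voxels
  mask[20:29, 1:10, 4:7] <- 1L                 # 400 voxels
  out <- filter_min_volume(mask, 20)
  lab <- sparsenuclei:::cpp_label3d(out, dim(out))
  expect_equal(max(lab), 2L)
  expect_identical(filter_min_volume(mask, 0), mask)
  # a 19-voxel speck dies, a radius-7 sphere survives
  ph <- render_phantom(sphere_phantom_spec(
    shape = c(40, 40, 16),
    spheres = data.frame(x = 15, y = 15, z = 8, r = 7, intensity = 100)))
  m2 <- array(0L, dim = dim(ph$gt$labels))
  m2[ph$gt$labels > 0] <- 1L
  m2[35:39, 35:38, 2] <- 1L  # 5*4*1 block minus one voxel = 19
  m2[39, 38, 2] <- 0L
  out2 <- filter_min_volume(m2, 20)
  expect_equal(sum(out2), ph$gt$volumes[1])
})

cone_field <- function(d, peaks) {
  # peaks: list of list(c0 = centre (1-based), r0, h)
  ax <- seq_len(d[1]); ay <- seq_len(d[2]); az <- seq_len(d[3])
  out <- array(0, d)
  for (p in peaks) {
    dd <- sqrt(outer(outer((ax - p$c0[1])^2, (ay - p$c0[2])^2, `+`),
                     (az - p$c0[3])^2, `+`))
    out <- pmax(out, p$h * pmax(0, 1 - dd / p$r0))
  }
  out
}

test_that("markers: one per isolated peak, merged when dilations overlap", {
  d <- c(40, 30, 12)
  mr <- cone_field(d, list(list(c0 = c(10, 15, 6), r0 = 8, h = 1),
                           list(c0 = c(30, 15, 6), r0 = 8, h = 0.9)))
  mask <- array(1L, d)
  mk <- detect_markers(mr, mask, segmentation_config())
  expect_equal(mk$n, 2L)
  expect_equal(sort(mk$centers[, 1]), c(9, 29))  # 0-based
  # empty mask -> no markers
  mk0 <- detect_markers(mr, array(0L, d), segmentation_config())
  expect_equal(mk0$n, 0L)
  # two nearby peaks merge into one marker through dilation
  mr2 <- cone_field(d, list(list(c0 = c(15, 15, 6), r0 = 6, h = 1),
                            list(c0 = c(19, 15, 6), r0 = 6, h = 0.95)))
  mk2 <- detect_markers(mr2, mask,
                        segmentation_config(nuclei_seed_dilation = 3))
  expect_equal(mk2$n, 1L)
})

test_that("marker detection is deterministic and components are maximal", {
  d <- c(25, 25, 9)
  set.seed(6)
  mr <- array(runif(prod(d)), d)
  mask <- array(1L, d)
  cfg <- segmentation_config(min_marker_response = 0)
  mk1 <- detect_markers(mr, mask, cfg)
  mk2 <- detect_markers(mr, mask, cfg)
  expect_identical(mk1$markers, mk2$markers)
  # relabeling the merged components reproduces the same partition
  relab <- sparsenuclei:::cpp_label3d(as.integer(mk1$markers > 0),
                                      as.integer(d))
  expect_equal(max(relab), mk1$n)
})

test_that("watershed respects masks, markers and counts", {
  # one marker in one component: the whole component takes one label
  d <- c(20, 20, 8)
  vol <- array(0, d)
  vol[5:12, 5:12, 3:6] <- 50
  mask <- array(as.integer(vol > 0), d)
  markers <- array(0L, d)
  markers[8, 8, 4] <- 1L
  lab <- watershed_segment(vol, mask, markers)
  expect_identical(lab > 0, mask == 1L)
  expect_equal(sort(unique(as.integer(lab))), c(0L, 1L))
  # zero markers -> all background
  lab0 <- watershed_segment(vol, mask, array(0L, d))
  expect_true(all(lab0 == 0))
})

test_that("touching spheres split into two labels of near-ideal volume", {
  spec <- small_phantom_spec(touching = TRUE)   # r 7 and 9, centres 16 apart
  ph <- render_phantom(spec)
  # cone-shaped intensity rising to each centre emulates the denoised image
  d <- spec$shape
  vol <- cone_field(d, list(
    list(c0 = c(spec$spheres$x[1], spec$spheres$y[1], spec$spheres$z[1]) + 1,
         r0 = spec$spheres$r[1] + 2, h = 100),
    list(c0 = c(spec$spheres$x[2], spec$spheres$y[2], spec$spheres$z[2]) + 1,
         r0 = spec$spheres$r[2] + 2, h = 100)))
  mask <- array(as.integer(ph$gt$labels > 0), d)
  mk <- detect_markers(vol, mask,
                       segmentation_config(nuclei_seed_dilation = 3))
  expect_equal(mk$n, 2L)
  lab <- watershed_segment(vol, mask, mk)
  expect_equal(max(lab), 2L)
  sizes <- tabulate(lab[lab > 0])
  ideal <- sort(4 / 3 * pi * c(7, 9)^3)
  expect_true(all(abs(sort(sizes) - ideal) / ideal < 0.2))
  # every labelled voxel was inside the initial mask
  expect_true(all(mask[lab > 0] == 1L))
})

test_that("the full pipeline is deterministic and resolves the phantom", {
  spec <- small_phantom_spec(touching = TRUE)
  ph <- render_phantom(spec)
  noisy <- apply_noise(ph$volume, noise_spec(gaussian_sigma = 60, seed = 23))
  cfg <- learning_config(K = 24, L = 3, n_iter = 5, seed = 7,
                         max_train = 5000)
  res1 <- segment_pipeline(noisy, patch_spec(c(11, 11, 5)), cfg,
                           segmentation_config(nuclei_seed_dilation = 3))
  res2 <- segment_pipeline(noisy, patch_spec(c(11, 11, 5)), cfg,
                           segmentation_config(nuclei_seed_dilation = 3))
  expect_identical(res1$labels, res2$labels)
  ev <- evaluate_segmentation(res1, ph$gt)
  expect_equal(ev$FN, 0)
  expect_equal(ev$FP, 0)
  expect_equal(res1$n, res1$markers$n)
})

test_that("patch volumes outside the 25-100% band are flagged", {
  g <- patch_size_guideline(patch_spec(c(15, 15, 5)), 1982)
  expect_true(g$in_band)
  expect_false(patch_size_guideline(patch_spec(c(20, 20, 5)), 1982)$in_band)
  expect_false(patch_size_guideline(patch_spec(c(5, 5, 5)), 1982)$in_band)
  ph <- render_phantom(small_phantom_spec())
  expect_warning(
    segment_pipeline(apply_noise(ph$volume,
                                 noise_spec(gaussian_sigma = 20, seed = 2)),
                     patch_spec(c(5, 5, 3)),
                     learning_config(K = 8, L = 2, n_iter = 2,
                                     max_train = 2000),
                     mean_nucleus_volume = 4 / 3 * pi * 125),
    "25--100")
})
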