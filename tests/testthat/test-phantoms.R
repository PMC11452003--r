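test_that("shape families are deterministic, connected and volume-bounded", {
  sp <- phantom_spec(n_subjects = 4, seed = 11)
  f1 <- generate_shape_family(sp)
  f2 <- generate_shape_family(sp)
  for (k in seq_along(f1)) expect_identical(f1[[k]]$grid, f2[[k]]$grid)
  # zero variability and bend: all subjects identical
  sp0 <- phantom_spec(n_subjects = 3, variability = 0, bend = 0, seed = 2)
  f0 <- generate_shape_family(sp0)
  expect_identical(f0[[1]]$grid, f0[[2]]$grid)
  expect_identical(f0[[2]]$grid, f0[[3]]$grid)
  # single 6-connected component each
  for (m in f1) {
    lab <- muscleshape:::label_components_cpp(as.logical(m$grid),
                                              dim(m$grid), 6L)
    expect_equal(max(lab), 1L)
  }
  # volumes within +-40% of the zero-variability volume (analytic-profile
  # oracle: the deterministic member integrates the base radius profile)
  v0 <- sum(f0[[1]]$grid)
  spv <- phantom_spec(n_subjects = 10, base_radius = 8, variability = 2,
                      seed = 5)
  vols <- sapply(generate_shape_family(spv), function(m) sum(m$grid))
  expect_true(all(abs(vols - v0) / v0 < 0.4))
})

test_that("multi-label phantoms pack disjoint tubes with a real gap", {
  sp <- phantom_spec(n_subjects = 1, labels = 3, base_radius = 6,
                     variability = 0.5, seed = 4)
  vol <- generate_multilabel_phantom(sp, gap = 1)
  labs <- setdiff(sort(unique(as.vector(vol$grid))), 0L)
  expect_identical(labs, 1:3)
  masks <- lapply(labs, extract_label_mask, vol = vol)
  for (i in 1:2) for (j in (i + 1):3)
    expect_false(any(masks[[i]]$grid & masks[[j]]$grid))
  # brute-force pairwise surface distance >= 1 voxel
  for (i in 1:2) for (j in (i + 1):3) {
    si <- surface_voxels(masks[[i]])
    sj <- surface_voxels(masks[[j]])
    dmin <- sqrt(min(muscleshape:::nn_bruteforce(si, sj)$d2))
    expect_gte(dmin, 1)
  }
  expect_error(generate_multilabel_phantom(phantom_spec(labels = 1)),
               class = "ms_spec_error")
  expect_error(generate_multilabel_phantom(
    phantom_spec(labels = 6, base_radius = 10, shape = c(64, 64, 96))),
    class = "ms_spec_error")
})

test_that("corruption reproduces the stated error modes deterministically", {
  sp <- phantom_spec(n_subjects = 1, seed = 3)
  gt <- label_volume(array(as.integer(generate_shape_family(sp)[[1]]$grid),
                           sp$shape))
  # all-zero corruption is the identity
  cz <- corruption_spec(hole_count = 0, blob_count = 0, boundary_noise = 0,
                        swap_fraction = 0, seed = 1)
  expect_identical(corrupt_prediction(gt, cz)$grid, gt$grid)
  # holes only: exactly hole_count voids carved out of the label
  ch <- corruption_spec(hole_count = 3, hole_radius = 3, blob_count = 0,
                        boundary_noise = 0, seed = 7)
  pred <- corrupt_prediction(gt, ch)
  removed <- gt$grid == 1L & pred$grid == 0L
  lab <- muscleshape:::label_components_cpp(as.logical(removed),
                                            dim(removed), 6L)
  expect_equal(max(lab), 3L)
  # metadata untouched, determinism
  expect_identical(pred$spacing, gt$spacing)
  expect_identical(corrupt_prediction(gt, ch)$grid, pred$grid)
  # blobs land 2-5 voxels away from the label
  cb <- corruption_spec(hole_count = 0, blob_count = 2, blob_radius = 2,
                        boundary_noise = 0, seed = 2)
  pb <- corrupt_prediction(gt, cb)
  spur <- pb$grid == 1L & gt$grid == 0L
  expect_true(any(spur))
  dmap <- muscleshape:::dist_to(gt$grid == 1L)
  expect_gt(min(dmap[spur]), 1.5)
  # swaps corrupt the contact zone of adjacent labels
  spm <- phantom_spec(n_subjects = 1, labels = 2, seed = 9)
  gtm <- generate_multilabel_phantom(spm)
  cs <- corruption_spec(hole_count = 0, blob_count = 0, boundary_noise = 0,
                        swap_fraction = 0.2, seed = 3)
  pm <- corrupt_prediction(gtm, cs)
  expect_lt(dsc(extract_label_mask(gtm, 1), extract_label_mask(pm, 1)), 1)
})

test_that("intensity images and unaries follow their constructions", {
  sp <- phantom_spec(n_subjects = 1, labels = 2, shape = c(32, 32, 16),
                     base_radius = 4, variability = 0, seed = 0)
  gt <- generate_multilabel_phantom(sp)
  img0 <- synth_intensity_image(gt, c(10, 60, 110), noise_sd = 0, seed = 1)
  expect_setequal(unique(as.vector(img0)), c(10, 60, 110))
  img <- synth_intensity_image(gt, c(10, 60, 110), noise_sd = 4, seed = 1)
  expect_identical(img, synth_intensity_image(gt, c(10, 60, 110), 4, seed = 1))
  for (cl in 0:2) {
    n <- sum(gt$grid == cl)
    expect_lt(abs(mean(img[gt$grid == cl]) - c(10, 60, 110)[cl + 1]),
              3 * 4 / sqrt(n))
  }
  # unaries: one-hot at zero flip, uniform split otherwise
  u0 <- unaries_from_labels(gt, 0, 3)
  expect_equal(range(u0), c(0, 1))
  u <- unaries_from_labels(gt, 0.2, 3)
  sums <- apply(u, 1:3, sum)
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_equal(sort(unique(as.vector(u))), c(0.1, 0.8))
  expect_error(unaries_from_labels(gt, 0.5), class = "ms_config_error")
})
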