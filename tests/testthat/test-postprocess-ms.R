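# one small bank shared across this file (44x44x56 tubes, 64 particles)
# radius 7 keeps the tapered end caps above the rough-opening element, so
# the pre-cleanup step is a no-op on clean shapes
local_bank <- local({
  fam <- lapply(seq(-1.2, 1.2, length.out = 6), function(a)
    tube_phantom(shape = c(44, 44, 56), base_radius = 7, harm_amp = c(a),
                 harm_phase = pi / 3))
  build_model_bank(list(fam), particles = 64, seed = 0, iterations = 15)
})

test_that("the identity pipeline returns the shape it was given", {
  mean_mask <- local_bank$entries[["1"]]$mean_mask
  out <- ms_postprocess_label(mean_mask, mean_mask, ns = 5, lambda = 1)
  expect_gte(dsc(mean_mask, out), 0.99)
})

test_that("holes and spurious blobs are absent from the warped mean", {
  gt <- tube_phantom(shape = c(44, 44, 56), base_radius = 7,
                     harm_amp = c(0.8), harm_phase = pi / 3)
  gtv <- label_volume(array(as.integer(gt$grid), dim(gt$grid)))
  pred <- corrupt_prediction(gtv, corruption_spec(
    hole_count = 3, hole_radius = 2, blob_count = 2, blob_radius = 2,
    boundary_noise = 0, seed = 4))
  pm <- extract_label_mask(pred, 1)
  out <- ms_postprocess_label(pm, local_bank$entries[["1"]]$mean_mask,
                              ns = 5, lambda = 1)
  # no interior holes: every background component touches the border
  bg <- muscleshape:::label_components_cpp(!out$grid, dim(out$grid), 6L)
  bg <- array(bg, dim(out$grid))
  border_ids <- unique(c(bg[1, , ], bg[dim(bg)[1], , ], bg[, 1, ],
                         bg[, dim(bg)[2], ], bg[, , 1], bg[, , dim(bg)[3]]))
  expect_true(all(unique(as.vector(bg)) %in% c(0L, border_ids)))
  # warped mean keeps the mean's topology: one 6-connected component
  lab <- muscleshape:::label_components_cpp(as.logical(out$grid),
                                            dim(out$grid), 6L)
  expect_equal(max(lab), 1L)
})

test_that("near-idempotence: reprocessing the output barely moves it", {
  gt <- tube_phantom(shape = c(44, 44, 56), base_radius = 7,
                     harm_amp = c(0.5), harm_phase = pi / 3)
  gtv <- label_volume(array(as.integer(gt$grid), dim(gt$grid)))
  pred <- corrupt_prediction(gtv, corruption_spec(
    hole_count = 2, hole_radius = 2, blob_count = 1, blob_radius = 2,
    boundary_noise = 0.8, seed = 9))
  pm <- extract_label_mask(pred, 1)
  mean_mask <- local_bank$entries[["1"]]$mean_mask
  once <- ms_postprocess_label(pm, mean_mask, ns = 5, lambda = 1)
  twice <- ms_postprocess_label(once, mean_mask, ns = 5, lambda = 1)
  expect_lt(abs(dsc(extract_label_mask(gtv, 1), once) -
                  dsc(extract_label_mask(gtv, 1), twice)), 0.02)
})

test_that("empty predictions are skipped with a warning", {
  empty <- binary_mask(array(FALSE, c(44, 44, 56)))
  expect_warning(
    out <- ms_postprocess_label(empty, local_bank$entries[["1"]]$mean_mask),
    "skipped")
  expect_false(any(out$grid))
  expect_true(attr(out, "skipped"))
})

test_that("multi-label recomposition partitions claimed voxels", {
  sp <- phantom_spec(n_subjects = 5, labels = 2, shape = c(56, 40, 56),
                     base_radius = 5, variability = 0.8, bend = 1, seed = 2)
  train <- lapply(1:5, function(s) {
    spx <- sp; spx$seed <- sp$seed + s
    generate_multilabel_phantom(spx)
  })
  bank2 <- build_model_bank(train, particles = 64, seed = 0, iterations = 15)
  spt <- sp; spt$seed <- 777
  gt <- generate_multilabel_phantom(spt)
  pred <- corrupt_prediction(gt, corruption_spec(
    hole_count = 2, hole_radius = 2, blob_count = 1, blob_radius = 2,
    boundary_noise = 0.8, swap_fraction = 0.05, seed = 3))
  out <- ms_postprocess_volume(pred, bank2, ns = 5, lambda = 1)
  # output labels never leave the bank's label set; valid partition by
  # construction of a label volume
  expect_true(all(unique(as.vector(out$grid)) %in% c(0L, bank2$labels)))
  lg <- attr(out, "log")
  expect_named(lg, c("1", "2"))
  expect_true(all(is.finite(sapply(lg, `[[`, "cost"))))
  # per-label ASSD does not get worse on average
  rep_raw <- pooled_metrics(gt, pred)
  rep_ms <- pooled_metrics(gt, out)
  sel <- rep_raw$label != "pooled"
  expect_lte(mean(rep_ms$assd[sel]), mean(rep_raw$assd[sel]))
  # single-label volume: recomposition equals the single processed mask
  gt1 <- label_volume(array(as.integer(extract_label_mask(gt, 1)$grid),
                            dim(gt$grid)))
  out1 <- ms_postprocess_volume(gt1, bank2, labels = 1, ns = 5, lambda = 1)
  single <- ms_postprocess_label(extract_label_mask(gt1, 1),
                                 bank2$entries[["1"]]$mean_mask,
                                 ns = 5, lambda = 1)
  expect_identical(out1$grid == 1L, single$grid)
  # missing model is a configuration error
  expect_error(ms_postprocess_volume(pred, bank2, labels = c(1, 2, 3)),
               class = "ms_config_error")
})
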