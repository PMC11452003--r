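#' Per-muscle shape model bank
#'
#' Bundles, per label, the fitted `shape_model` and its reconstructed mean
#' mask, built from a list of gold-standard segmentations. This is the
#' prior consumed by the mean-shape post-processor.
#'
#' @param training list of `label_volume` gold-standard segmentations, or a
#'   list of lists of `binary_mask` (one list per label).
#' @param labels integer labels to model (default: all labels present in
#'   the first training volume).
#' @param particles particles per shape.
#' @param seed RNG seed.
#' @param ... passed to [optimize_correspondences()].
#' @return a `ms_model_bank`: per-label list(model, mean_mask, ps) plus
#'   provenance (labels, particles, seed).
#' @export
build_model_bank <- function(training, labels = NULL, particles = 256,
                             seed = 0, ...) {
  if (inherits(training[[1]], "label_volume")) {
    if (is.null(labels))
      labels <- setdiff(sort(unique(as.vector(training[[1]]$grid))), 0L)
    per_label <- lapply(labels, function(l)
      lapply(training, extract_label_mask, label = l))
  } else {
    per_label <- training
    if (is.null(labels)) labels <- seq_along(per_label)
  }
  entries <- list()
  for (q in seq_along(labels)) {
    masks <- per_label[[q]]
    ps <- optimize_correspondences(masks, m = particles, seed = seed, ...)
    model <- build_shape_model(ps)
    mean_mask <- reconstruct_mean_mask(model, ps)
    if (!any(mean_mask$grid))
      stop_ms("ms_reconstruction_error", "empty mean mask for label %d",
              labels[q])
    entries[[as.character(labels[q])]] <-
      list(model = model, mean_mask = mean_mask, ps = ps)
  }
  structure(list(entries = entries, labels = labels, particles = particles,
                 seed = seed, n_training = length(per_label[[1]])),
            class = "ms_model_bank")
}

#' @export
print.ms_model_bank <- function(x, ...) {
  cat(sprintf("<ms_model_bank> %d labels (%s), %d training shapes, %d particles\n",
              length(x$labels), paste(x$labels, collapse = ","),
              x$n_training, x$particles))
  invisible(x)
}

#' Mean-shape post-processing of one predicted mask
#'
#' The headline pipeline for a single muscle: rough 3D cleanup of the
#' prediction, rigid ICP alignment of the mean shape onto the cleaned
#' prediction (fixed = prediction, moving = mean shape), nodal-grid
#' deformable registration of the aligned mean onto the prediction, and
#' warping of the aligned mean through the recovered field. The registered
#' mean shape -- not the prediction -- is the output, so blank regions are
#' filled and spurious structures are absent by construction.
#'
#' @param pred_mask predicted `binary_mask` for one label.
#' @param mean_mask the label's mean-shape `binary_mask`.
#' @param ns nodal spacing in voxels.
#' @param lambda smoothing coefficient or "auto".
#' @param cleanup_radius radius of the rough 3D opening (voxels); 0 skips.
#' @param ... further arguments to [deformable_register()].
#' @return warped mean `binary_mask` with attributes "soft" (pre-threshold
#'   values), "icp" (the rigid transform) and "registration" (the
#'   `registration_result`). An empty (post-cleanup) prediction yields an
#'   empty mask with attribute "skipped" = TRUE and a warning.
#' @export
ms_postprocess_label <- function(pred_mask, mean_mask, ns = 5,
                                 lambda = "auto", cleanup_radius = 1, ...) {
  stopifnot(inherits(pred_mask, "binary_mask"), inherits(mean_mask, "binary_mask"))
  pred <- if (cleanup_radius >= 1) cleanup_3d(pred_mask, cleanup_radius) else pred_mask
  if (!any(pred$grid)) {
    warning("empty prediction after cleanup: label skipped")
    out <- binary_mask(array(FALSE, dim(pred_mask$grid)), pred_mask$spacing,
                       pred_mask$origin)
    attr(out, "soft") <- array(0, dim(pred_mask$grid))
    attr(out, "skipped") <- TRUE
    return(out)
  }
  fixed_cloud <- surface_voxels(pred)
  moving_cloud <- surface_voxels(mean_mask)
  tr <- icp_rigid(subsample_rows(moving_cloud, 1200),
                  subsample_rows(fixed_cloud, 2500))
  # surface RMS cannot tell a near-symmetric flip of an elongated shape
  # from the true pose; disambiguate the converged ICP basins by volumetric
  # overlap with the prediction
  cands <- attr(tr, "candidates")
  if (is.null(cands)) cands <- list(tr)
  rms_vals <- vapply(cands, function(x) attr(x, "rms"), 0)
  keep <- which(rms_vals <= 1.25 * min(rms_vals))
  aligned <- NULL
  best_dsc <- -1
  for (q in keep) {
    al_q <- apply_rigid(mean_mask, cands[[q]], target = pred)
    d_q <- dsc(pred, al_q)
    if (d_q > best_dsc) { best_dsc <- d_q; aligned <- al_q; tr <- cands[[q]] }
  }
  if (!any(aligned$grid)) {
    warning("mean shape left the prediction grid after rigid alignment")
    out <- binary_mask(array(FALSE, dim(pred_mask$grid)), pred_mask$spacing,
                       pred_mask$origin)
    attr(out, "soft") <- array(0, dim(pred_mask$grid))
    attr(out, "skipped") <- TRUE
    return(out)
  }
  reg <- deformable_register(fixed = pred, moving = aligned, ns = ns,
                             lambda = lambda, ...)
  out <- apply_displacement(aligned, reg$field)
  attr(out, "icp") <- tr
  attr(out, "registration") <- reg
  out
}

#' Mean-shape post-processing of a multi-label volume
#'
#' Runs [ms_postprocess_label()] per label (ascending label id) and
#' recomposes a single label volume. Voxels claimed by several warped means
#' go to the label with the highest pre-threshold soft value (ties to the
#' lowest label id); unclaimed voxels stay background.
#'
#' @param pred predicted `label_volume`.
#' @param bank a `ms_model_bank` covering the labels to process.
#' @param labels labels to process (default: bank labels).
#' @param ns,lambda,cleanup_radius,... forwarded per label.
#' @return post-processed `label_volume` with attribute "log": per-label
#'   ICP transforms, registration costs and chosen lambdas.
#' @export
ms_postprocess_volume <- function(pred, bank, labels = bank$labels, ns = 5,
                                  lambda = "auto", cleanup_radius = 1, ...) {
  stopifnot(inherits(pred, "label_volume"), inherits(bank, "ms_model_bank"))
  missing_models <- setdiff(labels, bank$labels)
  if (length(missing_models))
    stop_ms("ms_config_error", "no model for label(s) %s",
            paste(missing_models, collapse = ","))
  d <- dim(pred$grid)
  best_soft <- array(0, d)
  out <- array(0L, d)
  log <- list()
  for (l in sort(as.integer(labels))) {
    pm <- extract_label_mask(pred, l)
    res <- ms_postprocess_label(pm, bank$entries[[as.character(l)]]$mean_mask,
                                ns = ns, lambda = lambda,
                                cleanup_radius = cleanup_radius, ...)
    soft <- attr(res, "soft")
    reg <- attr(res, "registration")
    log[[as.character(l)]] <- list(
      skipped = isTRUE(attr(res, "skipped")),
      icp = attr(res, "icp"),
      cost = if (!is.null(reg)) reg$cost else NA_real_,
      lambda = if (!is.null(reg)) reg$lambda else NA_real_,
      min_jacobian = if (!is.null(reg)) reg$min_jacobian else NA_real_)
    claim <- res$grid & (soft > best_soft) # strict: ties keep lower label
    out[claim] <- l
    best_soft <- pmax(best_soft, ifelse(res$grid, soft, 0))
  }
  vol <- label_volume(out, pred$spacing, pred$origin)
  attr(vol, "log") <- log
  vol
}
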