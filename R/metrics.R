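#' Segmentation evaluation metrics
#'
#' Dice similarity coefficient, signed relative volume error, Hausdorff
#' distance and average symmetric surface distance, all honouring the voxel
#' spacing (distances in mm; surfaces are the voxel centres with at least
#' one background 6-neighbour).
#'
#' @param ref,pred `binary_mask` objects on congruent grids.
#' @return `dsc` a fraction in [0,1]; `rve` a signed fraction; `hausdorff`
#'   and `assd` distances in mm.
#' @name metrics
NULL

check_congruent <- function(ref, pred) {
  if (!same_geometry(ref, pred))
    stop_ms("ms_geometry_error", "masks must share grid geometry")
}

#' @rdname metrics
#' @details `dsc` of two empty masks is defined as 1.0 (and flagged via
#'   attribute "degenerate" = TRUE) to avoid 0/0.
#' @export
dsc <- function(ref, pred) {
  check_congruent(ref, pred)
  nr <- sum(ref$grid)
  np <- sum(pred$grid)
  if (nr + np == 0) return(structure(1.0, degenerate = TRUE))
  2 * sum(ref$grid & pred$grid) / (nr + np)
}

#' @rdname metrics
#' @export
rve <- function(ref, pred) {
  check_congruent(ref, pred)
  vr <- sum(ref$grid)
  if (vr == 0) stop_ms("ms_degenerate_mask_error", "reference mask is empty")
  (sum(pred$grid) - vr) / vr
}

# distances (mm) from every surface voxel of `a` to the surface of `b`
surface_dists <- function(a, b) {
  sg_b <- surface_grid(b$grid)
  dmap <- dist_to(sg_b, a$spacing)
  dmap[surface_grid(a$grid)]
}

#' @rdname metrics
#' @export
hausdorff <- function(ref, pred) {
  check_congruent(ref, pred)
  if (!any(ref$grid) || !any(pred$grid))
    stop_ms("ms_empty_mask_error", "empty mask")
  max(max(surface_dists(ref, pred)), max(surface_dists(pred, ref)))
}

#' @rdname metrics
#' @export
assd <- function(ref, pred) {
  check_congruent(ref, pred)
  if (!any(ref$grid) || !any(pred$grid))
    stop_ms("ms_empty_mask_error", "empty mask")
  dr <- surface_dists(ref, pred) # ref surface -> pred surface
  dp <- surface_dists(pred, ref)
  (sum(dr) + sum(dp)) / (length(dr) + length(dp))
}

#' Per-label and pooled metrics report
#'
#' Computes the four metrics per label and on the pooled label set (all
#' listed labels merged into one mask). The pooled Hausdorff distance is
#' omitted by default since a pooled muscle region is much larger and
#' longer than any single muscle, making the worst-case surface distance
#' uninformative.
#'
#' @param ref,pred `label_volume` objects on congruent grids.
#' @param labels labels to evaluate (default: labels present in ref).
#' @param pooled_hd include the pooled HD anyway.
#' @return a `metrics_report` data.frame with one row per label plus a
#'   "pooled" row; columns label, dsc, rve, hd, assd.
#' @export
pooled_metrics <- function(ref, pred, labels = NULL, pooled_hd = FALSE) {
  stopifnot(inherits(ref, "label_volume"), inherits(pred, "label_volume"))
  if (!same_geometry(ref, pred))
    stop_ms("ms_geometry_error", "volumes must share grid geometry")
  if (is.null(labels))
    labels <- setdiff(sort(unique(as.vector(ref$grid))), 0L)
  rows <- list()
  for (l in sort(as.integer(labels))) {
    rm <- extract_label_mask(ref, l)
    pm <- extract_label_mask(pred, l)
    if (!any(rm$grid)) {
      warning(sprintf("label %d absent in reference: skipped", l))
      next
    }
    have_pred <- any(pm$grid)
    rows[[length(rows) + 1]] <- data.frame(
      label = as.character(l), dsc = dsc(rm, pm), rve = rve(rm, pm),
      hd = if (have_pred) hausdorff(rm, pm) else NA_real_,
      assd = if (have_pred) assd(rm, pm) else NA_real_)
  }
  pr <- binary_mask(array(ref$grid %in% labels, dim(ref$grid)), ref$spacing, ref$origin)
  pp <- binary_mask(array(pred$grid %in% labels, dim(pred$grid)), pred$spacing, pred$origin)
  pooled_ok <- any(pr$grid) && any(pp$grid)
  rows[[length(rows) + 1]] <- data.frame(
    label = "pooled", dsc = dsc(pr, pp),
    rve = if (any(pr$grid)) rve(pr, pp) else NA_real_,
    hd = if (pooled_hd && pooled_ok) hausdorff(pr, pp) else NA_real_,
    assd = if (pooled_ok) assd(pr, pp) else NA_real_)
  out <- do.call(rbind, rows)
  attr(out, "spacing") <- ref$spacing
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Wilcoxon signed-rank paired test
#'
#' Two-sided paired test on `a - b`. Zero differences are dropped before
#' ranking. For n <= 12 remaining pairs the p-value is exact, by full
#' enumeration of the 2^n sign assignments over the observed (possibly
#' tied) ranks; for larger n a normal approximation with tie and continuity
#' corrections is used.
#'
#' @param a,b equal-length paired samples (>= 5 non-zero differences).
#' @return list with `statistic` (W+, the positive-rank sum), `p.value`
#'   and `n` (pairs used).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_ms("ms_degenerate_sample_error", "all differences are zero")
  if (n < 5) stop_ms("ms_degenerate_sample_error",
                     "need >= 5 non-zero differences, got %d", n)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12) {
    # exact two-sided p by enumeration of all sign assignments
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
  }
  list(statistic = W, p.value = p, n = n)
}
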