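#' Parameters of the slice-wise 2D morphological pipeline
#'
#' Defaults follow the published tuning of the comparator: disk radius 3 for
#' erosion/dilation, 8-connectivity for component labelling, a 5x5 uniform
#' smoothing kernel and a 0.5 threshold.
#'
#' @param r erode/dilate disk radius in pixels (>= 1).
#' @param conn connectivity for 2D components, 4 or 8.
#' @param w uniform smoothing kernel width in pixels.
#' @param threshold smoothing threshold in (0, 1).
#' @param order operation order: "table" (erode, label, keep largest,
#'   dilate, fill, smooth) or "fill_first" (fill holes before dilation).
#' @return a `slice2d_params` list.
#' @export
slice2d_params <- function(r = 3, conn = 8, w = 5, threshold = 0.5,
                           order = c("table", "fill_first")) {
  if (r < 1) stop_ms("ms_config_error", "r must be >= 1")
  if (!conn %in% c(4, 8)) stop_ms("ms_config_error", "conn must be 4 or 8")
  if (threshold <= 0 || threshold >= 1)
    stop_ms("ms_config_error", "threshold must be in (0,1)")
  structure(list(r = r, conn = conn, w = w, threshold = threshold,
                 order = match.arg(order)), class = "slice2d_params")
}

# discrete disk morphology on a 2D slice via the 3D machinery (d3 = 1)
erode_disk2d <- function(g, r) {
  d3 <- array(g, c(dim(g), 1L))
  er <- edt_squared(!d3, dim(d3), c(1, 1, 1)) > r * r
  matrix(er, nrow(g), ncol(g))
}

dilate_disk2d <- function(g, r) {
  if (!any(g)) return(g & FALSE)
  d3 <- array(g, c(dim(g), 1L))
  di <- edt_squared(as.logical(d3), dim(d3), c(1, 1, 1)) <= r * r
  matrix(di, nrow(g), ncol(g))
}

label2d <- function(g, conn) {
  d3 <- array(g, c(dim(g), 1L))
  matrix(label_components_cpp(as.logical(d3), dim(d3), as.integer(conn)),
         nrow(g), ncol(g))
}

fill_holes2d <- function(g) {
  # background components not connected to the border are holes
  bg <- label2d(!g, 4)
  border <- unique(c(bg[1, ], bg[nrow(g), ], bg[, 1], bg[, ncol(g)]))
  border <- setdiff(border, 0L)
  filled <- g | !(bg %in% c(0L, border))
  matrix(filled, nrow(g), ncol(g))
}

keep_largest2d <- function(g, conn) {
  lab <- label2d(g, conn)
  if (max(lab) == 0L) return(g & FALSE)
  sizes <- tabulate(lab[lab > 0L])
  # ties: tabulate + which.max keeps the lowest component id, i.e. the
  # first component in scan order
  g & (lab == which.max(sizes))
}

smooth_threshold2d <- function(g, w, threshold) {
  counts <- box_sum2d(matrix(as.integer(g), nrow(g), ncol(g)), as.integer(w))
  counts > threshold * w * w
}

#' 2D morphological post-processing of one slice
#'
#' Operator chain (in the "table" order): erosion by a discrete disk of
#' radius r, connected-component labelling, retention of the single largest
#' component, dilation by the same disk, hole filling, and smoothing by a
#' uniform w x w convolution (zero padded) thresholded at `threshold`. A
#' slice emptied by the erosion stays empty.
#'
#' @param mask2d logical matrix (one label on one slice).
#' @param p a `slice2d_params`.
#' @return logical matrix.
#' @export
postprocess_slice <- function(mask2d, p = slice2d_params()) {
  stopifnot(is.matrix(mask2d), inherits(p, "slice2d_params"))
  g <- erode_disk2d(mask2d, p$r)
  if (!any(g)) return(g)
  g <- keep_largest2d(g, p$conn)
  if (p$order == "table") {
    g <- dilate_disk2d(g, p$r)
    g <- fill_holes2d(g)
  } else {
    g <- fill_holes2d(g)
    g <- dilate_disk2d(g, p$r)
  }
  smooth_threshold2d(g, p$w, p$threshold)
}

#' Slice-wise 2D post-processing of a multi-label volume
#'
#' Extracts each label, applies [postprocess_slice()] to every axial slice
#' (third axis), and recomposes the labels. Because each label keeps a
#' single component per slice, the per-label slice results cannot overlap
#' with themselves; voxels claimed by several labels go to the label whose
#' smoothed value is largest (ties to the lowest label id).
#'
#' @param pred a `label_volume`.
#' @param p a `slice2d_params`.
#' @param labels labels to process; default all present.
#' @return post-processed `label_volume`.
#' @export
postprocess_2d_volume <- function(pred, p = slice2d_params(), labels = NULL) {
  stopifnot(inherits(pred, "label_volume"))
  if (is.null(labels))
    labels <- setdiff(sort(unique(as.vector(pred$grid))), 0L)
  d <- dim(pred$grid)
  out <- array(0L, d)
  best <- array(0, d)
  for (l in sort(as.integer(labels))) {
    res <- array(FALSE, d)
    soft <- array(0, d)
    for (k in seq_len(d[3])) {
      sl <- pred$grid[, , k] == l
      if (!any(sl)) next
      g <- erode_disk2d(sl, p$r)
      if (!any(g)) next
      g <- keep_largest2d(g, p$conn)
      if (p$order == "table") {
        g <- dilate_disk2d(g, p$r); g <- fill_holes2d(g)
      } else {
        g <- fill_holes2d(g); g <- dilate_disk2d(g, p$r)
      }
      counts <- box_sum2d(matrix(as.integer(g), d[1], d[2]), as.integer(p$w))
      res[, , k] <- counts > p$threshold * p$w^2
      soft[, , k] <- counts / p$w^2
    }
    claim <- res & soft > best
    out[claim] <- l
    best <- pmax(best, ifelse(res, soft, 0))
  }
  label_volume(out, pred$spacing, pred$origin)
}
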