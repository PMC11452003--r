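#' Label volumes and binary masks
#'
#' A `label_volume` is the pipeline's main currency: a 3D array of
#' non-negative integer labels (0 = background) together with the voxel
#' spacing (mm, strictly positive per axis) and the world coordinate of voxel
#' `(0,0,0)`. Geometry is axis-aligned: `world = origin + index * spacing`
#' with 0-based indices. A `binary_mask` is the same thing with a logical
#' grid, normally obtained by selecting one label.
#'
#' @param grid 3D array (integer-valued for volumes, logical for masks).
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @return An object of class `label_volume` or `binary_mask`.
#' @examples
#' v <- label_volume(array(0:1, c(4, 4, 4)), spacing = c(1, 1, 1))
#' m <- extract_label_mask(v, 1)
#' sum(m$grid)
#' @export
label_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3)
  if (any(spacing <= 0)) stop_ms("ms_geometry_error", "spacing must be strictly positive")
  g <- grid
  storage.mode(g) <- "integer"
  if (any(g < 0L, na.rm = TRUE)) stop_ms("ms_format_error", "labels must be non-negative")
  structure(list(grid = g, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "label_volume")
}

#' @rdname label_volume
#' @export
binary_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(grid)) == 3)
  if (any(spacing <= 0)) stop_ms("ms_geometry_error", "spacing must be strictly positive")
  g <- grid
  storage.mode(g) <- "logical"
  structure(list(grid = g, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @export
print.label_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$grid))), 0L)
  cat(sprintf("<label_volume> %s voxels, spacing %s mm, labels {%s}\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(labs, collapse = ",")))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$grid), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$grid)))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read and write label volumes
#'
#' NIfTI files (`.nii`, `.nii.gz`) are handled through the RNifti library;
#' MetaImage headers (`.mhd` with a separate `.raw`, or local-data `.mha`)
#' are parsed directly. Only axis-aligned geometry is supported: a rotated
#' orientation matrix raises an `ms_orientation_error`, and non-integer voxel
#' data raises an `ms_format_error`.
#'
#' @param path file path ending in `.nii`, `.nii.gz`, `.mhd` or `.mha`.
#' @param vol a `label_volume` or `binary_mask` to write.
#' @return `read_label_volume` returns a `label_volume`.
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop_ms("ms_io_error", "file not found: %s", path)
  if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE)) {
    return(read_metaimage(path))
  }
  img <- RNifti::readNifti(path)
  x <- RNifti::xform(img)
  rot <- x[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (max(abs(offdiag)) > 1e-4 * max(abs(diag(rot))))
    stop_ms("ms_orientation_error",
            "non-axis-aligned orientation matrix is not supported")
  g <- array(as.numeric(img), dim(img)[1:3])
  if (max(abs(g - round(g))) > 1e-6)
    stop_ms("ms_format_error", "volume has non-integer voxel values")
  sp <- abs(RNifti::pixdim(img))[1:3]
  label_volume(array(as.integer(round(g)), dim(g)), spacing = sp,
               origin = as.numeric(x[1:3, 4]))
}

#' @rdname read_label_volume
#' @export
write_label_volume <- function(vol, path) {
  if (grepl("\\.(mhd|mha)$", path, ignore.case = TRUE)) {
    return(write_metaimage(vol, path))
  }
  g <- vol$grid
  storage.mode(g) <- "integer"
  img <- RNifti::asNifti(g)
  RNifti::pixdim(img) <- vol$spacing
  # record the origin through the sform
  RNifti::sform(img) <- structure(
    rbind(cbind(diag(vol$spacing), vol$origin), c(0, 0, 0, 1)), code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Extract one label as a binary mask
#'
#' @param vol a `label_volume`.
#' @param label integer label id (>= 1). A label absent from the volume
#'   yields an empty (all-FALSE) mask, not an error.
#' @return `binary_mask` with the parent's spacing and origin.
#' @export
extract_label_mask <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  if (label < 1) stop_ms("ms_format_error", "label must be >= 1")
  binary_mask(vol$grid == as.integer(label), vol$spacing, vol$origin)
}

#' Surface voxels of a mask as a world-coordinate point cloud
#'
#' A foreground voxel is a surface voxel when at least one of its six
#' face-neighbours is background; voxels on the array border always count.
#' Points are voxel centres in mm, in lexicographic (column-major) index
#' order, so the output is deterministic.
#'
#' @param mask a non-empty `binary_mask`.
#' @return numeric matrix (n x 3) of world coordinates in mm.
#' @export
surface_voxels <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$grid)) stop_ms("ms_empty_mask_error", "mask is empty")
  idx_to_world(which_idx3(surface_grid(mask$grid)), mask$spacing, mask$origin)
}

# logical array of surface voxels (6-neighbour rule, border = surface)
surface_grid <- function(g) {
  d <- dim(g)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  core <- function(di, dj, dk)
    pad[(2 + di):(d[1] + 1 + di), (2 + dj):(d[2] + 1 + dj), (2 + dk):(d[3] + 1 + dk)]
  all_nb <- core(1, 0, 0) & core(-1, 0, 0) & core(0, 1, 0) &
    core(0, -1, 0) & core(0, 0, 1) & core(0, 0, -1)
  g & !all_nb
}

#' Signed distance field of a binary mask
#'
#' Negative inside, positive outside, in mm. The magnitude at a voxel is its
#' exact Euclidean distance to the nearest voxel of the other phase, pulled
#' back by half the smallest voxel step so the zero level set sits at the
#' interface between boundary foreground voxels and the adjacent background;
#' thresholding the field at zero therefore reproduces the mask exactly.
#'
#' @param mask a `binary_mask` that is neither empty nor all-foreground.
#' @return object of class `sdf`: list(grid, spacing, origin) with a numeric
#'   grid in mm.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  if (!any(g) || all(g))
    stop_ms("ms_degenerate_mask_error", "mask must contain both phases")
  d_out <- dist_to(g, mask$spacing)        # distance to nearest foreground
  d_in <- dist_to(!g, mask$spacing)        # distance to nearest background
  h <- min(mask$spacing) / 2
  phi <- ifelse(g, -(d_in - h), d_out - h)
  structure(list(grid = array(phi, dim(g)), spacing = mask$spacing,
                 origin = mask$origin), class = "sdf")
}

#' Rough 3D morphological cleanup (opening)
#'
#' Morphological opening with the discrete radius-r ball of the Chebyshev
#' metric -- a (2r+1)^3 box -- as structuring element: erosion followed by
#' dilation with the same element. This removes isolated specks and
#' components thinner than the element while leaving convex bodies (and in
#' particular their corners) untouched, which is the behaviour wanted from
#' a "rough" cleanup of predicted masks; a Euclidean ball would round
#' corners off. Outside the array is treated as foreground for the erosion
#' and background for the dilation, so shapes touching the border are not
#' eaten away.
#'
#' @param mask a `binary_mask` (may be empty).
#' @param radius element radius in voxels, >= 1.
#' @return cleaned `binary_mask`.
#' @export
cleanup_3d <- function(mask, radius = 1) {
  stopifnot(inherits(mask, "binary_mask"))
  if (radius < 1) stop_ms("ms_config_error", "radius must be >= 1")
  if (!any(mask$grid)) return(mask)
  er <- erode_box(mask$grid, radius)
  binary_mask(dilate_box(er, radius), mask$spacing, mask$origin)
}

# shift a logical array by one voxel along an axis, padding with `fill`
shift1 <- function(g, ax, dir, fill) {
  d <- dim(g)
  n <- d[ax]
  out <- array(fill, d)
  src <- dst <- list(TRUE, TRUE, TRUE)
  if (dir > 0) { src[[ax]] <- 1:(n - 1); dst[[ax]] <- 2:n }
  else { src[[ax]] <- 2:n; dst[[ax]] <- 1:(n - 1) }
  do.call(`[<-`, c(list(out), dst,
                   list(do.call(`[`, c(list(g), src, list(drop = FALSE))))))
}

# separable box (Chebyshev-ball) morphology, r-fold unit-box passes
erode_box <- function(g, r) {
  for (q in seq_len(r)) for (ax in 1:3)
    g <- g & shift1(g, ax, 1, TRUE) & shift1(g, ax, -1, TRUE)
  g
}

dilate_box <- function(g, r) {
  for (q in seq_len(r)) for (ax in 1:3)
    g <- g | shift1(g, ax, 1, FALSE) | shift1(g, ax, -1, FALSE)
  g
}
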