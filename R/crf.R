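#' Fully connected CRF parameters
#'
#' Gaussian-kernel pairwise potentials: an appearance kernel (weight `W1`,
#' spatial bandwidth `theta_alpha` pixels, intensity bandwidth `theta_beta`)
#' and a smoothness kernel (weight `W2`, spatial bandwidth `theta_gamma`
#' pixels), with Potts label compatibility. Defaults are the published
#' setting W1 = theta_alpha = theta_beta = 10 and W2 = theta_gamma = 1,
#' with 5 mean-field iterations.
#'
#' @param W1,W2 non-negative kernel weights.
#' @param theta_alpha,theta_beta,theta_gamma positive bandwidths.
#' @param iterations mean-field iterations (>= 1).
#' @param max_pixels exact-inference cap per slice region.
#' @return a `crf_params` list.
#' @export
crf_params <- function(W1 = 10, theta_alpha = 10, theta_beta = 10,
                       W2 = 1, theta_gamma = 1, iterations = 5,
                       max_pixels = 4096) {
  if (any(c(theta_alpha, theta_beta, theta_gamma) <= 0))
    stop_ms("ms_config_error", "bandwidths must be positive")
  if (any(c(W1, W2) < 0) || iterations < 1)
    stop_ms("ms_config_error", "weights must be >= 0 and iterations >= 1")
  structure(list(W1 = W1, theta_alpha = theta_alpha, theta_beta = theta_beta,
                 W2 = W2, theta_gamma = theta_gamma,
                 iterations = as.integer(iterations),
                 max_pixels = as.integer(max_pixels)), class = "crf_params")
}

# flatten a slice into pixel features
slice_features <- function(nr, nc) {
  cbind(rep(seq_len(nr) - 1, nc), rep(seq_len(nc) - 1, each = nr))
}

#' Gibbs energy of a labelling under the fully connected CRF
#'
#' Exact double sum: unary terms `-log p_i(x_i)` plus Potts pairwise terms
#' (the Gaussian kernel evaluated for every unordered pixel pair with
#' differing labels). A zero probability at an assigned label yields +Inf.
#'
#' @param labels integer matrix of 0-based class labels.
#' @param unary 3D array (rows x cols x classes) of per-pixel class
#'   probabilities.
#' @param image numeric matrix of pixel intensities.
#' @param p a `crf_params`.
#' @return scalar energy.
#' @export
gibbs_energy <- function(labels, unary, image, p = crf_params()) {
  d <- dim(unary)
  stopifnot(all(dim(labels) == d[1:2]), all(dim(image) == d[1:2]))
  crf_gibbs_energy_cpp(as.integer(labels), matrix(unary, d[1] * d[2], d[3]),
                       slice_features(d[1], d[2]), as.numeric(image),
                       p$W1, p$theta_alpha, p$theta_beta, p$W2, p$theta_gamma)
}

#' Mean-field inference on one slice
#'
#' Exact O(n^2) pairwise message passing with synchronous updates
#' initialized at the unary distribution:
#' `Q_i(l) <- (1/Z_i) p_i(l) exp(-sum_j k(i,j) (1 - Q_j(l)))`.
#'
#' @param unary 3D array (rows x cols x classes), probabilities summing to
#'   one per pixel.
#' @param image numeric intensity matrix congruent with the unaries.
#' @param p a `crf_params`; slices larger than `p$max_pixels` pixels raise
#'   an error advising tiling.
#' @return list with `Q` (same shape as unary) and `labels` (0-based MAP
#'   matrix).
#' @export
mean_field_infer <- function(unary, image, p = crf_params()) {
  d <- dim(unary)
  stopifnot(length(d) == 3, all(dim(image) == d[1:2]))
  n <- d[1] * d[2]
  if (n > p$max_pixels)
    stop_ms("ms_scale_error",
            "slice has %d pixels, above the exact-inference cap %d; tile the slice",
            n, p$max_pixels)
  U <- matrix(unary, n, d[3])
  sums <- rowSums(U)
  if (max(abs(sums - 1)) > 1e-6)
    stop_ms("ms_input_error", "per-pixel probabilities must sum to 1")
  Q <- crf_mean_field_cpp(U, slice_features(d[1], d[2]), as.numeric(image),
                          p$W1, p$theta_alpha, p$theta_beta, p$W2,
                          p$theta_gamma, p$iterations)
  labels <- matrix(max.col(Q, ties.method = "first") - 1L, d[1], d[2])
  list(Q = array(Q, d), labels = labels)
}

#' CRF post-processing of a probability volume
#'
#' Applies [mean_field_infer()] independently to every axial slice (third
#' axis) of a per-class probability volume and stacks the MAP labels.
#'
#' @param prob 4D array (x, y, z, class), probabilities summing to one per
#'   voxel (tolerance 1e-6).
#' @param intensity 3D numeric array, the image the pairwise terms read.
#' @param p a `crf_params`.
#' @param spacing,origin geometry of the output volume.
#' @return a `label_volume` of MAP labels.
#' @export
crf_postprocess_volume <- function(prob, intensity, p = crf_params(),
                                   spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  d <- dim(prob)
  stopifnot(length(d) == 4, all(dim(intensity) == d[1:3]))
  sums <- apply(prob, c(1, 2, 3), sum)
  if (max(abs(sums - 1)) > 1e-6)
    stop_ms("ms_input_error", "probability channels must sum to 1 per voxel")
  out <- array(0L, d[1:3])
  for (k in seq_len(d[3])) {
    res <- mean_field_infer(array(prob[, , k, ], c(d[1], d[2], d[4])),
                            intensity[, , k], p)
    out[, , k] <- res$labels
  }
  label_volume(out, spacing, origin)
}
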