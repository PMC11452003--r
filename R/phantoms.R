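#' Phantom specifications
#'
#' `phantom_spec` describes a family of elongated, muscle-like tubes used to
#' emulate an imaging cohort: every subject is a tapered tube aligned with
#' the third array axis whose per-slice radius is a shared base profile plus
#' a smooth, low-frequency, per-subject perturbation, optionally bent by a
#' smooth centerline offset. `corruption_spec` describes how a gold-standard
#' phantom is degraded into a "prediction", reproducing the two error modes
#' seen in segmenter output: blank regions (spherical voids) and
#' mis-segmentation (spurious blobs near the shape, boundary noise, and
#' label swaps in the contact zone of adjacent labels).
#'
#' @param n_subjects number of family members.
#' @param labels number of tube labels in a multi-label phantom (>= 2 there).
#' @param shape volume dimensions in voxels.
#' @param base_radius peak radius of the base profile, voxels.
#' @param variability amplitude of the per-subject radius perturbation,
#'   voxels (low-order cosine basis, at most 4 harmonics).
#' @param bend amplitude of the smooth centerline offset, voxels.
#' @param seed integer RNG seed; every generator is a pure function of
#'   (spec, seed).
#' @return a `phantom_spec` / `corruption_spec` list.
#' @export
phantom_spec <- function(n_subjects = 10, labels = 1, shape = c(64, 64, 96),
                         base_radius = 8, variability = 1.5, bend = 2,
                         seed = 0) {
  stopifnot(n_subjects >= 1, base_radius > 0, variability >= 0, bend >= 0)
  structure(list(n_subjects = n_subjects, labels = labels, shape = shape,
                 base_radius = base_radius, variability = variability,
                 bend = bend, seed = seed), class = "phantom_spec")
}

#' @rdname phantom_spec
#' @param hole_count,hole_radius number and radius (voxels) of spherical
#'   voids punched into each label (blank regions).
#' @param blob_count,blob_radius number and radius of spurious spheres of a
#'   label placed 2-5 voxels outside it (mis-segmentation).
#' @param boundary_noise amplitude in voxels of the band around the surface
#'   in which voxels are randomly flipped.
#' @param swap_fraction fraction of a label's voxels in the contact zone of
#'   an adjacent label that are reassigned to that label.
#' @export
corruption_spec <- function(hole_count = 3, hole_radius = 4, blob_count = 3,
                            blob_radius = 3, boundary_noise = 1.5,
                            swap_fraction = 0, seed = 0) {
  stopifnot(hole_count >= 0, blob_count >= 0, boundary_noise >= 0,
            swap_fraction >= 0, swap_fraction <= 1)
  structure(list(hole_count = hole_count, hole_radius = hole_radius,
                 blob_count = blob_count, blob_radius = blob_radius,
                 boundary_noise = boundary_noise,
                 swap_fraction = swap_fraction, seed = seed),
            class = "corruption_spec")
}

# per-slice radius (voxels) for subject-level parameters
# t in (0,1): base profile is a sine-arch taper of the peak radius
tube_radius_profile <- function(t, base_radius, harm_amp, harm_phase) {
  r <- base_radius * (0.35 + 0.65 * sin(pi * t))
  if (length(harm_amp)) {
    for (h in seq_along(harm_amp))
      r <- r + harm_amp[h] * cos(2 * pi * h * t + harm_phase[h])
  }
  pmax(r, 0.8)
}

# draw the per-subject low-dimensional shape parameters
draw_subject_params <- function(spec) {
  nh <- 4
  amp <- rnorm(nh, 0, spec$variability / sqrt(nh))
  phase <- runif(nh, 0, 2 * pi)
  bx <- rnorm(1, 0, spec$bend / 2)
  by <- rnorm(1, 0, spec$bend / 2)
  list(amp = amp, phase = phase, bend = c(bx, by))
}

# rasterise one tube: centre (cx, cy) per slice, radius r(z)
rasterise_tube <- function(shape, centre_xy, bend, radii, zrange) {
  d <- shape
  g <- array(FALSE, d)
  x <- seq_len(d[1]) - 1
  y <- seq_len(d[2]) - 1
  for (k in zrange) {
    t <- (k - zrange[1] + 0.5) / length(zrange)
    cx <- centre_xy[1] + bend[1] * sin(pi * t)
    cy <- centre_xy[2] + bend[2] * sin(pi * t)
    r <- radii[k - zrange[1] + 1]
    dx2 <- (x - cx)^2
    dy2 <- (y - cy)^2
    g[, , k + 1] <- outer(dx2, dy2, `+`) <= r * r
  }
  g
}

subject_mask_grid <- function(spec, pars, centre_xy) {
  d <- spec$shape
  margin <- 3L
  if (d[3] < 2L * margin + 4L)
    stop_ms("ms_spec_error", "volume too thin along the tube axis")
  zrange <- seq.int(margin, d[3] - 1L - margin)
  t <- (seq_along(zrange) - 0.5) / length(zrange)
  radii <- tube_radius_profile(t, spec$base_radius, pars$amp, pars$phase)
  maxr <- max(radii) + max(abs(pars$bend))
  if (centre_xy[1] - maxr < 2 || centre_xy[1] + maxr > d[1] - 3 ||
      centre_xy[2] - maxr < 2 || centre_xy[2] + maxr > d[2] - 3)
    stop_ms("ms_spec_error", "phantom shape overflows the volume")
  rasterise_tube(d, centre_xy, pars$bend, radii, zrange)
}

#' Deterministic single tube phantom
#'
#' Builds one tube mask from explicit shape parameters (no RNG): useful for
#' one-parameter families where the generative parameter must be known
#' exactly.
#'
#' @param shape volume dimensions.
#' @param base_radius peak radius, voxels.
#' @param harm_amp,harm_phase cosine-harmonic amplitudes and phases of the
#'   radius profile (up to 4 harmonics).
#' @param bend centerline offset amplitudes (x, y), voxels.
#' @return a `binary_mask`.
#' @export
tube_phantom <- function(shape = c(64, 64, 96), base_radius = 8,
                         harm_amp = numeric(0), harm_phase = numeric(0),
                         bend = c(0, 0)) {
  spec <- phantom_spec(n_subjects = 1, shape = shape,
                       base_radius = base_radius, variability = 0, bend = 0)
  pars <- list(amp = harm_amp,
               phase = if (length(harm_phase)) harm_phase
                       else rep(0, length(harm_amp)),
               bend = bend)
  binary_mask(subject_mask_grid(spec, pars, (shape[1:2] - 1) / 2))
}

#' Generate a family of muscle-like shapes
#'
#' @param spec a `phantom_spec`.
#' @return list of `n_subjects` binary masks (1 mm isotropic by default),
#'   each a single 6-connected component; identical seeds give identical
#'   output and `variability = 0, bend = 0` gives identical subjects.
#' @export
generate_shape_family <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    centre <- (spec$shape[1:2] - 1) / 2
    lapply(seq_len(spec$n_subjects), function(s) {
      pars <- draw_subject_params(spec)
      binary_mask(subject_mask_grid(spec, pars, centre))
    })
  })
}

#' Generate a multi-label phantom of parallel adjacent tubes
#'
#' `labels` parallel non-overlapping tubes packed side by side along the
#' first axis with a 1-2 voxel gap, labelled 1..L.
#'
#' @param spec a `phantom_spec` with `labels >= 2`.
#' @param gap inter-tube gap in voxels (1 or 2).
#' @return a `label_volume`.
#' @export
generate_multilabel_phantom <- function(spec, gap = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  L <- spec$labels
  if (L < 2) stop_ms("ms_spec_error", "multi-label phantom needs labels >= 2")
  d <- spec$shape
  maxr <- spec$base_radius + spec$variability + 1
  pitch <- 2 * maxr + gap
  width <- pitch * (L - 1)
  if (width + 2 * maxr + 6 > d[1])
    stop_ms("ms_spec_error", "cannot pack %d tubes without overlap", L)
  x0 <- (d[1] - 1 - width) / 2
  with_seed(spec$seed, {
    out <- array(0L, d)
    for (l in seq_len(L)) {
      pars <- draw_subject_params(spec)
      pars$bend <- c(0, pars$bend[2]) # bending across the packing axis risks contact
      g <- subject_mask_grid(spec, pars, c(x0 + (l - 1) * pitch, (d[2] - 1) / 2))
      if (any(out[g] != 0L)) stop_ms("ms_spec_error", "tube overlap while packing")
      out[g] <- l
    }
    label_volume(out)
  })
}

#' Corrupt a gold-standard phantom into a "prediction"
#'
#' Applies, per label: spherical voids (blank regions), spurious blobs
#' placed 2-5 voxels outside the label, random flips in a band around the
#' boundary, and reassignment of part of the contact zone to an adjacent
#' label (mis-segmentation). Spacing/origin/shape metadata are untouched and
#' an all-zero spec returns the input unchanged.
#'
#' @param gt a `label_volume` ground truth.
#' @param cspec a `corruption_spec`.
#' @return corrupted `label_volume`.
#' @export
corrupt_prediction <- function(gt, cspec) {
  stopifnot(inherits(gt, "label_volume"), inherits(cspec, "corruption_spec"))
  d <- dim(gt$grid)
  labs <- setdiff(sort(unique(as.vector(gt$grid))), 0L)
  with_seed(cspec$seed, {
    out <- gt$grid
    for (l in labs) {
      fg <- gt$grid == l
      if (!any(fg)) next
      # (c) smooth boundary displacement: the label surface is moved by a
      # short-correlation (2-voxel) random field of the stated amplitude,
      # emulating segmenter boundary notches rather than voxel salt-and-
      # pepper; applied first so voids and blobs act on the noisy shape
      if (cspec$boundary_noise > 0) {
        nf <- signed_distance(binary_mask(fg))
        noise <- array(gauss_smooth3(rnorm(prod(d)), d, c(2, 2, 2)), d)
        noise <- noise / stats::sd(noise)
        fg2 <- nf$grid < cspec$boundary_noise * noise
        out[fg & !fg2 & out == l] <- 0L
        out[!fg & fg2 & out == 0L] <- l
        fg <- fg2 & (out == l)
      }
      idx <- which_idx3(fg & out == l)
      if (nrow(idx) == 0) next
      # (a) spherical voids, kept mutually disjoint so hole_count components
      # of the label are actually removed
      if (cspec$hole_count > 0) {
        centres <- matrix(numeric(0), 0, 3)
        tries <- 0
        while (nrow(centres) < cspec$hole_count && tries < 200) {
          tries <- tries + 1
          cand <- idx[sample.int(nrow(idx), 1), ]
          if (nrow(centres) == 0 ||
              min(sqrt(rowSums(sweep(centres, 2, cand)^2))) >
                2 * cspec$hole_radius + 2)
            centres <- rbind(centres, cand)
        }
        for (q in seq_len(nrow(centres)))
          out[sphere_region(d, centres[q, ], cspec$hole_radius) & fg] <- 0L
      }
      # (b) spurious blobs just outside the label
      if (cspec$blob_count > 0) {
        surf <- which_idx3(surface_grid(fg))
        dist_fg <- dist_to(fg)
        for (q in seq_len(cspec$blob_count)) {
          sp <- surf[sample.int(nrow(surf), 1), ]
          offd <- runif(1, 2, 5)
          dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
          ctr <- round(sp + dir * (offd + cspec$blob_radius))
          ctr <- pmin(pmax(ctr, 0), d - 1)
          reg <- sphere_region(d, ctr, cspec$blob_radius) & dist_fg > 1.5 & out == 0L
          out[reg] <- l
        }
      }
      # (d) label swaps in the contact zone of an adjacent label
      if (cspec$swap_fraction > 0 && length(labs) > 1) {
        others <- setdiff(labs, l)
        dmin <- sapply(others, function(o) min(dist_to(gt$grid == o)[fg]))
        adj <- others[which.min(dmin)]
        dadj <- dist_to(gt$grid == adj)
        # contact zone: the label's voxels nearest the adjacent label
        zone <- which(fg & dadj <= min(dadj[fg]) + 2)
        take <- sample(zone, ceiling(cspec$swap_fraction * length(zone)))
        out[take] <- adj
      }
    }
    label_volume(out, gt$spacing, gt$origin)
  })
}

sphere_region <- function(d, centre, radius) {
  x <- (seq_len(d[1]) - 1 - centre[1])^2
  y <- (seq_len(d[2]) - 1 - centre[2])^2
  z <- (seq_len(d[3]) - 1 - centre[3])^2
  outer(outer(x, y, `+`), z, `+`) <= radius^2
}

#' Synthetic intensity image for a label volume
#'
#' Piecewise-constant class means plus zero-mean Gaussian noise, seeded.
#'
#' @param gt a `label_volume`.
#' @param class_means named or positional numeric vector with one mean per
#'   label value 0..L (first entry = background).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed RNG seed.
#' @return 3D numeric array.
#' @export
synth_intensity_image <- function(gt, class_means, noise_sd = 5, seed = 0) {
  stopifnot(inherits(gt, "label_volume"))
  labs <- sort(unique(as.vector(gt$grid)))
  if (length(class_means) < length(labs))
    stop_ms("ms_config_error", "need one class mean per label incl. background")
  with_seed(seed, {
    img <- array(class_means[gt$grid + 1L], dim(gt$grid))
    if (noise_sd > 0) img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
    img
  })
}

#' Label-noise unaries
#'
#' Per-class probability maps from an observed (possibly noisy) label
#' volume: probability `1 - flip_prob` on the observed label and `flip_prob`
#' split uniformly over the remaining classes, so per-voxel probabilities
#' sum to one.
#'
#' @param noisy_labels a `label_volume` whose values lie in 0..(n_classes-1).
#' @param flip_prob in [0, 0.5).
#' @param n_classes number of classes (background included); defaults to
#'   max(label) + 1.
#' @return 4D array (x, y, z, class).
#' @export
unaries_from_labels <- function(noisy_labels, flip_prob,
                                n_classes = max(noisy_labels$grid) + 1L) {
  stopifnot(inherits(noisy_labels, "label_volume"))
  if (flip_prob < 0 || flip_prob >= 0.5)
    stop_ms("ms_config_error", "flip_prob must be in [0, 0.5)")
  d <- dim(noisy_labels$grid)
  off <- if (n_classes > 1) flip_prob / (n_classes - 1) else 0
  u <- array(off, c(d, n_classes))
  for (cl in seq_len(n_classes) - 1L) {
    sel <- noisy_labels$grid == cl
    plane <- array(FALSE, c(d, n_classes))
    plane[, , , cl + 1L] <- sel
    u[plane] <- 1 - flip_prob
  }
  u
}
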