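#' Generalized rigid alignment of a shape ensemble
#'
#' Removes pose (rotation + translation, never scale: size is a real
#' biological signal) from an ensemble of binary masks before shape
#' statistics. Each shape is first moved by its foreground centroid and
#' principal axes onto the frame of the first shape, then refined by
#' iterative-closest-point passes against the pooled aligned surface cloud
#' until the mean transform update falls below `tol`.
#'
#' @param masks list of >= 2 non-empty `binary_mask` objects.
#' @param tol convergence tolerance on the mean transform update (mm).
#' @param max_outer maximum alignment sweeps.
#' @param n_sub surface points subsampled per shape for the refinement.
#' @return list with `transforms` (per-shape `rigid_transform` mapping the
#'   shape into the common frame), `aligned` (masks resampled into the
#'   common frame), `sdfs` (signed distance fields of the aligned masks) and
#'   `geometry` (the common-frame grid geometry).
#' @export
procrustes_align <- function(masks, tol = 1e-4, max_outer = 5, n_sub = 800) {
  if (length(masks) < 2) stop_ms("ms_ensemble_error", "need >= 2 shapes")
  for (m in masks) if (!any(m$grid)) stop_ms("ms_empty_mask_error", "empty mask in ensemble")
  ref <- masks[[1]]
  clouds <- lapply(masks, function(m) subsample_rows(surface_voxels(m), n_sub))
  fgpts <- lapply(masks, function(m)
    idx_to_world(which_idx3(m$grid), m$spacing, m$origin))

  axes_of <- function(pts) {
    c0 <- colMeans(pts)
    e <- eigen(stats::cov(pts), symmetric = TRUE)
    V <- e$vectors[, order(e$values, decreasing = TRUE)]
    if (det(V) < 0) V[, 3] <- -V[, 3]
    list(centroid = c0, V = V)
  }
  ref_ax <- axes_of(fgpts[[1]])
  apply_T <- function(pts, tr) sweep(pts %*% t(tr$R), 2, tr$t, `+`)
  rms_to <- function(pts, refpts) sqrt(mean(nn_bruteforce(pts, refpts)$d2))

  # initial pose per shape: centroid translation with either the identity
  # rotation or a principal-axes rotation (four proper sign variants),
  # whichever leaves the smallest residual against the reference surface.
  # Near-axisymmetric shapes have degenerate transverse moments, so a
  # moments-only initialization can pick an arbitrary large rotation; the
  # identity candidate guards against that.
  transforms <- lapply(seq_along(masks), function(k) {
    ax <- axes_of(fgpts[[k]])
    cands <- list(list(R = diag(3),
                       t = as.numeric(ref_ax$centroid - ax$centroid)))
    for (alt in list(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))) {
      Vk <- ax$V
      Vk[, 1] <- alt[1] * Vk[, 1]
      Vk[, 2] <- alt[2] * Vk[, 2]
      Vk[, 3] <- Vk[, 3] * alt[1] * alt[2] # keep det = +1
      R0 <- ref_ax$V %*% t(Vk)
      cands[[length(cands) + 1]] <- list(
        R = R0, t = as.numeric(ref_ax$centroid - R0 %*% ax$centroid))
    }
    sc <- vapply(cands, function(tr) rms_to(apply_T(clouds[[k]], tr),
                                            clouds[[1]]), 0)
    cands[[which.min(sc)]]
  })

  # signed distance is rigid-invariant, so each shape's aligned SDF is its
  # native-frame SDF sampled trilinearly through the inverse transform;
  # this avoids the surface jitter of nearest-neighbour mask resampling
  geometry <- list(dim = dim(ref$grid), spacing = ref$spacing,
                   origin = ref$origin)
  native_sdfs <- lapply(masks, signed_distance)
  warped_sdfs <- function(transforms)
    lapply(seq_along(masks), function(k)
      warp_sdf(native_sdfs[[k]], transforms[[k]], geometry))

  # refinement: align every shape to the surface of the evolving mean
  # (zero level of the averaged aligned SDFs), not to a pooled cloud --
  # the pooled superposition is fuzzy and lets thin members drift
  for (outer in seq_len(max_outer)) {
    sdfs <- warped_sdfs(transforms)
    acc <- Reduce(`+`, lapply(sdfs, function(s) s$grid)) / length(masks)
    mean_mask <- binary_mask(acc < 0, ref$spacing, ref$origin)
    if (!any(mean_mask$grid))
      stop_ms("ms_ensemble_error",
              "shapes share no common region after alignment")
    mean_cloud <- subsample_rows(surface_voxels(mean_mask), 2 * n_sub)
    upd <- 0
    for (k in seq_along(masks)) {
      dT <- icp_rigid(apply_T(clouds[[k]], transforms[[k]]), mean_cloud,
                      max_iter = 10, tol = 1e-4, init = "moments")
      transforms[[k]] <- list(R = dT$R %*% transforms[[k]]$R,
                              t = as.numeric(dT$R %*% transforms[[k]]$t + dT$t))
      upd <- upd + sqrt(sum(dT$t^2)) + norm(dT$R - diag(3), "F")
    }
    if (upd / length(masks) < tol) break
  }
  transforms <- lapply(transforms, function(tr)
    structure(tr, class = "rigid_transform"))
  sdfs <- warped_sdfs(transforms)
  aligned <- lapply(sdfs, function(s)
    binary_mask(s$grid < 0, ref$spacing, ref$origin))
  for (m in aligned) if (!any(m$grid))
    stop_ms("ms_ensemble_error", "shape left the common-frame grid during alignment")
  list(transforms = transforms, aligned = aligned, sdfs = sdfs,
       geometry = geometry)
}

# resample a signed distance field through a rigid transform (trilinear);
# values outside the native grid saturate at the field maximum
warp_sdf <- function(sdf, tr, geometry) {
  d <- geometry$dim
  idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1, j = seq_len(d[2]) - 1,
                               k = seq_len(d[3]) - 1))
  w <- idx_to_world(idx, geometry$spacing, geometry$origin)
  src <- sweep(w, 2, tr$t) %*% tr$R # R^-1 (w - t)
  big <- max(abs(sdf$grid))
  vals <- trilinear_sample(as.numeric(sdf$grid), dim(sdf$grid),
                           world_to_idx(src, sdf$spacing, sdf$origin),
                           outside = big)
  structure(list(grid = array(vals, d), spacing = geometry$spacing,
                 origin = geometry$origin), class = "sdf")
}

subsample_rows <- function(x, n) {
  if (nrow(x) <= n) return(x)
  x[round(seq(1, nrow(x), length.out = n)), , drop = FALSE]
}

# --- particle machinery -----------------------------------------------------

sdf_value <- function(sdf, pts) {
  trilinear_sample(as.numeric(sdf$grid), dim(sdf$grid),
                   world_to_idx(pts, sdf$spacing, sdf$origin),
                   outside = max(abs(sdf$grid)))
}

sdf_gradient <- function(sdf, pts) {
  h <- min(sdf$spacing) / 2
  g <- matrix(0, nrow(pts), 3)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- h
    g[, ax] <- (sdf_value(sdf, sweep(pts, 2, e, `+`)) -
                  sdf_value(sdf, sweep(pts, 2, e, `-`))) / (2 * h)
  }
  g
}

# Newton projection of points onto the SDF zero level set; points are
# clamped into the grid so the gradient never degenerates to zero far field
project_to_surface <- function(sdf, pts, iters = 4) {
  d <- dim(sdf$grid)
  lo <- sdf$origin
  hi <- sdf$origin + (d - 1) * sdf$spacing
  for (q in seq_len(iters)) {
    for (ax in 1:3) pts[, ax] <- pmin(pmax(pts[, ax], lo[ax]), hi[ax])
    phi <- sdf_value(sdf, pts)
    g <- sdf_gradient(sdf, pts)
    gn2 <- rowSums(g^2)
    gn2[gn2 < 1e-12] <- 1
    pts <- pts - g * (phi / gn2)
  }
  pts
}

# adaptive Parzen bandwidth: distance to about the 6th nearest neighbour
parzen_sigma <- function(D2) {
  m <- nrow(D2)
  kth <- min(6L, m - 1L)
  apply(D2, 1, function(r) sqrt(sort(r)[kth + 1L])) # +1 skips self (0)
}

# one repulsion step on a single surface: Gaussian-weighted mean of unit
# directions away from the neighbours, scaled by the adaptive bandwidth.
# Using unit directions (not raw offsets) makes near-coincident particles
# -- freshly split duplicates -- separate at O(sigma) speed.
sampling_step <- function(pts, sdf, step_frac = 0.4) {
  m <- nrow(pts)
  if (m < 2) return(pts)
  D <- as.matrix(stats::dist(pts))
  D2 <- D^2
  sig <- parzen_sigma(D2)
  W <- exp(-D2 / (2 * sig^2)) # row j: kernel of bandwidth sigma_j
  diag(W) <- 0
  Wd <- W / (D + 1e-9 * sig)
  diag(Wd) <- 0
  wdsum <- rowSums(Wd) + 1e-12
  # weighted mean of unit directions away from neighbours, magnitude <= 1
  dirs <- (wdsum * pts - Wd %*% pts) / wdsum
  mv <- step_frac * sig * dirs
  # cap the step at 2 voxels: the adaptive bandwidth approaches the shape
  # diameter for small m and would otherwise fling particles off the grid
  cap <- 2 * min(sdf$spacing)
  nrm <- sqrt(rowSums(mv^2))
  sc <- pmin(1, cap / pmax(nrm, 1e-12))
  pts + mv * sc
}

# leave-one-out Parzen estimate of the differential entropy of one
# particle set (mm units)
sampling_entropy <- function(pts) {
  m <- nrow(pts)
  if (m < 2) return(0)
  D2 <- as.matrix(stats::dist(pts))^2
  sig <- parzen_sigma(D2)
  W <- exp(-D2 / (2 * sig^2)) / ((2 * pi)^(3 / 2) * sig^3)
  diag(W) <- 0
  p <- rowSums(W) / (m - 1)
  -mean(log(pmax(p, 1e-300)))
}

# Gaussian-model ensemble entropy and its per-shape gradient via the
# N x N dual of the 3m x 3m covariance
ensemble_entropy_grad <- function(X, alpha_rel = 1e-3) {
  N <- nrow(X)
  mu <- colMeans(X)
  Y <- t(X) - mu # 3m x N
  n <- N - 1
  C <- crossprod(Y) / n # N x N dual
  ev <- eigen(C, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  alpha <- alpha_rel * sum(lam) / ncol(X) + 1e-8
  H <- 0.5 * (sum(log(lam + alpha)) + (ncol(X) - N) * log(alpha))
  Minv <- ev$vectors %*% (t(ev$vectors) / (lam * n + alpha * n))
  G <- n * Y %*% Minv # 3m x N, column k = d H-ish / d x_k direction
  list(H = H, grad = t(G), alpha = alpha, lambda = lam)
}

#' Seed and split particles on one surface
#'
#' Starts from a single surface voxel and repeatedly doubles the particle
#' count (each particle duplicated with a small random offset, projected
#' back to the zero level set, then relaxed by surface repulsion) until
#' `m_target` particles are reached.
#'
#' @param sdf a signed distance field (class `sdf`).
#' @param m_target particle count, a power of two >= 16.
#' @param seed RNG seed.
#' @param relax_iters repulsion iterations after each split.
#' @return m_target x 3 matrix of particle positions in mm, all within half
#'   a voxel of the surface.
#' @export
initialize_particles <- function(sdf, m_target = 256, seed = 0,
                                 relax_iters = 12) {
  if (!is_power_of_two(m_target) || m_target < 16)
    stop_ms("ms_config_error", "m_target must be a power of two >= 16")
  surf <- which(abs(sdf$grid) <= min(sdf$spacing))
  if (length(surf) == 0) stop_ms("ms_degenerate_mask_error", "no surface voxels")
  with_seed(seed, {
    i0 <- surf[which.min(abs(sdf$grid[surf]))] - 1L
    d <- dim(sdf$grid)
    idx0 <- c(i0 %% d[1], (i0 %/% d[1]) %% d[2], i0 %/% (d[1] * d[2]))
    pts <- matrix(idx_to_world(rbind(idx0), sdf$spacing, sdf$origin), 1, 3)
    pts <- project_to_surface(sdf, pts)
    h <- min(sdf$spacing)
    while (nrow(pts) < m_target) {
      off <- matrix(rnorm(length(pts), 0, 0.5 * h), nrow(pts), 3)
      pts <- rbind(pts, pts + off)
      pts <- project_to_surface(sdf, pts)
      for (q in seq_len(relax_iters))
        pts <- project_to_surface(sdf, sampling_step(pts, sdf), iters = 2)
    }
    pts
  })
}

#' Entropy-based particle correspondence optimization
#'
#' Optimizes homologous correspondence particles across an aligned shape
#' ensemble by minimizing `Q = H(Z) - sum_k H(x_k)`: a Gaussian shape-space
#' model pulls corresponding particles into a compact ensemble distribution
#' while per-surface Parzen repulsion spreads particles uniformly on each
#' surface. Every step ends with Newton projection back to the zero level
#' set; steps that fail to decrease Q trigger step halving, so the recorded
#' energy trace is non-increasing.
#'
#' @param masks list of `binary_mask` (>= 2; a single mask is accepted and
#'   optimized with the ensemble term disabled).
#' @param m particles per shape (power of two >= 16).
#' @param iterations outer iteration cap.
#' @param step_sampling repulsion step fraction.
#' @param step_ensemble ensemble descent step: the largest per-particle
#'   move per sweep, in voxels.
#' @param seed RNG seed.
#' @param rel_tol relative energy change stopping rule.
#' @param alpha_rel regularization of the shape-space covariance relative to
#'   its mean eigenvalue.
#' @return a `particle_system`: positions `[m, 3, N]` in common-frame mm,
#'   aligned SDFs, Procrustes transforms, and an energy trace with columns
#'   iter / Q / ensemble / sampling_sum.
#' @export
optimize_correspondences <- function(masks, m = 256, iterations = 200,
                                     step_sampling = 0.4,
                                     step_ensemble = 0.5, seed = 0,
                                     rel_tol = 1e-5, alpha_rel = 1e-3) {
  if (!is_power_of_two(m) || m < 16)
    stop_ms("ms_config_error", "m must be a power of two >= 16")
  N <- length(masks)
  single <- N == 1
  if (single) {
    sdfs <- list(signed_distance(masks[[1]]))
    geometry <- list(dim = dim(masks[[1]]$grid), spacing = masks[[1]]$spacing,
                     origin = masks[[1]]$origin)
    transforms <- list(structure(list(R = diag(3), t = c(0, 0, 0)),
                                 class = "rigid_transform"))
  } else {
    al <- procrustes_align(masks)
    sdfs <- al$sdfs
    geometry <- al$geometry
    transforms <- al$transforms
  }
  # correspondence-preserving initialization: split/relax one particle set
  # on the surface of the ensemble mean SDF, then project that same
  # configuration onto every aligned shape. Identical shapes thus get
  # identical particles, and similar shapes start index-matched with the
  # smallest possible projection displacements (half the inter-subject
  # spread instead of the full spread from an extreme member).
  P <- array(0, c(m, 3, N))
  if (N == 1) {
    P[, , 1] <- initialize_particles(sdfs[[1]], m, seed)
  } else {
    msdf <- sdfs[[1]]
    msdf$grid <- array(Reduce(`+`, lapply(sdfs, function(s) s$grid)) / N,
                       dim(msdf$grid))
    P0 <- initialize_particles(msdf, m, seed)
    for (k in seq_len(N)) P[, , k] <- project_to_surface(sdfs[[k]], P0,
                                                         iters = 8)
  }

  flat <- function(P) t(apply(P, 3, function(x) as.vector(t(x)))) # N x 3m
  energy <- function(P) {
    Hx <- vapply(seq_len(N), function(k) sampling_entropy(P[, , k]), 0)
    if (single) {
      list(Q = -sum(Hx), HZ = 0, Hx = Hx)
    } else {
      ee <- ensemble_entropy_grad(flat(P), alpha_rel)
      list(Q = ee$H - sum(Hx), HZ = ee$H, Hx = Hx)
    }
  }
  voxel <- min(sdfs[[1]]$spacing)
  cur <- energy(P)
  trace <- data.frame(iter = 0L, Q = cur$Q, ensemble = cur$HZ,
                      sampling = sum(cur$Hx))
  check_surface <- function(P) {
    for (k in seq_len(N))
      if (max(abs(sdf_value(sdfs[[k]], P[, , k]))) > 2 * voxel)
        stop_ms("ms_optimization_error",
                "particle left the surface by more than 2 voxels")
  }
  for (it in seq_len(iterations)) {
    q_before <- cur$Q
    # (a) sampling-entropy sweep: per-surface repulsion, own acceptance
    ssc <- step_sampling
    for (half in 0:4) {
      Pn <- P
      for (k in seq_len(N))
        Pn[, , k] <- project_to_surface(sdfs[[k]],
                                        sampling_step(P[, , k], sdfs[[k]], ssc))
      new <- energy(Pn)
      if (new$Q <= cur$Q) { P <- Pn; cur <- new; break }
      ssc <- ssc / 2
    }
    # (b) ensemble-entropy sweep: compact the shape-space distribution,
    # step normalized so the largest particle move is step_ensemble voxels
    if (!single) {
      ee <- ensemble_entropy_grad(flat(P), alpha_rel)
      gmax <- max(abs(ee$grad))
      if (gmax > 0) {
        sec <- step_ensemble * voxel / gmax
        for (half in 0:4) {
          Pn <- P
          for (k in seq_len(N)) {
            gk <- matrix(ee$grad[k, ], m, 3, byrow = TRUE)
            Pn[, , k] <- project_to_surface(sdfs[[k]], P[, , k] - sec * gk)
          }
          new <- energy(Pn)
          if (new$Q <= cur$Q) { P <- Pn; cur <- new; break }
          sec <- sec / 2
        }
      }
    }
    if (cur$Q > q_before - 1e-12 && it > 1) break # no sweep accepted
    check_surface(P)
    trace <- rbind(trace, data.frame(iter = it, Q = cur$Q, ensemble = cur$HZ,
                                     sampling = sum(cur$Hx)))
    if (abs(q_before - cur$Q) <= rel_tol * max(abs(q_before), 1) && it > 3)
      break
  }
  structure(list(positions = P, m = m, N = N, sdfs = sdfs,
                 transforms = transforms, geometry = geometry,
                 trace = trace, seed = seed),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat(sprintf("<particle_system> %d shapes x %d particles, %d accepted steps, Q = %.4g\n",
              x$N, x$m, nrow(x$trace) - 1L, tail(x$trace$Q, 1)))
  invisible(x)
}

#' Energy breakdown of a particle system
#'
#' Returns the recorded trace of the correspondence energy
#' `Q = H(Z) - sum_k H(x_k)` (ensemble entropy minus the per-surface
#' sampling entropies) over accepted iterations.
#'
#' @param ps a `particle_system`.
#' @return data.frame with columns iter, Q, ensemble, sampling.
#' @export
energy_breakdown <- function(ps) {
  stopifnot(inherits(ps, "particle_system"))
  ps$trace
}

#' Build the statistical shape model from converged correspondences
#'
#' Mean correspondence vector plus PCA modes and eigenvalues from the
#' eigen-decomposition of the N x N dual of the sample covariance; at most
#' N-1 eigenvalues are strictly positive.
#'
#' @param ps a converged `particle_system` with N >= 2 shapes.
#' @return a `shape_model` with fields mean (3m), modes (3m x (N-1)),
#'   eigenvalues (mm^2, non-increasing), and the ensemble geometry.
#' @export
build_shape_model <- function(ps) {
  stopifnot(inherits(ps, "particle_system"))
  if (ps$N < 2) stop_ms("ms_ensemble_error", "shape model needs >= 2 shapes")
  X <- t(apply(ps$positions, 3, function(x) as.vector(t(x)))) # N x 3m
  mu <- colMeans(X)
  Y <- t(X) - mu
  n <- ps$N - 1
  C <- crossprod(Y) / n
  ev <- eigen(C, symmetric = TRUE)
  lam <- ev$values
  keep <- which(lam > max(lam, 0) * 1e-10 & lam > 0)
  keep <- head(keep, n)
  modes <- Y %*% ev$vectors[, keep, drop = FALSE]
  if (length(keep))
    modes <- sweep(modes, 2, sqrt(colSums(modes^2)), `/`)
  structure(list(mean = mu, modes = modes,
                 eigenvalues = pmax(lam[keep], 0),
                 m = ps$m, N = ps$N, geometry = ps$geometry,
                 transforms = ps$transforms),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("<shape_model> %d shapes, %d particles, %d modes\n",
              x$N, x$m, length(x$eigenvalues)))
  if (length(x$eigenvalues)) {
    pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
    cat("  variance explained (%):", paste(sprintf("%.1f", head(pct, 5)),
                                           collapse = ", "),
        if (length(pct) > 5) "..." else "", "\n")
  }
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  ev <- object$eigenvalues
  out <- data.frame(mode = seq_along(ev), eigenvalue = ev,
                    prop_var = if (length(ev)) ev / sum(ev) else numeric(0))
  class(out) <- c("summary.shape_model", "data.frame")
  out
}

#' Mode scores of the ensemble (or of new correspondence vectors)
#'
#' @param model a `shape_model`.
#' @param ps a `particle_system` (defaults its own ensemble) or an N x 3m
#'   matrix of correspondence vectors.
#' @return N x n_modes matrix of PCA scores.
#' @export
shape_scores <- function(model, ps) {
  X <- if (inherits(ps, "particle_system"))
    t(apply(ps$positions, 3, function(x) as.vector(t(x)))) else as.matrix(ps)
  sweep(X, 2, model$mean) %*% model$modes
}

#' Reconstruct the mean shape as a voxel mask
#'
#' Default strategy: take the ensemble member whose correspondence vector is
#' nearest the mean, build a smooth radial-basis interpolant (biharmonic
#' kernel plus affine part) from the mean particle positions to that
#' member's particles, and classify every voxel of the common frame by the
#' member's signed distance sampled at the warped position. The fallback
#' `method = "mean_sdf"` averages the aligned SDFs and thresholds at zero.
#'
#' @param model a `shape_model`.
#' @param ps the `particle_system` the model was built from.
#' @param method "rbf" (default) or "mean_sdf".
#' @return `binary_mask` in the common Procrustes frame.
#' @export
reconstruct_mean_mask <- function(model, ps, method = c("rbf", "mean_sdf")) {
  method <- match.arg(method)
  geo <- ps$geometry
  if (method == "mean_sdf") {
    acc <- Reduce(`+`, lapply(ps$sdfs, function(s) s$grid)) / ps$N
    return(binary_mask(acc < 0, geo$spacing, geo$origin))
  }
  mu <- matrix(model$mean, ps$m, 3, byrow = TRUE)
  X <- t(apply(ps$positions, 3, function(x) as.vector(t(x))))
  k_star <- which.min(rowSums(sweep(X, 2, model$mean)^2))
  target <- ps$positions[, , k_star]
  warp <- rbf_warp(mu, target) # maps mean frame -> member
  sdfk <- ps$sdfs[[k_star]]
  # evaluate over the volume in chunks
  d <- geo$dim
  all_idx <- as.matrix(expand.grid(i = seq_len(d[1]) - 1,
                                   j = seq_len(d[2]) - 1,
                                   k = seq_len(d[3]) - 1))
  pts <- idx_to_world(all_idx, geo$spacing, geo$origin)
  inside <- logical(nrow(pts))
  big <- max(abs(sdfk$grid))
  # the interpolant is only meaningful near the particle cloud: restrict to
  # its bounding box plus a margin, where extrapolation is mild
  margin <- 4 * max(geo$spacing)
  lo <- apply(mu, 2, min) - margin
  hi <- apply(mu, 2, max) + margin
  inbox <- pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
    pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
    pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  sel <- which(inbox)
  chunk <- 20000L
  for (s in seq(1, length(sel), by = chunk)) {
    e <- min(s + chunk - 1L, length(sel))
    q <- sel[s:e]
    w <- warp(pts[q, , drop = FALSE])
    inside[q] <- trilinear_sample(as.numeric(sdfk$grid), d,
                                  world_to_idx(w, sdfk$spacing, sdfk$origin),
                                  outside = big) < 0
  }
  g <- array(inside, d)
  # stray specks can appear where the warp folds far from the particles;
  # the mean shape is by construction a single body
  lab <- array(label_components_cpp(as.logical(g), d, 6L), d)
  if (max(lab) > 1L) g <- lab == which.max(tabulate(lab[lab > 0L]))
  binary_mask(array(g, d), geo$spacing, geo$origin)
}

# biharmonic (|r|) RBF interpolant with affine term; returns a function
rbf_warp <- function(centres, values) {
  m <- nrow(centres)
  D <- as.matrix(stats::dist(centres))
  Pm <- cbind(1, centres)
  A <- rbind(cbind(D, Pm), cbind(t(Pm), matrix(0, 4, 4)))
  rhs <- rbind(values - centres, matrix(0, 4, 3))
  coef <- tryCatch(solve(A, rhs), error = function(e)
    stop_ms("ms_reconstruction_error",
            "singular RBF system (coincident particles)"))
  w <- coef[seq_len(m), , drop = FALSE]
  a <- coef[m + 1:4, , drop = FALSE]
  function(x) {
    K <- sqrt(pmax(outer(rowSums(x^2), rowSums(centres^2), `+`) -
                     2 * x %*% t(centres), 0))
    x + K %*% w + cbind(1, x) %*% a
  }
}
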