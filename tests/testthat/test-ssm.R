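# smaller grids and particle counts than the defaults keep these tests fast
# while exercising every code path

test_that("procrustes alignment recovers pose and handles identity", {
  # the bend breaks the axial symmetry: a rotation about the tube axis is
  # only recoverable when the centerline bow is well above voxel noise
  b <- tube_phantom(shape = c(48, 48, 64), base_radius = 6,
                    harm_amp = c(1.2), bend = c(5, 0))
  # identical masks: identity transforms
  al <- procrustes_align(list(b, b, b))
  for (tr in al$transforms) {
    expect_lt(norm(tr$R - diag(3), "F"), 1e-6)
    expect_lt(max(abs(tr$t)), 1e-6)
  }
  # pure translation recovered relative to the common frame
  g2 <- array(FALSE, dim(b$grid))
  g2[6:dim(b$grid)[1], , ] <- b$grid[1:(dim(b$grid)[1] - 5), , ]
  al2 <- procrustes_align(list(b, binary_mask(g2)))
  expect_lt(max(abs(al2$transforms[[2]]$t - c(-5, 0, 0))), 0.5)
  # 15-degree rotation about the tube axis of a bent tube
  R <- rot_about(c(0, 0, 1), 15)
  ctr <- (dim(b$grid) - 1) / 2
  idx <- as.matrix(expand.grid(0:(dim(b$grid)[1] - 1), 0:(dim(b$grid)[2] - 1),
                               0:(dim(b$grid)[3] - 1)))
  src <- sweep(sweep(idx, 2, ctr) %*% R, 2, ctr, `+`) # inverse rotation map
  si <- round(src)
  ok <- si[, 1] >= 0 & si[, 2] >= 0 & si[, 3] >= 0 &
    si[, 1] < 48 & si[, 2] < 48 & si[, 3] < 64
  rotg <- logical(nrow(si))
  rotg[ok] <- b$grid[si[ok, , drop = FALSE] + 1]
  al3 <- procrustes_align(list(b, binary_mask(array(rotg, dim(b$grid)))))
  # the common frame is defined up to a global pose: compare the relative
  # transform between the two shapes with the known ground truth
  R_rel <- crossprod(al3$transforms[[1]]$R, al3$transforms[[2]]$R)
  expect_lt(rotation_error_deg(R_rel, t(R)), 1)
  expect_error(procrustes_align(list(b)), class = "ms_ensemble_error")
})

test_that("particle initialization stays on-surface and spreads evenly", {
  s <- signed_distance(ball_mask(8, 33))
  p <- initialize_particles(s, 16, seed = 1)
  expect_equal(nrow(p), 16)
  expect_lt(max(abs(muscleshape:::sdf_value(s, p))), 0.5)
  expect_identical(p, initialize_particles(s, 16, seed = 1))
  p64 <- initialize_particles(s, 64, seed = 2)
  expect_lt(sqrt(sum((colMeans(p64) - 16)^2)), 1) # sphere centre by symmetry
  expect_error(initialize_particles(s, 20, seed = 1),
               class = "ms_config_error")
})

test_that("correspondence optimization is monotone and degenerate-safe", {
  b <- ball_mask(8, 25)
  # identical spheres: shape-space variance collapses, sampling entropies tie
  ps <- optimize_correspondences(list(b, b, b), m = 32, iterations = 10,
                                 seed = 1)
  X <- t(apply(ps$positions, 3, function(x) as.vector(t(x))))
  expect_lt(sum(diag(cov(X))), 1e-8)
  tr <- energy_breakdown(ps)
  Hx <- sapply(1:3, function(k)
    muscleshape:::sampling_entropy(ps$positions[, , k]))
  expect_lt(max(Hx) - min(Hx), 1e-3)
  # energy identity Q = H(Z) - sum H(x_k) at every recorded iteration
  expect_lt(max(abs(tr$Q - (tr$ensemble - tr$sampling))), 1e-10)
  # Q non-increasing over accepted steps
  tubes <- lapply(seq(-1.5, 1.5, length.out = 6), function(a)
    tube_phantom(shape = c(40, 40, 56), base_radius = 5, harm_amp = c(a)))
  pst <- optimize_correspondences(tubes, m = 64, iterations = 15, seed = 1)
  expect_true(all(diff(energy_breakdown(pst)$Q) <= 1e-9))
  # single shape: uniform spread on a sphere (ensemble term disabled)
  ps1 <- optimize_correspondences(list(b), m = 64, iterations = 30, seed = 1)
  p <- ps1$positions[, , 1]
  D <- as.matrix(dist(p)); diag(D) <- Inf
  nnd <- apply(D, 1, min)
  expect_lt(sd(nnd) / mean(nnd), 0.5)
})

test_that("shape models obey the rank bound and permutation invariance", {
  b8 <- ball_mask(8, 33); b10 <- ball_mask(10, 33); b12 <- ball_mask(12, 33)
  ps <- optimize_correspondences(list(b8, b10, b12), m = 32, iterations = 10,
                                 seed = 1)
  model <- build_shape_model(ps)
  expect_lte(length(model$eigenvalues), 2) # N - 1 modes at most
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
  if (ncol(model$modes) > 1)
    expect_lt(max(abs(crossprod(model$modes) - diag(ncol(model$modes)))), 1e-8)
  # permuting the ensemble changes neither mean nor eigenvalues
  ps_perm <- ps
  ps_perm$positions <- ps$positions[, , c(3, 1, 2)]
  mp <- build_shape_model(ps_perm)
  expect_lt(max(abs(mp$eigenvalues - model$eigenvalues)),
            1e-9 * max(model$eigenvalues))
  expect_lt(max(abs(mp$mean - model$mean)), 1e-9)
  # identical shapes: all eigenvalues at numerical zero
  psi <- optimize_correspondences(list(b8, b8), m = 32, iterations = 5,
                                  seed = 1)
  mi <- build_shape_model(psi)
  expect_true(length(mi$eigenvalues) == 0 ||
                max(mi$eigenvalues) <= 1e-8 * sum(diag(cov(
                  t(apply(psi$positions, 3, function(x) as.vector(t(x))))))) + 1e-12)
  expect_error(build_shape_model(
    optimize_correspondences(list(b8), m = 32, iterations = 2, seed = 1)),
    class = "ms_ensemble_error")
})

test_that("mean mask reconstruction averages the generative parameter", {
  # identical inputs: the warp is the identity
  b <- tube_phantom(shape = c(40, 40, 56), base_radius = 6, harm_amp = c(1))
  ps <- optimize_correspondences(list(b, b), m = 32, iterations = 5, seed = 1)
  mm <- reconstruct_mean_mask(build_shape_model(ps), ps)
  expect_gte(dsc(b, mm), 0.99)
  # concentric balls: mean radius halfway within a voxel
  psb <- optimize_correspondences(list(ball_mask(8, 33), ball_mask(12, 33)),
                                  m = 64, iterations = 20, seed = 1)
  mb <- reconstruct_mean_mask(build_shape_model(psb), psb)
  r_eff <- (3 * sum(mb$grid) / (4 * pi))^(1 / 3)
  expect_lt(abs(r_eff - 10), 1)
  # tube family: single 6-connected component; volume between the extremes
  tubes <- lapply(seq(-1.5, 1.5, length.out = 6), function(a)
    tube_phantom(shape = c(40, 40, 56), base_radius = 5, harm_amp = c(a)))
  pst <- optimize_correspondences(tubes, m = 64, iterations = 10, seed = 1)
  mt <- reconstruct_mean_mask(build_shape_model(pst), pst)
  lab <- muscleshape:::label_components_cpp(as.logical(mt$grid),
                                            dim(mt$grid), 6L)
  expect_equal(max(lab), 1L)
  vols <- sapply(tubes, function(m) sum(m$grid))
  expect_gte(sum(mt$grid), min(vols) * 0.95)
  expect_lte(sum(mt$grid), max(vols) * 1.05)
  # fallback strategy exists and is sane
  mf <- reconstruct_mean_mask(build_shape_model(pst), pst, method = "mean_sdf")
  expect_gt(dsc(mt, mf), 0.8)
})
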