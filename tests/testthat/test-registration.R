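test_that("ICP recovers rigid transforms of phantom clouds", {
  mk <- tube_phantom(shape = c(48, 48, 64), base_radius = 6,
                     harm_amp = c(1), bend = c(2, 1))
  pc <- surface_voxels(mk)
  # identity on identical clouds
  tr0 <- icp_rigid(pc, pc)
  expect_lt(norm(tr0$R - diag(3), "F"), 1e-6)
  expect_lt(max(abs(tr0$t)), 1e-6)
  # 10-degree rotation + (4,2,0) mm translation, exact copies
  R <- rot_about(c(0.2, -0.5, 1), 10)
  tt <- c(4, 2, 0)
  fixedpts <- sweep(pc %*% t(R), 2, tt, `+`)
  tr <- icp_rigid(pc, fixedpts)
  expect_lt(rotation_error_deg(tr$R, R), 0.1)
  expect_lt(sqrt(sum((tr$t - tt)^2)), 0.1)
  # jittered cloud: the fit still reduces the RMS residual
  set.seed(4)
  jit <- fixedpts + matrix(runif(length(pc), -0.5, 0.5), ncol = 3)
  trj <- icp_rigid(pc, jit)
  expect_lt(attr(trj, "rms"), attr(trj, "rms_initial"))
  # degenerate clouds are rejected
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(icp_rigid(line, pc), class = "ms_geometry_error")
})

test_that("apply_rigid resamples exactly on lattice-preserving maps", {
  m <- tube_phantom(shape = c(40, 40, 48), base_radius = 5)
  expect_identical(apply_rigid(m, rigid_transform())$grid, m$grid)
  # integer translation is exact
  tr <- rigid_transform(t = c(3, 0, 0))
  sh <- apply_rigid(m, tr)
  expect_identical(sh$grid[4:40, , ], m$grid[1:37, , ])
  expect_false(any(sh$grid[1:3, , ]))
  # 30-degree rotation of a fat shape preserves volume within 5%
  b <- ball_mask(8, 33)
  rot <- apply_rigid(b, rigid_transform(R = rot_about(c(0, 0, 1), 30),
                                        t = (diag(3) - rot_about(c(0, 0, 1), 30)) %*% rep(16, 3)))
  expect_lt(abs(sum(rot$grid) - sum(b$grid)) / sum(b$grid), 0.05)
})

test_that("deformable registration recovers shifts and synthetic fields", {
  mk <- tube_phantom(shape = c(48, 48, 64), base_radius = 6, harm_amp = c(1))
  d <- dim(mk$grid)
  # identical masks: the zero field is optimal
  res0 <- deformable_register(mk, mk, ns = 5, lambda = 1)
  expect_lt(max(abs(res0$field$u_vox)), 0.1)
  expect_true(all(diff(res0$cost_trace) <= 1e-9))
  # 3-voxel shift at the published optimum NS = 5
  gs <- array(FALSE, d)
  gs[4:d[1], , ] <- mk$grid[1:(d[1] - 3), , ]
  fixed <- binary_mask(gs)
  expect_lte(dsc(fixed, mk), 0.80)
  res <- deformable_register(fixed, mk, ns = 5, lambda = 1)
  w <- apply_displacement(mk, res$field)
  expect_gte(dsc(fixed, w), 0.95)
  expect_true(all(diff(res$cost_trace) <= 1e-9))
  expect_lte(res$cost, res$cost_trace[1])
  # known smooth sinusoidal field of 2-voxel amplitude
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  ut <- cbind(2 * sin(2 * pi * idx[, 3] / d[3]),
              2 * cos(2 * pi * idx[, 3] / d[3]), 0)
  Fs <- muscleshape:::gauss_smooth3(as.numeric(mk$grid), d, c(1, 1, 1))
  mv <- muscleshape:::trilinear_sample(Fs, d, idx + ut, outside = 0)
  moving <- binary_mask(array(mv > 0.5, d))
  resf <- deformable_register(mk, moving, ns = 5, lambda = 1)
  dense <- muscleshape:::dense_field_cpp(resf$field$u_vox, resf$field$ndims,
                                         resf$field$node0, resf$field$ns,
                                         as.integer(d))
  err <- sqrt(rowSums((dense + ut)^2)) # recovered field approximates -u_true
  expect_lte(mean(err[as.vector(mk$grid)]), 1)
  # contract errors
  expect_error(deformable_register(mk, binary_mask(array(FALSE, d)), ns = 5),
               class = "ms_degenerate_mask_error")
  expect_error(deformable_register(mk, mk, ns = -1),
               class = "ms_config_error")
})

test_that("auto_lambda picks the smallest fold-free candidate", {
  mk <- tube_phantom(shape = c(40, 40, 48), base_radius = 5)
  # identical images: the zero field never folds, smallest value wins
  sel <- auto_lambda(mk, mk, ns = 5, lambda_grid = c(0.5, 5, 50))
  expect_equal(sel$lambda, 0.5)
  # 3-voxel shift with the log-spaced audit grid: chosen map is fold-free
  d <- dim(mk$grid)
  gs <- array(FALSE, d)
  gs[4:d[1], , ] <- mk$grid[1:(d[1] - 3), , ]
  sel2 <- auto_lambda(binary_mask(gs), mk, ns = 5, lambda_grid = 10^seq(-2, 2))
  expect_gt(sel2$result$min_jacobian, 0)
  expect_true(all(sel2$trace$min_jacobian[-nrow(sel2$trace)] <= 0))
  # larger lambda gives a smaller mean displacement on the same pair
  r_lo <- deformable_register(binary_mask(gs), mk, ns = 5, lambda = sel2$lambda)
  r_hi <- deformable_register(binary_mask(gs), mk, ns = 5,
                              lambda = 1000 * sel2$lambda)
  mean_u <- function(r) mean(sqrt(rowSums(muscleshape:::dense_field_cpp(
    r$field$u_vox, r$field$ndims, r$field$node0, r$field$ns,
    as.integer(dim(mk$grid)))^2)))
  expect_lt(mean_u(r_hi), mean_u(r_lo))
  expect_error(auto_lambda(mk, mk, lambda_grid = numeric(0)),
               class = "ms_config_error")
})

test_that("apply_displacement warps exactly on trivial fields", {
  mk <- tube_phantom(shape = c(40, 40, 48), base_radius = 5)
  d <- dim(mk$grid)
  grid <- muscleshape:::make_node_grid(d, 5)
  zero <- structure(list(ns = 5, ndims = grid$ndims, node0 = c(0, 0, 0),
                         u_vox = matrix(0, prod(grid$ndims), 3), dim = d,
                         spacing = mk$spacing, origin = mk$origin),
                    class = "displacement_field")
  expect_identical(apply_displacement(mk, zero)$grid, mk$grid)
  # uniform integer displacement: exact shift (backward map samples x + u)
  shift <- zero
  shift$u_vox[, 1] <- 2
  w <- apply_displacement(mk, shift)
  expect_identical(w$grid[1:(d[1] - 2), , ], mk$grid[3:d[1], , ])
  # volume change bounded by the Jacobian range of a smooth field
  fl <- zero
  set.seed(2)
  fl$u_vox <- matrix(rnorm(length(fl$u_vox), 0, 0.6), ncol = 3)
  dense <- muscleshape:::dense_field_cpp(fl$u_vox, fl$ndims, fl$node0, fl$ns,
                                         as.integer(d))
  ja <- sapply(1:3, function(ax) array(dense[, ax], d))
  # central-difference Jacobian of the dense backward map
  J <- with(list(ux = array(dense[, 1], d), uy = array(dense[, 2], d),
                 uz = array(dense[, 3], d)), {
    cd <- muscleshape:::central_diff
    (1 + cd(ux, 1)) * ((1 + cd(uy, 2)) * (1 + cd(uz, 3)) - cd(uy, 3) * cd(uz, 2)) -
      cd(ux, 2) * (cd(uy, 1) * (1 + cd(uz, 3)) - cd(uy, 3) * cd(uz, 1)) +
      cd(ux, 3) * (cd(uy, 1) * cd(uz, 2) - (1 + cd(uy, 2)) * cd(uz, 1))
  })
  wf <- apply_displacement(mk, fl)
  ratio <- sum(wf$grid) / sum(mk$grid)
  # backward-map volume scales like 1/J of the warp
  expect_gte(ratio, 1 / max(J) * 0.9)
  expect_lte(ratio, 1 / max(min(J), 1e-3) * 1.1)
})
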