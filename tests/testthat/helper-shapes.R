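# Shared fixture builders and independent oracles. Everything is generated
# in code; no stored volumes.

ball_mask <- function(r, n = 2 * r + 9, centre = rep((n - 1) / 2, 3),
                      spacing = c(1, 1, 1)) {
  idx <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  g <- array(sqrt(rowSums(sweep(idx, 2, centre)^2)) <= r, c(n, n, n))
  binary_mask(g, spacing = spacing)
}

cube_mask <- function(side, n = side + 6, spacing = c(1, 1, 1)) {
  g <- array(FALSE, c(n, n, n))
  lo <- floor((n - side) / 2) + 1
  g[lo:(lo + side - 1), lo:(lo + side - 1), lo:(lo + side - 1)] <- TRUE
  binary_mask(g, spacing = spacing)
}

random_mask <- function(seed, n = 16, p = 0.5, spacing = c(1, 1, 1)) {
  set.seed(seed)
  # smooth blobby masks: threshold smoothed noise so surfaces are non-trivial
  raw <- array(rnorm(n^3), c(n, n, n))
  sm <- array(muscleshape:::gauss_smooth3(as.numeric(raw), rep(n, 3),
                                          c(2, 2, 2)), rep(n, 3))
  binary_mask(sm > quantile(sm, 1 - p), spacing = spacing)
}

disk_fixture <- function(r, n, centre = c((n + 1) / 2, (n + 1) / 2)) {
  outer(seq_len(n), seq_len(n), function(i, j)
    (i - centre[1])^2 + (j - centre[2])^2 <= r^2)
}

rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

rotation_error_deg <- function(R1, R2) {
  acos(pmin(pmax((sum(diag(crossprod(R1, R2))) - 1) / 2, -1), 1)) * 180 / pi
}

# --- brute-force metric oracles (independent of the implementation path) ---

oracle_surface_pts <- function(mask) {
  g <- mask$grid
  d <- dim(g)
  pts <- NULL
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!g[i, j, k]) next
    nb_all_fg <- TRUE
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + o[1]; jj <- j + o[2]; kk <- k + o[3]
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3] ||
          !g[ii, jj, kk]) { nb_all_fg <- FALSE; break }
    }
    if (!nb_all_fg)
      pts <- rbind(pts, (c(i, j, k) - 1) * mask$spacing + mask$origin)
  }
  pts
}

oracle_metrics <- function(ref, pred) {
  nr <- sum(ref$grid); np <- sum(pred$grid)
  inter <- sum(ref$grid & pred$grid)
  br <- oracle_surface_pts(ref)
  bp <- oracle_surface_pts(pred)
  D <- sqrt(outer(rowSums(br^2), rowSums(bp^2), `+`) - 2 * br %*% t(bp))
  d_r <- apply(D, 1, min) # ref surface -> pred surface
  d_p <- apply(D, 2, min)
  list(dsc = 2 * inter / (nr + np),
       rve = (np - nr) / nr,
       hd = max(max(d_r), max(d_p)),
       assd = (sum(d_r) + sum(d_p)) / (length(d_r) + length(d_p)))
}

# full 2^n enumeration oracle for the signed-rank test
oracle_signed_rank_p <- function(a, b) {
  d <- (a - b)[a != b]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  Wall <- numeric(2^n)
  for (q in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(q)[1:n])
    Wall[q + 1] <- sum(r[bits == 1])
  }
  min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
}

# hand-replayed 2D operator chain (disk morphology via explicit offsets)
oracle_postprocess_slice <- function(m, r = 3, conn = 8, w = 5, thr = 0.5) {
  offs <- which(outer((-r:r)^2, (-r:r)^2, `+`) <= r^2, arr.ind = TRUE) - r - 1
  nr <- nrow(m); nc <- ncol(m)
  shift_ok <- function(g, di, dj, pad) {
    out <- matrix(pad, nr, nc)
    si <- max(1, 1 - di):min(nr, nr - di)
    sj <- max(1, 1 - dj):min(nc, nc - dj)
    out[si + di, sj + dj] <- g[si, sj]
    out
  }
  erode <- function(g) {
    acc <- matrix(TRUE, nr, nc)
    for (q in seq_len(nrow(offs)))
      acc <- acc & shift_ok(g, offs[q, 1], offs[q, 2], TRUE)
    acc
  }
  dilate <- function(g) {
    acc <- matrix(FALSE, nr, nc)
    for (q in seq_len(nrow(offs)))
      acc <- acc | shift_ok(g, offs[q, 1], offs[q, 2], FALSE)
    acc
  }
  lab_flood <- function(g, conn) {
    lab <- matrix(0L, nr, nc)
    nb <- if (conn == 8) expand.grid(di = -1:1, dj = -1:1)
          else data.frame(di = c(1, -1, 0, 0), dj = c(0, 0, 1, -1))
    nb <- nb[!(nb$di == 0 & nb$dj == 0), ]
    cur <- 0L
    for (j in seq_len(nc)) for (i in seq_len(nr)) {
      if (!g[i, j] || lab[i, j] != 0L) next
      cur <- cur + 1L
      stack <- list(c(i, j)); lab[i, j] <- cur
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (q in seq_len(nrow(nb))) {
          ii <- p[1] + nb$di[q]; jj <- p[2] + nb$dj[q]
          if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc &&
              g[ii, jj] && lab[ii, jj] == 0L) {
            lab[ii, jj] <- cur
            stack[[length(stack) + 1]] <- c(ii, jj)
          }
        }
      }
    }
    lab
  }
  g <- erode(m)
  if (!any(g)) return(g)
  lab <- lab_flood(g, conn)
  sizes <- tabulate(lab[lab > 0])
  g <- g & (lab == which.max(sizes))
  g <- dilate(g)
  # fill holes: background flood from the border (4-connectivity)
  bg <- lab_flood(!g, 4)
  border_ids <- setdiff(unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc])), 0L)
  g <- g | !(matrix(bg %in% c(0L, border_ids), nr, nc))
  # exact integer convolution + threshold
  conv <- matrix(0, nr, nc)
  rr <- w %/% 2
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0L
    for (di in -rr:(w - 1 - rr)) for (dj in -rr:(w - 1 - rr)) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc && g[ii, jj])
        acc <- acc + 1L
    }
    conv[i, j] <- acc
  }
  conv > thr * w^2
}
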