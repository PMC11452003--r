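# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_ms <- function(class, msg, ...) {
  stop(structure(class = c(class, "muscleshape_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# voxel index array (0-based triples) of TRUE voxels, column-major order
which_idx3 <- function(grid) {
  w <- which(grid) - 1L
  d <- dim(grid)
  cbind(i = w %% d[1],
        j = (w %/% d[1]) %% d[2],
        k = w %/% (d[1] * d[2]))
}

# 0-based index triples -> world mm coordinates
idx_to_world <- function(idx, spacing, origin) {
  sweep(sweep(idx, 2, spacing, `*`), 2, origin, `+`)
}

world_to_idx <- function(pts, spacing, origin) {
  sweep(sweep(pts, 2, origin, `-`), 2, spacing, `/`)
}

# distance (mm) from every voxel to the nearest TRUE voxel
dist_to <- function(grid, spacing = c(1, 1, 1)) {
  d2 <- edt_squared(as.logical(grid), dim(grid), as.numeric(spacing))
  array(sqrt(d2), dim(grid))
}

is_power_of_two <- function(x) x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
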