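# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never disturb the
# global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic per-item seed derivation from a master seed: a counter-based
# scheme so extending a cohort never reshuffles earlier subjects.
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 2654435761 + as.double(counter) * 7919 + 104729) %%
    2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based). Out-of-grid samples return `fill`.
interp_trilinear <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  x0 <- floor(xi); y0 <- floor(yi); z0 <- floor(zi)
  fx <- xi - x0; fy <- yi - y0; fz <- zi - z0
  acc <- numeric(length(xi))
  mass <- numeric(length(xi))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    xs <- x0 + dx; ys <- y0 + dy; zs <- z0 + dz
    ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3] & w > 0
    if (any(ok)) {
      idx <- xs[ok] + (ys[ok] - 1) * d[1] + (zs[ok] - 1) * d[1] * d[2]
      acc[ok] <- acc[ok] + w[ok] * arr[idx]
      mass[ok] <- mass[ok] + w[ok]
    }
  }
  acc + fill * (1 - mass)
}

# Nearest-neighbour sampling at fractional voxel coordinates (1-based).
interp_nearest <- function(arr, xi, yi, zi, fill = 0) {
  d <- dim(arr)
  xs <- round(xi); ys <- round(yi); zs <- round(zi)
  out <- rep(fill, length(xi))
  ok <- xs >= 1 & xs <= d[1] & ys >= 1 & ys <= d[2] & zs >= 1 & zs <= d[3]
  idx <- xs[ok] + (ys[ok] - 1) * d[1] + (zs[ok] - 1) * d[1] * d[2]
  out[ok] <- arr[idx]
  out
}

# Smooth random scalar field over a voxel grid: iid normal values on a coarse
# control lattice, trilinearly upsampled. `control_spacing` in voxels.
smooth_field <- function(shape, control_spacing = 4) {
  nc <- pmax(2L, ceiling(shape / control_spacing) + 1L)
  coarse <- array(rnorm(prod(nc)), dim = nc)
  # map voxel index i (1..n) onto coarse coordinate 1..nc
  xi <- seq(1, nc[1], length.out = shape[1])
  yi <- seq(1, nc[2], length.out = shape[2])
  zi <- seq(1, nc[3], length.out = shape[3])
  g <- expand.grid(x = xi, y = yi, z = zi)
  array(interp_trilinear(coarse, g$x, g$y, g$z), dim = shape)
}

# 6-connectivity binary erosion / dilation via array shifts.
shift_arr <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

erode6 <- function(m) {
  r <- m
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    sh <- shift_arr(m, s[1], s[2], s[3])
    r <- r * sh  # out-of-grid treated as background
  }
  r
}

dilate6 <- function(m) {
  r <- m
  for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    r <- pmax(r, shift_arr(m, s[1], s[2], s[3]))
  }
  array(r, dim(m))
}
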