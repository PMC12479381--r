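# Shared fixtures and independent brute-force oracles. Everything is built
# in code at test time; nothing is read from disk.

# Reduced-size phantom parameters for fast unit tests (the acceptance suite
# uses the full defaults).
small_params <- function(...) {
  phantom_params(grid_shape = c(56L, 44L, 14L), sn_voxels_target = 400,
                 cc_voxels_target = 1400, ...)
}

# random binary mask with n foreground voxels on a given grid
random_mask <- function(shape, n, spacing = c(0.67, 1.0, 1.34)) {
  idx <- sample(prod(shape), n)
  a <- array(0, shape)
  a[idx] <- 1
  label_mask(a, spacing)
}

# ---- brute-force metric oracles (voxel loops, no shared code paths) ----

bf_dice <- function(x, y) {
  xv <- as.vector(x$data); yv <- as.vector(y$data)
  inter <- 0; nx <- 0; ny <- 0
  for (i in seq_along(xv)) {
    if (xv[i] == 1) nx <- nx + 1
    if (yv[i] == 1) ny <- ny + 1
    if (xv[i] == 1 && yv[i] == 1) inter <- inter + 1
  }
  if (nx + ny == 0) return(1)
  2 * inter / (nx + ny)
}

# boundary voxel centres (mm) by explicit 6-neighbour check
bf_surface <- function(mask) {
  d <- dim(mask$data)
  pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (mask$data[i, j, k] != 1) next
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    on_surface <- FALSE
    for (r in seq_len(6)) {
      p <- nb[r, ]
      if (any(p < 1) || any(p > d)) { on_surface <- TRUE; break }
      if (mask$data[p[1], p[2], p[3]] == 0) { on_surface <- TRUE; break }
    }
    if (on_surface) pts <- rbind(pts, (c(i, j, k) - 1) * mask$spacing)
  }
  pts
}

bf_one_sided <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      dd <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (dd < best) best <- dd
    }
    best
  }, 0)
}

bf_msd <- function(x, y) {
  sa <- bf_surface(x); sb <- bf_surface(y)
  mean(c(bf_one_sided(sa, sb), bf_one_sided(sb, sa)))
}

bf_hd95 <- function(x, y) {
  sa <- bf_surface(x); sb <- bf_surface(y)
  max(quantile(bf_one_sided(sa, sb), 0.95, names = FALSE),
      quantile(bf_one_sided(sb, sa), 0.95, names = FALSE))
}

bf_hd_exact <- function(x, y) {
  sa <- bf_surface(x); sb <- bf_surface(y)
  max(max(bf_one_sided(sa, sb)), max(bf_one_sided(sb, sa)))
}

# small compact blob mask (cuboid plus jitter) guaranteed non-empty
random_blob <- function(shape, target, spacing = c(0.67, 1.0, 1.34)) {
  ctr <- pmax(2, pmin(shape - 1, round(runif(3, 0.3, 0.7) * shape)))
  half <- pmax(0, round((target^(1 / 3) - 1) / 2 + runif(3, 0, 1)))
  a <- array(0, shape)
  lo <- pmax(1, ctr - half); hi <- pmin(shape, ctr + half)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  label_mask(a, spacing)
}

# single-voxel mask helper
one_voxel <- function(shape, at, spacing = c(0.67, 1.0, 1.34)) {
  a <- array(0, shape)
  a[at[1], at[2], at[3]] <- 1
  label_mask(a, spacing)
}
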