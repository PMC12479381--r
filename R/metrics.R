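#' Dice-Sorensen similarity coefficient
#'
#' `DSC = 2|X intersect Y| / (|X| + |Y|)` over the foreground voxels of two
#' binary masks on the same grid. By convention two empty masks score 1 and
#' exactly one empty mask scores 0, so total segmentation failures stay loud
#' (near-zero DSC) rather than turning into NaN.
#'
#' @param x,y [label_mask] objects on the same grid.
#' @return DSC in `[0, 1]`.
#' @export
dice <- function(x, y) {
  stopifnot(is_mask(x), is_mask(y))
  check_same_grid(x, y)
  nx <- sum(x$data); ny <- sum(y$data)
  if (nx + ny == 0) return(1)
  2 * sum(x$data * y$data) / (nx + ny)
}

#' Extract the boundary surface of a mask as points in millimetres
#'
#' The surface is the set of centres of foreground voxels that have at least
#' one face-adjacent (6-connectivity) background neighbour; voxels on the grid
#' edge count the outside as background. Point coordinates are
#' `(index - 1) * spacing`, in mm.
#'
#' @param mask a non-empty [label_mask].
#' @return A numeric matrix with one row per surface point and columns
#'   `x`, `y`, `z` (mm).
#' @export
extract_surface <- function(mask) {
  stopifnot(is_mask(mask))
  if (sum(mask$data) == 0) stop("cannot extract the surface of an empty mask",
                                call. = FALSE)
  interior <- erode6(mask$data)
  boundary <- mask$data * (1 - interior)
  idx <- which(boundary > 0, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, mask$spacing, "*")
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' One-sided surface distances
#'
#' For each point `a` of surface `a`, the minimum Euclidean distance (mm) to
#' any point of surface `b`.
#'
#' @param a,b point matrices as returned by [extract_surface()].
#' @return Numeric vector of length `nrow(a)`.
#' @export
surface_distances <- function(a, b) {
  if (NROW(a) == 0 || NROW(b) == 0) {
    stop("surface point sets must be non-empty", call. = FALSE)
  }
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  # per-coordinate differences: numerically exact (the |a|^2+|b|^2-2ab
  # expansion loses precision by cancellation)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2 +
    outer(a[, 3], b[, 3], "-")^2
  sqrt(apply(d2, 1, min))
}

surfaces_of <- function(x, y) {
  list(a = extract_surface(x), b = extract_surface(y))
}

#' Mean surface distance in millimetres
#'
#' The mean of the two one-sided distance vectors `d(A,B)` and `d(B,A)`
#' concatenated, weighting each surface point equally (the two-direction
#' means coincide when the surfaces have equal size).
#'
#' @param x,y non-empty [label_mask] objects on the same grid.
#' @return MSD in mm.
#' @export
msd <- function(x, y) {
  check_same_grid(x, y)
  if (sum(x$data) == 0 || sum(y$data) == 0) {
    stop("mean surface distance is undefined for an empty mask", call. = FALSE)
  }
  s <- surfaces_of(x, y)
  mean(c(surface_distances(s$a, s$b), surface_distances(s$b, s$a)))
}

#' 95th-percentile Hausdorff distance in millimetres
#'
#' `h(A,B) = P95(d(A,B))` for each direction, then the maximum of the two.
#' Percentiles use linear interpolation between closest order statistics
#' (`quantile` type 7).
#'
#' @inheritParams msd
#' @return HD95 in mm.
#' @export
hd95 <- function(x, y) {
  check_same_grid(x, y)
  if (sum(x$data) == 0 || sum(y$data) == 0) {
    stop("HD95 is undefined for an empty mask", call. = FALSE)
  }
  s <- surfaces_of(x, y)
  hab <- quantile(surface_distances(s$a, s$b), 0.95, names = FALSE, type = 7)
  hba <- quantile(surface_distances(s$b, s$a), 0.95, names = FALSE, type = 7)
  max(hab, hba)
}

#' Evaluate a predicted mask against the truth
#'
#' Bundles DSC, MSD and HD95 for one prediction/truth pair. Surface metrics
#' are reported as `NA` when either mask is empty (DSC is still defined).
#'
#' @param pred,truth [label_mask] objects on the same grid. Bilateral
#'   structures should be passed as their union (the default convention
#'   throughout the package); evaluate sides separately for per-side reports.
#' @param id optional subject identifier carried into the result.
#' @return A one-row `data.frame` with columns `id`, `dsc`, `msd_mm`,
#'   `hd95_mm`.
#' @export
evaluate_pair <- function(pred, truth, id = NA_character_) {
  check_same_grid(pred, truth)
  d <- dice(pred, truth)
  if (sum(pred$data) == 0 || sum(truth$data) == 0) {
    return(data.frame(id = id, dsc = d, msd_mm = NA_real_, hd95_mm = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(id = id, dsc = d, msd_mm = msd(pred, truth),
             hd95_mm = hd95(pred, truth), stringsAsFactors = FALSE)
}
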