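# Combinatorial contrast screening: a K x K matrix of cross-validated DSC
# scores, pairs off the diagonal and single-contrast models on the diagonal,
# plus the derived delta matrices, per-contrast improvement potential and a
# sorted model ranking.

#' Build the contrast-pair screening matrix
#'
#' Entry `(i, j)` is the mean out-of-fold DSC of the segmenter calibrated on
#' contrasts `{i, j}` (`{i}` on the diagonal), averaged over the folds. One
#' calibration is run per unordered pair and stored mirrored, so the matrix
#' is symmetric by construction.
#'
#' @param cohort a `nm_cohort` in which every subject carries every contrast.
#' @param contrasts character vector of K >= 1 contrast names.
#' @param folds a [make_folds()] assignment (default 3 folds, seed 0).
#' @param calibrator function `(cohort, contrasts, folds) -> score` returning
#'   the cross-validated DSC; the default wraps [calibrate()] and reports its
#'   `cv_dsc` attribute.
#' @return A K x K numeric matrix with contrast names on both dimnames,
#'   class `screening_matrix`.
#' @export
build_matrix <- function(cohort, contrasts, folds = NULL, calibrator = NULL) {
  stopifnot(length(contrasts) >= 1)
  for (s in cohort$subjects) {
    missing <- setdiff(contrasts, names(s$images))
    if (length(missing) > 0) {
      stop("subject ", s$subject_id, " is missing contrast(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(folds)) folds <- make_folds(cohort, 3, seed = 0)
  if (is.null(calibrator)) {
    calibrator <- function(cohort, contrasts, folds) {
      attr(calibrate(cohort, contrasts, folds = folds), "cv_dsc")
    }
  }
  K <- length(contrasts)
  A <- matrix(NA_real_, K, K, dimnames = list(contrasts, contrasts))
  for (i in seq_len(K)) {
    for (j in i:K) {
      sc <- calibrator(cohort, unique(contrasts[c(i, j)]), folds)
      A[i, j] <- sc
      A[j, i] <- sc
    }
  }
  class(A) <- c("screening_matrix", class(A))
  A
}

check_square <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  invisible(m)
}

#' Delta-DSC of each pair versus its column's single-contrast model
#'
#' `B[i, j] = A[i, j] - A[j, j]`: row `i` is the influence of adding contrast
#' `i` to models trained on each other contrast; column `j` is the change the
#' contrast-`j` model experiences from additions. The diagonal is zero and
#' `A` is recoverable as `B[i, j] + A[j, j]`.
#'
#' @param m a [build_matrix()] result.
#' @return K x K matrix.
#' @export
delta_vs_single <- function(m) {
  check_square(m)
  b <- sweep(unclass(m), 2, diag(unclass(m)), "-")
  dimnames(b) <- dimnames(m)
  b
}

#' Delta-DSC of each pair versus the best of its constituents
#'
#' `C[i, j] = A[i, j] - max(A[i, i], A[j, j])`; the diagonal is zero and
#' `C <= delta_vs_single` elementwise.
#'
#' @param m a [build_matrix()] result.
#' @return K x K matrix.
#' @export
delta_vs_best <- function(m) {
  check_square(m)
  a <- unclass(m)
  d <- diag(a)
  best <- outer(d, d, pmax)
  out <- a - best
  diag(out) <- 0
  dimnames(out) <- dimnames(m)
  out
}

#' Per-contrast improvement potential
#'
#' For each column `j` of a delta matrix, the mean of the off-diagonal
#' entries: how much the contrast-`j` single model tends to gain from adding
#' an arbitrary second contrast. Entries marked missing (`NA`) are excluded,
#' with the usable count reported alongside.
#'
#' @param b a delta matrix with zero diagonal ([delta_vs_single()]).
#' @return `data.frame` with columns `contrast`, `potential`, `n_used`.
#' @export
improvement_potential <- function(b) {
  check_square(b)
  if (nrow(b) < 2) stop("improvement potential is undefined for K = 1",
                        call. = FALSE)
  stopifnot(all(abs(diag(b)) < 1e-12))
  res <- lapply(seq_len(ncol(b)), function(j) {
    off <- b[-j, j]
    data.frame(contrast = colnames(b)[j],
               potential = mean(off, na.rm = TRUE),
               n_used = sum(!is.na(off)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank all single and pair models by DSC
#'
#' All K singles and K(K-1)/2 pairs sorted from highest to lowest score,
#' tagged by type, with ties broken stably by label.
#'
#' @param m a [build_matrix()] result.
#' @return `data.frame` with columns `label`, `type` (`single`/`pair`),
#'   `score`, of length `K + K(K-1)/2`.
#' @export
rank_models <- function(m) {
  check_square(m)
  cs <- rownames(m)
  K <- length(cs)
  singles <- data.frame(label = cs, type = "single", score = diag(unclass(m)),
                        stringsAsFactors = FALSE)
  pairs <- if (K >= 2) {
    cmb <- combn(K, 2)
    data.frame(label = paste(cs[cmb[1, ]], cs[cmb[2, ]], sep = "+"),
               type = "pair",
               score = unclass(m)[cbind(cmb[1, ], cmb[2, ])],
               stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(singles, pairs)
  out <- out[order(-out$score, out$label), ]
  rownames(out) <- NULL
  out
}
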