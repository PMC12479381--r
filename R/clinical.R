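# Clinical-validation statistics: Mann-Whitney tests, common-language effect
# size, dominant-side assignment, SBR laterality and the seed-averaged
# 2-fold cross-validated logistic ROC.

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. The two-sided p-value uses the exact null
#' distribution when it is feasible (`pwilcox` for tie-free samples; full
#' enumeration of rank assignments for tied samples when the number of
#' assignments is at most `2e5`) and the normal approximation with tie
#' correction and continuity correction otherwise. If every value is
#' identical across both samples, `p = 1`.
#'
#' @param x,y numeric samples, both non-empty.
#' @return list with `u` (the U statistic for `x`), `p` (two-sided) and
#'   `method`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (length(unique(c(x, y))) == 1) {
    return(list(u = u, p = 1, method = "degenerate"))
  }
  ties <- any(duplicated(c(x, y)))
  if (!ties && max(nx, ny) <= 50) {
    # exact distribution of U for untied samples
    p_low <- stats::pwilcox(u, nx, ny)
    p_high <- 1 - stats::pwilcox(u - 1, nx, ny)
    return(list(u = u, p = min(1, 2 * min(p_low, p_high)),
                method = "exact"))
  }
  if (choose(nx + ny, nx) <= 2e5) {
    # enumeration over all rank assignments, valid with midrank ties
    sets <- combn(nx + ny, nx)
    us <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, p = p, method = "enumeration"))
  }
  n <- nx + ny
  tie_tab <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  mu <- nx * ny / 2
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Common-language effect size
#'
#' The probability that a random draw from `x` exceeds one from `y`, with
#' ties counted one half:
#' `(#\{x_i > y_j\} + 0.5 #\{x_i = y_j\}) / (n_x n_y)`. Satisfies
#' `cles(x, y) + cles(y, x) = 1` exactly and equals `U(x) / (n_x n_y)`.
#'
#' @param x,y numeric samples, both non-empty.
#' @return Proportion in `[0, 1]`.
#' @export
cles <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  d <- outer(x, y, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

#' Left/right specific-binding-ratio ratio
#'
#' @param sbr_left,sbr_right strictly positive SBR values (vectorized).
#' @return `sbr_left / sbr_right`.
#' @export
sbr_ratio <- function(sbr_left, sbr_right) {
  if (any(sbr_left <= 0) || any(sbr_right <= 0)) {
    stop("SBR values must be strictly positive", call. = FALSE)
  }
  sbr_left / sbr_right
}

#' Clinically dominant side from per-side UPDRS-III sums
#'
#' The side with the larger brady-rigidity + tremor sum; equal sums give
#' `"undetermined"` (excluded from laterality analyses).
#'
#' @param updrs_left,updrs_right non-negative per-side sums (vectorized).
#' @return Character vector in `{"left", "right", "undetermined"}`.
#' @export
dominant_side <- function(updrs_left, updrs_right) {
  stopifnot(all(updrs_left >= 0), all(updrs_right >= 0))
  ifelse(updrs_left > updrs_right, "left",
         ifelse(updrs_right > updrs_left, "right", "undetermined"))
}

#' Area under the ROC curve (rank form)
#'
#' The probability that a random positive outranks a random negative, ties
#' counted one half: identical to `cles(scores[positive], scores[negative])`,
#' hence invariant under strictly increasing score transforms.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels logical (or coercible 0/1) class labels.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  cles(scores[labels], scores[!labels])
}

# Ridge-penalized logistic regression (penalty excludes the intercept) by
# iteratively reweighted least squares. The light fixed penalty guarantees
# convergence on separable folds; with two standardized features and a few
# dozen subjects this is the entire model class needed here.
ridge_logistic <- function(X, y, lambda = 0.01, max_iter = 100, tol = 1e-8) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X1, X1 * w) + pen
    beta_new <- solve(H, crossprod(X1, w * z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Seed-averaged cross-validated logistic ROC
#'
#' For each seed: a stratified random fold split (subject-level), per fold a
#' lightly ridge-penalized logistic model fitted on the training fold with
#' features standardized on the training fold only, out-of-fold scores
#' pooled across folds into a single AUC per seed. Reports the per-seed AUCs
#' and their arithmetic mean. Bit-reproducible under a fixed master seed.
#'
#' @param features numeric matrix / data.frame (subjects x features) or a
#'   vector for a single feature.
#' @param labels logical (or coercible) class labels; each class needs at
#'   least `n_folds` members (>= 5 per class recommended).
#' @param n_folds folds per seed (default 2).
#' @param n_seeds number of random splits averaged (default 100).
#' @param master_seed integer master seed.
#' @param lambda ridge penalty (fixed, light).
#' @return list with `mean_auc`, `aucs` (per seed), `n_folds`, `n_seeds`,
#'   `features` (names).
#' @export
cv_roc_auc <- function(features, labels, n_folds = 2, n_seeds = 100,
                       master_seed = 0, lambda = 0.01) {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  y <- as.numeric(as.logical(labels))
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2 || min(table(y)) < n_folds) {
    stop("each class must have at least n_folds members", call. = FALSE)
  }
  aucs <- vapply(seq_len(n_seeds), function(s) {
    with_seed(derive_seed(master_seed, s), {
      fold <- integer(length(y))
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      scores <- numeric(length(y))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        mu <- colMeans(X[tr, , drop = FALSE])
        sdv <- apply(X[tr, , drop = FALSE], 2, sd)
        sdv[sdv == 0] <- 1
        Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
        beta <- ridge_logistic(Xs[tr, , drop = FALSE], y[tr], lambda)
        scores[!tr] <- drop(cbind(1, Xs[!tr, , drop = FALSE]) %*% beta)
      }
      auc(scores, y == 1)
    })
  }, 0)
  list(mean_auc = mean(aucs), aucs = aucs, n_folds = n_folds,
       n_seeds = n_seeds, features = colnames(X))
}

#' Clinical table of a cohort
#'
#' @param cohort a `nm_cohort` whose subjects passed [assign_clinical()].
#' @return `data.frame` with ids, group, UPDRS sums, SBR values, dominant
#'   side and truth per-side CNR / volumes.
#' @export
clinical_table <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, group = s$group,
               updrs_left = s$clinical$updrs_left,
               updrs_right = s$clinical$updrs_right,
               sbr_left = s$clinical$sbr_left,
               sbr_right = s$clinical$sbr_right,
               dominant_side = dominant_side(s$clinical$updrs_left,
                                             s$clinical$updrs_right),
               cnr_left = s$truth$cnr_left, cnr_right = s$truth$cnr_right,
               sn_volume_left_mm3 = s$truth$sn_volume_left_mm3,
               sn_volume_right_mm3 = s$truth$sn_volume_right_mm3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Symptomatic laterality analysis
#'
#' For each per-side measure (left/right SBR ratio, truth CNR ratio, truth
#' volume ratio), the Mann-Whitney p-value and common-language effect size
#' between left- and right-dominant PD subjects. HC and undetermined-side
#' subjects are excluded. A measure is skipped (NA row, with a message) when
#' fewer than 3 subjects remain per side.
#'
#' @param cohort a `nm_cohort`.
#' @param extra_measures optional named list of per-subject numeric vectors
#'   (aligned with [clinical_table()] rows) to analyse alongside the
#'   defaults.
#' @return `data.frame` with columns `measure`, `n_left`, `n_right`, `cles`,
#'   `p`.
#' @export
laterality_analysis <- function(cohort, extra_measures = NULL) {
  tb <- clinical_table(cohort)
  pd <- tb[tb$group == "PD" & tb$dominant_side != "undetermined", ]
  measures <- c(list(
    sbr_ratio = sbr_ratio(pd$sbr_left, pd$sbr_right),
    cnr_ratio = pd$cnr_left / pd$cnr_right,
    volume_ratio = pd$sn_volume_left_mm3 / pd$sn_volume_right_mm3
  ), if (!is.null(extra_measures)) {
    lapply(extra_measures, function(v) v[match(pd$subject_id, tb$subject_id)])
  })
  left <- pd$dominant_side == "left"
  rows <- lapply(names(measures), function(nm) {
    v <- measures[[nm]]
    nl <- sum(left); nr <- sum(!left)
    if (nl < 3 || nr < 3) {
      message("laterality analysis skipped for ", nm,
              ": fewer than 3 subjects per side")
      return(data.frame(measure = nm, n_left = nl, n_right = nr,
                        cles = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mw <- mann_whitney(v[left], v[!left])
    data.frame(measure = nm, n_left = nl, n_right = nr,
               cles = cles(v[left], v[!left]), p = mw$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
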