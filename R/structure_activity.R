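#' Variation filter for descriptor matrices
#'
#' Keeps a descriptor only when at least two chemicals differ from the modal
#' value of the column: near-constant descriptors have essentially no power
#' to detect associations. The filter is idempotent.
#'
#' @param x Numeric matrix or data frame, chemicals x descriptors.
#' @return The filtered matrix (possibly zero columns).
#' @export
variation_filter <- function(x) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 3)
  keep <- apply(x, 2, function(col) {
    tab <- table(col)
    modal <- as.numeric(names(tab)[which.max(tab)])
    sum(col != modal) >= 2
  })
  x[, keep, drop = FALSE]
}

#' Spearman screen of descriptors against bioactivity phenotypes
#'
#' Spearman rank correlations (average ranks on ties) for every descriptor x
#' phenotype pair, with two-sided p-values from the t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` and Benjamini-Hochberg q-values across
#' all pairs. Pairs are flagged significant at `q < 0.1`. A negative
#' correlation means lower POD (higher potency) with a higher descriptor
#' value. Zero-variance vectors give undefined correlations and are excluded
#' (counted in the `n_excluded` attribute).
#'
#' @param descriptors Numeric matrix, chemicals x descriptors (rownames =
#'   chemical ids).
#' @param bioactivity Numeric matrix, chemicals x phenotype-variables
#'   (aligned rows), e.g. log10 PODs.
#' @param q_threshold Significance threshold on the BH q-value (0.1).
#' @return Tibble: `descriptor`, `phenotype`, `spearman_rho`, `p`, `q`,
#'   `significant`.
#' @export
spearman_screen <- function(descriptors, bioactivity, q_threshold = 0.1) {
  descriptors <- as.matrix(descriptors)
  bioactivity <- as.matrix(bioactivity)
  stopifnot(nrow(descriptors) == nrow(bioactivity), nrow(descriptors) >= 5)
  n <- nrow(descriptors)
  if (is.null(colnames(descriptors))) {
    colnames(descriptors) <- paste0("d", seq_len(ncol(descriptors)))
  }
  if (is.null(colnames(bioactivity))) {
    colnames(bioactivity) <- paste0("y", seq_len(ncol(bioactivity)))
  }
  rx <- apply(descriptors, 2, rank)
  ry <- apply(bioactivity, 2, rank)
  sd_x <- apply(rx, 2, sd)
  sd_y <- apply(ry, 2, sd)
  grid <- tidyr::expand_grid(descriptor = colnames(descriptors),
                             phenotype = colnames(bioactivity))
  # cor(rx, ry) is descriptors x phenotypes; the grid is descriptor-major
  rho_mat <- suppressWarnings(stats::cor(rx, ry))
  grid$spearman_rho <- as.numeric(t(rho_mat))
  bad <- sd_x[grid$descriptor] == 0 | sd_y[grid$phenotype] == 0
  grid$spearman_rho[bad] <- NA_real_
  r <- grid$spearman_rho
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  grid$p <- 2 * pt(-abs(tstat), df = n - 2)
  grid$p[!is.na(r) & abs(r) == 1] <- 0
  grid$q <- NA_real_
  ok <- !is.na(grid$p)
  grid$q[ok] <- p.adjust(grid$p[ok], method = "BH")
  grid$significant <- !is.na(grid$q) & grid$q < q_threshold
  n_excluded <- sum(bad)
  attr(grid, "n_excluded") <- n_excluded
  grid
}

# precompute everything y-independent for ridge CV on a fixed design and
# fold assignment: per-fold standardized SVD, hat diagonals per penalty,
# and held-out projection matrices
ridge_precompute <- function(x, folds, lambda) {
  lapply(unique(sort(folds)), function(f) {
    tr <- which(folds != f)
    te <- which(folds == f)
    xt <- x[tr, , drop = FALSE]
    ctr <- colMeans(xt)
    scl <- apply(xt, 2, sd)
    scl[scl == 0] <- Inf  # zero-variance column in fold: contributes nothing
    xs <- sweep(sweep(xt, 2, ctr), 2, scl, "/")
    sv <- svd(xs)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    u <- sv$u[, pos, drop = FALSE]
    d <- sv$d[pos]
    v <- sv$v[, pos, drop = FALSE]
    d2 <- d^2
    s_shrink <- outer(d2, lambda, function(a, l) a / (a + l))   # r x L
    s_beta <- outer(seq_along(d), seq_along(lambda), function(i, j) {
      d[i] / (d2[i] + lambda[j])
    })
    h <- (u^2) %*% s_shrink                                     # n_tr x L
    xe <- sweep(sweep(x[te, , drop = FALSE], 2, ctr), 2, scl, "/")
    g <- xe %*% v                                               # n_te x r
    list(tr = tr, te = te, u = u, s_shrink = s_shrink, s_beta = s_beta,
         h = h, g = g)
  })
}

# cross-validated ridge predictions for every column of y (n x m), choosing
# the penalty per fold by leave-one-out PRESS on the training fold
ridge_cv_core <- function(pre, y) {
  y <- as.matrix(y)
  n <- nrow(y); m <- ncol(y)
  preds <- matrix(NA_real_, n, m)
  nl <- ncol(pre[[1]]$s_shrink)
  for (fold in pre) {
    ytr <- y[fold$tr, , drop = FALSE]
    mtr <- colMeans(ytr)
    yc <- sweep(ytr, 2, mtr)
    a <- crossprod(fold$u, yc)                    # r x m
    press <- matrix(NA_real_, nl, m)
    pred_l <- array(NA_real_, c(nl, length(fold$te), m))
    for (l in seq_len(nl)) {
      fitted <- fold$u %*% (fold$s_shrink[, l] * a)
      resid <- (yc - fitted) / (1 - fold$h[, l])
      press[l, ] <- colSums(resid^2)
      pred_l[l, , ] <- sweep(fold$g %*% (fold$s_beta[, l] * a), 2, mtr, "+")
    }
    best <- apply(press, 2, which.min)
    for (j in seq_len(m)) preds[fold$te, j] <- pred_l[best[j], , j]
  }
  preds
}

#' Cross-validated common-penalty ridge prediction of one phenotype
#'
#' Multivariate ridge regression with a single penalty shared across all
#' descriptors. Outer cross-validation (default leave-one-out) produces an
#' out-of-fold prediction for every chemical; within each training fold the
#' penalty is chosen from `lambda` by the closed-form leave-one-out PRESS.
#' Descriptor columns are centered and scaled inside each training fold.
#'
#' @param descriptors Numeric matrix, chemicals x descriptors (already
#'   variation-filtered).
#' @param y Numeric phenotype vector (e.g. log10 POD), one value per
#'   chemical.
#' @param n_folds Number of outer folds; `NULL` (default) means leave-one-out.
#' @param lambda Penalty grid (default 25 log-spaced values).
#' @param seed Seed for the fold assignment (irrelevant under leave-one-out).
#' @return List: `cv_r` (Pearson correlation between cross-validated
#'   predictions and observations; `NA` for a constant phenotype),
#'   `predictions`, `folds`.
#' @export
ridge_cv_predict <- function(descriptors, y, n_folds = NULL,
                             lambda = 10^seq(-2, 5, length.out = 25),
                             seed = 1L) {
  x <- as.matrix(descriptors)
  stopifnot(nrow(x) == length(y), all(is.finite(y)) || all(!is.na(y)))
  n <- nrow(x)
  folds <- make_folds(n, n_folds, seed)
  pre <- ridge_precompute(x, folds, lambda)
  preds <- as.numeric(ridge_cv_core(pre, matrix(y, ncol = 1)))
  cv_r <- if (sd(y) == 0 || sd(preds) == 0) NA_real_ else cor(preds, y)
  list(cv_r = cv_r, predictions = preds, folds = folds)
}

make_folds <- function(n, n_folds = NULL, seed = 1L) {
  if (is.null(n_folds) || n_folds >= n) return(seq_len(n))
  stopifnot(n_folds >= 2)
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}

#' Permutation-calibrated significance of cross-validated predictions
#'
#' For each bioactivity phenotype, computes the observed cross-validated
#' prediction correlation and an empirical p-value from `n_perm` permutations
#' of the phenotype labels across chemicals (the whole CV procedure,
#' including per-fold penalty selection, is re-run on every permutation):
#' `empirical_p = (1 + #\{permuted r >= observed r\}) / (n_perm + 1)`.
#' P-values are then adjusted across phenotypes with Holm's method (`p_adj`)
#' and the Benjamini-Hochberg FDR (`q`).
#'
#' @param descriptors Numeric matrix, chemicals x descriptors.
#' @param bioactivity Numeric matrix, chemicals x phenotype-variables.
#' @param n_perm Number of permutations (10,000 in full mode; 999 at desk
#'   scale; below 100 triggers a resolution warning).
#' @param n_folds Outer folds (`NULL` = leave-one-out).
#' @param lambda Penalty grid.
#' @param seed Seed for permutations and fold assignment.
#' @return Tibble: `phenotype`, `cv_prediction_r`, `empirical_p`, `p_adj`,
#'   `q`.
#' @export
permutation_significance <- function(descriptors, bioactivity, n_perm = 999,
                                     n_folds = NULL,
                                     lambda = 10^seq(-2, 5, length.out = 25),
                                     seed = 1L) {
  x <- as.matrix(descriptors)
  yb <- as.matrix(bioactivity)
  stopifnot(nrow(x) == nrow(yb))
  if (n_perm < 100) warning("n_perm < 100: empirical p-value resolution is coarse")
  n <- nrow(x)
  folds <- make_folds(n, n_folds, seed)
  pre <- ridge_precompute(x, folds, lambda)
  set.seed(child_seed(seed, "permutations"))
  perms <- replicate(n_perm, sample.int(n))
  out <- purrr::map_dfr(seq_len(ncol(yb)), function(j) {
    y <- yb[, j]
    if (sd(y) == 0) {
      return(tibble::tibble(phenotype = colnames(yb)[j] %||% paste0("y", j),
                            cv_prediction_r = NA_real_,
                            empirical_p = NA_real_))
    }
    ymat <- cbind(y, matrix(y[perms], n, n_perm))
    preds <- ridge_cv_core(pre, ymat)
    rs <- vapply(seq_len(ncol(ymat)), function(k) {
      p <- preds[, k]
      if (sd(p) == 0) 0 else cor(p, ymat[, k])
    }, numeric(1))
    tibble::tibble(
      phenotype = colnames(yb)[j] %||% paste0("y", j),
      cv_prediction_r = rs[1],
      empirical_p = (1 + sum(rs[-1] >= rs[1])) / (n_perm + 1))
  })
  ok <- !is.na(out$empirical_p)
  out$p_adj <- NA_real_
  out$q <- NA_real_
  out$p_adj[ok] <- p.adjust(out$empirical_p[ok], method = "holm")
  out$q[ok] <- p.adjust(out$empirical_p[ok], method = "BH")
  out
}

#' Assemble the bioactivity matrix from donor-level PODs
#'
#' Builds the chemicals x phenotype-variables matrix used for
#' structure-activity analyses: per-donor PODs for each phenotype plus the
#' across-donor minimum per phenotype (85 variables at 5 phenotypes x 16
#' donors). PODs enter as log10(µM); censored or inactive entries are imputed
#' at 3x the maximum tested concentration (300 µM by default), consistent
#' with the POD-range activity criterion.
#'
#' @param donor_pods Tibble: `chemical_id`, `phenotype`, `donor_id`, `pod`
#'   (µM, `Inf` = censored).
#' @param censor_value Imputation value for censored PODs (µM).
#' @return Numeric matrix, chemicals x (phenotypes x (donors + 1)), rownames
#'   = chemical ids; columns named `<phenotype>.<donor>` and
#'   `<phenotype>.min`.
#' @export
build_bioactivity <- function(donor_pods, censor_value = 300) {
  check_columns(donor_pods, c("chemical_id", "phenotype", "donor_id", "pod"),
                "donor_pods")
  dp <- donor_pods |>
    dplyr::mutate(pod_imp = ifelse(is.finite(.data$pod), .data$pod,
                                   censor_value))
  mins <- dp |>
    dplyr::group_by(.data$chemical_id, .data$phenotype) |>
    dplyr::summarise(pod_imp = min(.data$pod_imp), .groups = "drop") |>
    dplyr::mutate(donor_id = "min")
  long <- dplyr::bind_rows(dp[names(mins)], mins) |>
    dplyr::mutate(variable = paste(.data$phenotype, .data$donor_id, sep = "."),
                  log10_pod = log10(.data$pod_imp))
  wide <- tidyr::pivot_wider(long[c("chemical_id", "variable", "log10_pod")],
                             names_from = "variable",
                             values_from = "log10_pod")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$chemical_id
  m
}
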