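test_that("variation filter requires two differing samples and is idempotent", {
  x <- cbind(one_diff = c(rep(0, 9), 1),
             two_diff = c(rep(0, 8), 1, 1),
             constant = rep(3, 10),
             spread = 1:10)
  xf <- variation_filter(x)
  expect_setequal(colnames(xf), c("two_diff", "spread"))
  expect_identical(variation_filter(xf), xf)
})

test_that("Spearman screen matches hand values and cor.test on random data", {
  # hand-derived: sum d^2 = 2 -> rho = 1 - 12/120 = 0.9
  x <- matrix(c(1, 2, 3, 4, 5), ncol = 1, dimnames = list(NULL, "d1"))
  y <- matrix(c(1, 2, 3, 5, 4), ncol = 1, dimnames = list(NULL, "y1"))
  sc <- spearman_screen(x, y)
  expect_equal(sc$spearman_rho, 0.9)
  sc2 <- spearman_screen(x, -x + 10)
  expect_equal(sc2$spearman_rho, -1)
  # random 20 x 10 matrices vs the independent reference implementation
  set.seed(14)
  xm <- matrix(rnorm(20 * 10), 20, dimnames = list(NULL, paste0("d", 1:10)))
  xm[, 3] <- round(xm[, 3])  # introduce ties
  ym <- matrix(rnorm(20 * 4), 20, dimnames = list(NULL, paste0("y", 1:4)))
  sc3 <- spearman_screen(xm, ym)
  for (k in sample(nrow(sc3), 12)) {
    i <- match(sc3$descriptor[k], paste0("d", 1:10))
    j <- match(sc3$phenotype[k], paste0("y", 1:4))
    ref <- suppressWarnings(
      stats::cor.test(xm[, i], ym[, j], method = "spearman", exact = FALSE))
    expect_equal(sc3$spearman_rho[k], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(sc3$p[k], ref$p.value, tolerance = 1e-9)
  }
  # zero-variance descriptor excluded with count
  xz <- cbind(xm, dz = rep(1, 20))
  scz <- spearman_screen(xz, ym)
  expect_equal(attr(scz, "n_excluded"), 4)
  expect_true(all(is.na(scz$spearman_rho[scz$descriptor == "dz"])))
})

test_that("BH and Holm adjustments match brute-force step procedures", {
  # worked BH example: all q equal 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"), rep(0.04, 4))
  expect_equal(bh_brute(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # worked Holm example
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
  expect_equal(holm_brute(c(0.01, 0.04)), c(0.02, 0.04))
  # random vectors: package route (p.adjust) agrees with brute force
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
    expect_equal(p.adjust(p, "holm"), holm_brute(p), tolerance = 1e-12)
  }
})

test_that("ridge CV detects planted signal and stays null-calibrated", {
  set.seed(4)
  n <- 56; p <- 123
  x <- matrix(rnorm(n * p), n)
  beta <- c(rnorm(10), rep(0, p - 10))
  signal <- as.numeric(x %*% beta)
  y <- signal + rnorm(n, 0, sd(signal) / 3)  # 3:1 signal-to-noise
  fit <- ridge_cv_predict(x, y)
  expect_gt(fit$cv_r, 0.5)
  expect_length(fit$predictions, n)
  # pure noise: cv r centered near zero
  rs <- vapply(1:50, function(i) {
    set.seed(100 + i)
    ridge_cv_predict(x, rnorm(n))$cv_r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 0.2)
})

test_that("ridge agrees with glmnet at a fixed penalty (independent route)", {
  skip_if_not_installed("glmnet")
  set.seed(6)
  n <- 40; p <- 12
  x <- matrix(rnorm(n * p), n)
  y <- as.numeric(x[, 1] - x[, 2] + rnorm(n, 0, 0.5))
  lam <- 3
  # our closed-form held-out prediction at fixed lambda, leave-one-out
  pre <- cardiopop:::ridge_precompute(x, seq_len(n), lam)
  ours <- as.numeric(cardiopop:::ridge_cv_core(pre, matrix(y, ncol = 1)))
  ref <- vapply(seq_len(n), function(i) {
    xt <- x[-i, ]; yt <- y[-i]
    ctr <- colMeans(xt); scl <- apply(xt, 2, sd)
    xs <- scale(xt, ctr, scl)
    # glmnet's gaussian path standardizes y internally, so its lambda is on
    # the RSS/(2n) + lambda*sd(y)*||b||^2/2 scale
    g <- glmnet::glmnet(xs, yt, alpha = 0,
                        lambda = lam / nrow(xs) * sd(yt),
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-14)
    as.numeric(glmnet::predict.glmnet(
      g, matrix(scale(x[i, , drop = FALSE], ctr, scl), 1)))
  }, numeric(1))
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("duplicating rows leaves fixed-penalty held-out predictions unchanged", {
  # ridge linearity: leave-pair-out on the duplicated data with penalty
  # 2*lambda equals leave-one-out on the originals with lambda (the RSS term
  # doubles, the penalty must too)
  set.seed(7)
  n <- 15; p <- 6
  x <- matrix(rnorm(n * p), n)
  y <- as.numeric(x[, 1] + rnorm(n, 0, 0.3))
  lam <- 5
  pre1 <- cardiopop:::ridge_precompute(x, seq_len(n), lam)
  p1 <- as.numeric(cardiopop:::ridge_cv_core(pre1, matrix(y, ncol = 1)))
  x2 <- rbind(x, x); y2 <- c(y, y)
  folds2 <- rep(seq_len(n), 2)  # both copies of a chemical held out together
  pre2 <- cardiopop:::ridge_precompute(x2, folds2, 2 * lam)
  p2 <- as.numeric(cardiopop:::ridge_cv_core(pre2, matrix(y2, ncol = 1)))
  expect_equal(p2[seq_len(n)], p1, tolerance = 0.02)
  expect_equal(p2[n + seq_len(n)], p2[seq_len(n)], tolerance = 1e-8)
})

test_that("permutation p-values hit the formula floor and are null-uniform", {
  set.seed(9)
  n <- 24
  x <- matrix(rnorm(n * 8), n)
  y <- as.numeric(x[, 1] * 2 + rnorm(n, 0, 0.2))  # strong signal
  res <- permutation_significance(x, cbind(strong = y), n_perm = 199,
                                  seed = 10)
  expect_equal(res$empirical_p, 1 / 200)  # observed r beats every permutation
  expect_warning(
    permutation_significance(x, cbind(y = y), n_perm = 50, seed = 1),
    "resolution")
  # null calibration on a reduced grid (acceptance covers the 85-variable case)
  yn <- matrix(rnorm(n * 20), n)
  resn <- permutation_significance(x, yn, n_perm = 199, seed = 11)
  expect_gt(suppressWarnings(
    stats::ks.test(resn$empirical_p, "punif")$p.value), 0.01)
  expect_true(all(resn$empirical_p >= 1 / 200))
  expect_true(all(resn$p_adj >= resn$empirical_p - 1e-12))
  expect_true(all(resn$q >= resn$empirical_p / length(resn$empirical_p)))
})

test_that("bioactivity matrix has phenotype x (donors + 1) layout with imputation", {
  dp <- tidyr::expand_grid(chemical_id = c("A", "B", "C"),
                           phenotype = c("p1", "p2"),
                           donor_id = c("d1", "d2"))
  dp$pod <- c(1, 2, 4, 8, Inf, Inf, 16, 32, 3, 9, 27, 81)
  m <- build_bioactivity(dp, censor_value = 300)
  expect_equal(dim(m), c(3, 2 * 3))  # 2 phenotypes x (2 donors + min)
  expect_equal(sort(rownames(m)), c("A", "B", "C"))
  expect_equal(m["A", "p1.min"], log10(1))
  expect_equal(m["B", "p1.d1"], log10(300))  # censored imputed at 300
  expect_equal(m["B", "p1.min"], log10(300))
})
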