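test_that("Ledoit-Wolf shrinkage behaves across the sample-size regimes", {
  set.seed(61)
  # n >> p with structured covariance: almost no shrinkage
  L <- matrix(c(2, 0, 0, 0, 0, 1, 0.5, 0, 0, 0, 0, 0.5, 1, 0, 0,
                0, 0, 0, 0.5, 0, 0, 0, 0, 0, 3), 5, 5)
  big <- matrix(rnorm(5000 * 5), 5000, 5) %*% L
  sc <- shrink_covariance(big)
  expect_lt(sc$lambda, 0.05)
  # a single repeated observation has no empirical structure: full shrinkage
  rep1 <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)
  expect_equal(shrink_covariance(rep1)$lambda, 1)
  # spectral floor of the convex combination
  small <- matrix(rnorm(8 * 12), 8, 12)
  sc2 <- shrink_covariance(small)
  mu <- mean(diag(crossprod(sweep(small, 2, colMeans(small))) / 8))
  expect_gte(min(eigen(sc2$sigma, symmetric = TRUE)$values) * (1 + 1e-12),
             sc2$lambda * mu)
  expect_error(shrink_covariance(small[1, , drop = FALSE]), "2 observations")
})

test_that("CSP matches a brute-force variance-ratio search on a 2-channel toy", {
  set.seed(62)
  n_ep <- 40; n_s <- 200
  covs_A <- array(0, c(2, 2, n_ep)); covs_B <- covs_A
  for (i in seq_len(n_ep)) {
    xa <- rbind(rnorm(n_s, sd = 3), rnorm(n_s, sd = 1))
    xb <- rbind(rnorm(n_s, sd = 1), rnorm(n_s, sd = 1))
    covs_A[, , i] <- tcrossprod(xa) / n_s
    covs_B[, , i] <- tcrossprod(xb) / n_s
  }
  model <- fit_csp(covs_A, covs_B, n_pairs = 1)
  CA <- apply(covs_A, c(1, 2), mean); CB <- apply(covs_B, c(1, 2), mean)
  # brute force over 3600 unit vectors
  ang <- seq(0, pi, length.out = 3600)
  ratios <- vapply(ang, function(a) {
    w <- c(cos(a), sin(a))
    (w %*% CA %*% w) / (w %*% (CA + CB) %*% w)
  }, numeric(1))
  w1 <- model$filters[, 1]
  r1 <- (w1 %*% CA %*% w1) / (w1 %*% (CA + CB) %*% w1)
  expect_lt(abs(r1 - max(ratios)) / max(ratios), 0.01)
  # normalization w' (CA+CB) w = 1 (shrunk composite)
  comp <- model$composite_cov
  expect_equal(as.numeric(w1 %*% comp %*% w1), 1, tolerance = 1e-8)
})

test_that("CSP yields 4 filters with flat eigenvalues when classes match", {
  set.seed(63)
  covs <- array(0, c(6, 6, 60))
  L <- matrix(rnorm(36), 6)
  for (i in 1:60)
    covs[, , i] <- tcrossprod(L %*% matrix(rnorm(6 * 100), 6)) / 100
  model <- fit_csp(covs[, , 1:30], covs[, , 31:60], n_pairs = 2)
  expect_equal(ncol(model$filters), 4)
  expect_true(all(abs(model$eigenvalues - 0.5) < 0.1))
})

test_that("sLDA reduces to closed-form LDA and classifies separable data", {
  set.seed(64)
  # hand-computed 2-D example at lambda = 0
  X <- rbind(c(1, 0), c(2, 1), c(0, -1), c(5, 4), c(6, 5), c(7, 3))
  y <- c("low", "low", "low", "high", "high", "high")
  m <- fit_slda(X, y, lambda = 0)
  mu0 <- colMeans(X[1:3, ]); mu1 <- colMeans(X[4:6, ])
  pooled <- rbind(sweep(X[1:3, ], 2, mu0), sweep(X[4:6, ], 2, mu1))
  S <- crossprod(pooled) / 6
  w_ref <- solve(S, mu1 - mu0)
  expect_lt(max(abs(m$weights - w_ref)), 1e-10)
  expect_equal(m$bias, -sum(w_ref * (mu0 + mu1)) / 2, tolerance = 1e-12)
  # symmetric means with identity covariance: w along the mean difference
  Xs <- rbind(matrix(rnorm(400), 200) - 3, matrix(rnorm(400), 200) + 3)
  ys <- rep(c("low", "high"), each = 200)
  ms <- fit_slda(Xs, ys)
  expect_lt(abs(ms$weights[1] / ms$weights[2] - 1), 0.1)
  expect_lt(abs(ms$bias) / sqrt(sum(ms$weights^2)), 0.2)
  expect_equal(mean(predict(ms, Xs) == ys), 1)
})

test_that("mRMR defers redundant copies and matches brute-force greedy MI", {
  set.seed(65)
  n <- 400
  y <- rep(c("low", "high"), each = n / 2)
  f1 <- ifelse(y == "high", 1, 0) + rnorm(n, sd = 0.3)
  f2 <- f1                                  # exact redundant copy
  f3 <- rnorm(n)
  X <- cbind(f1, f2, f3)
  sel <- mrmr_select(X, y, k = 3)
  expect_equal(sel[1:2], c(1, 3))           # the copy is deferred
  # independent brute-force greedy on the same discretization contract
  bins <- function(v) as.integer(cut(rank(v, ties.method = "first"),
                                     breaks = 8, labels = FALSE))
  mi <- function(a, b) {
    p <- table(a, b) / length(a)
    pa <- rowSums(p); pb <- colSums(p); nz <- p > 0
    sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  }
  D <- apply(X, 2, bins)
  rel <- apply(D, 2, mi, b = y)
  first <- unname(which.max(rel))
  rest <- setdiff(1:3, first)
  second <- rest[unname(which.max(rel[rest] -
                             vapply(rest, function(j) mi(D[, j], D[, first]),
                                    numeric(1))))]
  expect_equal(sel[1], first)
  expect_equal(sel[2], second)
  # k = feature count returns everything, relevance-first
  expect_setequal(mrmr_select(X, y, k = 3), 1:3)
  expect_error(mrmr_select(X, y, k = 9), "exceeds")
})

test_that("under label-independent features the first mRMR pick is null-level", {
  set.seed(66)
  n <- 200
  X <- matrix(rnorm(n * 10), n, 10)
  y <- rep(c("low", "high"), each = n / 2)
  sel <- mrmr_select(X, y, k = 1)
  obs <- flightload:::discrete_mi(flightload:::equal_freq_bins(X[, sel[1]]), y)
  null <- replicate(200, {
    yp <- sample(y)
    max(apply(X, 2, function(v)
      flightload:::discrete_mi(flightload:::equal_freq_bins(v), yp)))
  })
  expect_lt(obs, quantile(null, 0.99))
})

test_that("cross-validation is stratified, leakage-free and reports coherent metrics", {
  set.seed(67)
  n <- 100
  y <- rep(c("low", "high"), each = n / 2)
  fold <- make_stratified_folds(y, 5, seed = 2)
  expect_true(all(table(fold, y) == 10))
  # features where one constant column would make a majority predictor:
  # balanced accuracy of a constant predictor is exactly 50%
  X <- matrix(rnorm(n * 4), n, 4)
  fm <- new_feature_matrix(X, paste0("f", 1:4), y)
  rep0 <- crossvalidate(y, erp = fm, seed = 3)
  expect_equal(rep0$mean[["balanced_accuracy"]],
               mean(rep0$metrics[, "balanced_accuracy"]), tolerance = 1e-12)
  expect_true(all(rep0$metrics[, "balanced_accuracy"] ==
                    (rep0$metrics[, "sensitivity"] +
                       rep0$metrics[, "specificity"]) / 2))
  # informative features classify; determinism given the seed
  Xi <- X; Xi[, 1] <- Xi[, 1] + ifelse(y == "high", 5, 0)
  fmi <- new_feature_matrix(Xi, paste0("f", 1:4), y)
  r1 <- crossvalidate(y, erp = fmi, seed = 3)
  r2 <- crossvalidate(y, erp = fmi, seed = 3)
  expect_identical(r1$metrics, r2$metrics)
  expect_gt(r1$mean[["balanced_accuracy"]], 0.95)
  expect_error(crossvalidate(y[1:8], erp = NULL), "ERP features")
})

test_that("a constant majority predictor scores exactly 50% balanced accuracy", {
  truth <- c(rep("high", 30), rep("low", 10))
  pred <- rep("high", 40)
  m <- flightload:::classification_metrics(truth, pred, "high")
  expect_equal(m[["balanced_accuracy"]], 0.5)
  expect_equal(m[["sensitivity"]], 1)
  expect_equal(m[["specificity"]], 0)
})
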