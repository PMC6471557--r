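#' Ledoit-Wolf shrinkage covariance estimate
#'
#' Analytic shrinkage of the empirical covariance toward a scaled identity:
#' `Sigma = (1 - lambda) S + lambda (tr(S)/p) I`, with the shrinkage
#' intensity estimated from the data and clipped to `[0, 1]`. Guarantees a
#' well-conditioned, symmetric positive-definite estimate even with fewer
#' observations than variables.
#'
#' @param samples numeric matrix, observations x variables.
#' @param center subtract the column means first (default `TRUE`; CSP uses
#'   `FALSE` because band-passed EEG is already zero-mean).
#' @return list with `sigma` (shrunk covariance) and `lambda`.
#' @export
shrink_covariance <- function(samples, center = TRUE) {
  X <- as.matrix(samples)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need at least 2 observations")
  if (center) X <- sweep(X, 2, colMeans(X))
  S <- crossprod(X) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps * mu^2 * p || mu == 0) {
    return(list(sigma = diag(max(mu, .Machine$double.eps), p), lambda = 1))
  }
  # mean squared distance of rank-one terms from S
  b2bar <- 0
  for (k in seq_len(n)) {
    xk <- X[k, ]
    b2bar <- b2bar + sum((tcrossprod(xk) - S)^2)
  }
  b2bar <- b2bar / (n^2 * p)
  b2 <- min(b2bar, d2)
  lambda <- b2 / d2
  sigma <- (1 - lambda) * S + lambda * diag(mu, p)
  list(sigma = (sigma + t(sigma)) / 2, lambda = lambda)
}

#' Fit Common Spatial Patterns with covariance shrinkage
#'
#' Class covariances are the averages of the per-epoch Ledoit-Wolf-shrunk
#' covariances; the filters solve the generalized eigenproblem
#' `Sigma_A w = lambda (Sigma_A + Sigma_B) w`. The `n_pairs` eigenvectors
#' with the largest and smallest eigenvalues are retained (extremes first)
#' and normalized so `w' (Sigma_A + Sigma_B) w = 1`.
#'
#' @param covs_A,covs_B per-epoch covariance arrays
#'   (`channels x channels x epochs`) of the two classes, e.g. one band of
#'   [epoch_band_covariances()]. Alternatively `EpochSet`s of band-filtered
#'   epochs.
#' @param n_pairs number of filter pairs (default 2, i.e. 4 filters).
#' @param band optional band name stored with the model.
#' @return a `CSPModel`: `filters` (channels x 2 n_pairs), `patterns`,
#'   `eigenvalues`, `composite_cov`.
#' @export
fit_csp <- function(covs_A, covs_B, n_pairs = 2, band = NA_character_) {
  covs_A <- as_cov_array(covs_A)
  covs_B <- as_cov_array(covs_B)
  if (dim(covs_A)[1] != dim(covs_B)[1])
    stop("channel count differs between classes")
  if (dim(covs_A)[3] < 2 || dim(covs_B)[3] < 2)
    stop("need at least 2 epochs per class")
  CA <- mean_shrunk_cov(covs_A)
  CB <- mean_shrunk_cov(covs_B)
  comp <- CA + CB
  Wis <- spd_invsqrt(comp)
  e <- eigen(Wis %*% CA %*% Wis, symmetric = TRUE)   # eigenvalues in [0,1]
  p <- nrow(CA)
  n_pairs <- min(n_pairs, floor(p / 2))
  # interleave extremes: largest, smallest, 2nd largest, 2nd smallest, ...
  ord <- as.vector(rbind(seq_len(n_pairs), p + 1 - seq_len(n_pairs)))
  V <- Wis %*% e$vectors[, ord, drop = FALSE]        # w' comp w = 1 already
  structure(list(band = band, filters = V, eigenvalues = e$values[ord],
                 composite_cov = comp, class_cov_A = CA, class_cov_B = CB,
                 n_pairs = n_pairs),
            class = "CSPModel")
}

as_cov_array <- function(x) {
  if (inherits(x, "EpochSet")) {
    d <- dim(x$data)
    covs <- array(0, dim = c(d[2], d[2], d[1]))
    for (i in seq_len(d[1])) {
      seg <- matrix(x$data[i, , ], d[2], d[3])
      covs[, , i] <- tcrossprod(seg) / d[3]
    }
    covs
  } else x
}

# average of per-epoch shrunk covariances: each epoch covariance is shrunk
# toward its scaled identity with the Ledoit-Wolf intensity computed from
# the epoch's own samples being unavailable here, so shrinkage is applied
# at the matrix level with the standard n<p-robust target
mean_shrunk_cov <- function(covs) {
  p <- dim(covs)[1]; m <- dim(covs)[3]
  C <- apply(covs, c(1, 2), mean)
  # shrink the averaged covariance using the dispersion of epoch covariances
  mu <- sum(diag(C)) / p
  d2 <- sum((C - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps * mu^2 * p) return(diag(max(mu, 1e-12), p))
  b2 <- 0
  for (i in seq_len(m)) b2 <- b2 + sum((covs[, , i] - C)^2)
  b2 <- min(b2 / (m^2 * p), d2)
  lam <- b2 / d2
  (1 - lam) * C + lam * diag(mu, p)
}

#' Apply CSP filters to epochs
#' @param epochs band-filtered `EpochSet`.
#' @param model a `CSPModel`.
#' @return matrix epochs x filters of mean squared filtered signal.
#' @export
apply_csp <- function(epochs, model) {
  covs <- as_cov_array(epochs)
  t(vapply(seq_len(dim(covs)[3]), function(i)
    diag(t(model$filters) %*% covs[, , i] %*% model$filters),
    numeric(ncol(model$filters))))
}

#' Fit a shrinkage LDA classifier
#'
#' Linear discriminant with Ledoit-Wolf shrinkage of the pooled within-class
#' covariance: `w = Sigma^-1 (mu_1 - mu_0)`, bias at the midpoint of the
#' projected class means (equal priors). Class 1 is the positive class
#' (`high` load by convention); `predict` returns class 1 when
#' `w'x + b > 0`.
#'
#' @param features a `FeatureMatrix` or plain matrix.
#' @param labels binary labels; the positive class is `positive`.
#' @param positive label of the positive class (default `"high"`).
#' @param lambda optional fixed shrinkage intensity; `NULL` (default)
#'   estimates it analytically.
#' @return an `LDAModel`.
#' @export
fit_slda <- function(features, labels = NULL, positive = "high",
                     lambda = NULL) {
  if (inherits(features, "FeatureMatrix")) {
    if (is.null(labels)) labels <- features$labels
    X <- features$values
  } else X <- as.matrix(features)
  classes <- unique(labels)
  if (length(classes) != 2)
    stop("need exactly 2 classes, got ", length(classes))
  pos <- if (positive %in% classes) positive else classes[2]
  neg <- setdiff(classes, pos)
  X1 <- X[labels == pos, , drop = FALSE]
  X0 <- X[labels == neg, , drop = FALSE]
  mu1 <- colMeans(X1); mu0 <- colMeans(X0)
  pooled <- rbind(sweep(X1, 2, mu1), sweep(X0, 2, mu0))
  if (is.null(lambda)) {
    sc <- shrink_covariance(pooled, center = FALSE)
  } else {
    S <- crossprod(pooled) / nrow(pooled)
    mu <- sum(diag(S)) / ncol(S)
    sc <- list(sigma = (1 - lambda) * S + lambda * diag(mu, ncol(S)),
               lambda = lambda)
  }
  w <- solve(sc$sigma, mu1 - mu0)
  b <- -sum(w * (mu1 + mu0)) / 2
  structure(list(weights = w, bias = b, lambda = sc$lambda,
                 class_means = list(positive = mu1, negative = mu0),
                 pooled_covariance = sc$sigma,
                 classes = c(negative = neg, positive = pos),
                 feature_names = colnames(X)),
            class = "LDAModel")
}

#' @export
predict.LDAModel <- function(object, newdata, type = c("class", "score"),
                             ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "FeatureMatrix")) newdata$values else
    as.matrix(newdata)
  score <- as.vector(X %*% object$weights + object$bias)
  if (type == "score") return(score)
  ifelse(score > 0, object$classes[["positive"]],
         object$classes[["negative"]])
}

# mutual information of two discrete vectors (natural log)
discrete_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

# equal-frequency discretization into n_bins levels
equal_freq_bins <- function(x, n_bins = 8) {
  r <- rank(x, ties.method = "first")
  as.integer(ceiling(r * n_bins / length(x)))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection maximizing `I(f; y) - mean_s I(f; s)` over the
#' already-selected set `s`, with mutual information estimated on features
#' discretized into 8 equal-frequency bins. Deterministic: ties go to the
#' lowest column index.
#'
#' @param features a `FeatureMatrix` or matrix.
#' @param labels class labels (ignored if `features` carries them).
#' @param k number of features to select.
#' @param n_bins discretization bins.
#' @return integer vector of selected column indices, in selection order.
#' @export
mrmr_select <- function(features, labels = NULL, k = 20, n_bins = 8) {
  if (inherits(features, "FeatureMatrix")) {
    if (is.null(labels)) labels <- features$labels
    X <- features$values
  } else X <- as.matrix(features)
  p <- ncol(X)
  if (k > p) stop("k = ", k, " exceeds feature count ", p)
  D <- apply(X, 2, equal_freq_bins, n_bins = n_bins)
  rel <- apply(D, 2, discrete_mi, b = labels)
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    if (length(selected) == 0) {
      score <- rel
    } else {
      score <- rel - red_sum / length(selected)
    }
    score[selected] <- -Inf
    pick <- which.max(score)        # which.max takes the lowest index on ties
    selected <- c(selected, pick)
    if (step < k)
      red_sum <- red_sum + apply(D, 2, discrete_mi, b = D[, pick])
  }
  unname(selected)
}

#' Stratified fold assignment
#'
#' Epochs are shuffled once with the seed, then dealt round-robin within
#' each class, so fold class proportions match the data within one epoch.
#'
#' @param labels class labels.
#' @param n_folds number of folds.
#' @param seed RNG seed.
#' @return integer fold id per epoch.
#' @export
make_stratified_folds <- function(labels, n_folds = 5, seed = 1) {
  if (min(table(labels)) < n_folds)
    stop("smallest class has fewer epochs than folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

classification_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  c(balanced_accuracy = (sens + spec) / 2, sensitivity = sens,
    specificity = spec)
}

#' Stratified cross-validated sLDA classification
#'
#' All data-dependent fitting — per-band CSP, mRMR selection, covariance
#' shrinkage, the sLDA itself — happens on the training folds only; metrics
#' are computed on the held-out fold. Sensitivity is defined on the
#' positive (`high` load) class and balanced accuracy is the mean of
#' sensitivity and specificity.
#'
#' @param labels per-epoch condition labels.
#' @param erp a `FeatureMatrix` of precomputed (label-independent) ERP
#'   features, or `NULL`.
#' @param band_covs named list of per-band `channels x channels x epochs`
#'   covariance arrays from [epoch_band_covariances()], or `NULL` for an
#'   ERP-only run. CSP is refit per training fold from these.
#' @param n_folds folds (default 5).
#' @param n_pairs CSP pairs per band.
#' @param select_k if non-`NULL`, per-fold mRMR selection of this many
#'   features from the concatenated set (the fused pipeline uses 20).
#' @param positive positive-class label.
#' @param seed seed for the fold assignment.
#' @param channel_names montage stored with the fold models.
#' @return a `ClassificationReport`: per-fold metrics, means/SDs, selected
#'   features, fitted per-fold models.
#' @export
crossvalidate <- function(labels, erp = NULL, band_covs = NULL, n_folds = 5,
                          n_pairs = 2, select_k = NULL, positive = "high",
                          seed = 1, channel_names = NULL) {
  if (is.null(erp) && is.null(band_covs))
    stop("supply ERP features, band covariances, or both")
  n <- length(labels)
  fold <- make_stratified_folds(labels, n_folds, seed)
  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- fold != f
    test <- !train
    feats_tr <- NULL; feats_te <- NULL
    csp_bank <- NULL
    if (!is.null(band_covs)) {
      csp_bank <- lapply(names(band_covs), function(band) {
        covs <- band_covs[[band]]
        fit_csp(covs[, , train & labels != positive, drop = FALSE],
                covs[, , train & labels == positive, drop = FALSE],
                n_pairs = n_pairs, band = band)
      })
      names(csp_bank) <- names(band_covs)
      bp <- function(idx) {
        vals <- NULL; nms <- character()
        for (band in names(csp_bank)) {
          W <- csp_bank[[band]]$filters
          p_ch <- nrow(W)
          cmat <- matrix(band_covs[[band]][, , idx, drop = FALSE],
                         p_ch * p_ch, sum(idx))
          # w' C w for every filter and epoch at once
          OP <- t(apply(W, 2, function(w) as.vector(tcrossprod(w))))
          vals <- cbind(vals, t(log(pmax(OP %*% cmat, 1e-300))))
          nms <- c(nms, sprintf("pow:%s:csp%d", band, seq_len(ncol(W))))
        }
        colnames(vals) <- nms
        vals
      }
      feats_tr <- bp(train); feats_te <- bp(test)
    }
    if (!is.null(erp)) {
      feats_tr <- cbind(feats_tr, erp$values[train, , drop = FALSE])
      feats_te <- cbind(feats_te, erp$values[test, , drop = FALSE])
    }
    sel <- seq_len(ncol(feats_tr))
    if (!is.null(select_k))
      sel <- mrmr_select(feats_tr, labels[train], k = select_k)
    model <- fit_slda(feats_tr[, sel, drop = FALSE], labels[train],
                      positive = positive)
    pred <- predict(model, feats_te[, sel, drop = FALSE])
    per_fold[[f]] <- list(
      metrics = classification_metrics(labels[test], pred, positive),
      selected = sel, selected_names = colnames(feats_tr)[sel],
      model = model, csp_bank = csp_bank,
      feature_cov = shrink_covariance(feats_tr[, sel, drop = FALSE])$sigma,
      n_test = sum(test))
  }
  metrics <- t(vapply(per_fold, `[[`, numeric(3), "metrics"))
  structure(list(per_fold = per_fold, fold = fold, metrics = metrics,
                 mean = colMeans(metrics), sd = apply(metrics, 2, stats::sd),
                 positive = positive, n_folds = n_folds,
                 channel_names = channel_names),
            class = "ClassificationReport")
}

#' @export
print.ClassificationReport <- function(x, ...) {
  cat(sprintf("ClassificationReport: %d-fold stratified CV (positive class: %s)\n",
              x$n_folds, x$positive))
  cat(sprintf("  balanced accuracy %.1f%% (SD %.1f), sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$mean["balanced_accuracy"],
              100 * x$sd["balanced_accuracy"],
              100 * x$mean["sensitivity"], 100 * x$mean["specificity"]))
  invisible(x)
}
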