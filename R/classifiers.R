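# The three supervised algorithms behind one fit/predict surface:
# Gaussian naive Bayes, pooled-covariance linear discriminant analysis
# (classic Fisher/Bayes form), and a soft-margin SVM trained by SMO with
# the Pearson VII universal (PUK) kernel (see svm-smo.R). Multiclass SVM
# is one-vs-one with pairwise voting.

#' PUK kernel parameters
#'
#' @param omega Pearson-VII shape parameter (default 1: Lorentzian tail).
#' @param sigma Kernel width (default 1).
#' @param c_regularization Soft-margin penalty C (default 10).
#' @return An object of class `puk_params`.
#' @export
puk_params <- function(omega = 1, sigma = 1, c_regularization = 10) {
  if (omega <= 0 || sigma <= 0 || c_regularization <= 0) {
    stop_stroopfc("omega, sigma and C must be strictly positive")
  }
  structure(list(omega = omega, sigma = sigma,
                 c_regularization = c_regularization),
            class = "puk_params")
}

#' Pearson VII universal kernel
#'
#' `K(x, y) = 1 / (1 + (2 * ||x - y|| * sqrt(2^(1/omega) - 1) / sigma)^2)^omega`.
#' A heavy-tailed radial kernel; `K(x, x) = 1` and `K` decays towards 0
#' with distance, with tail weight controlled by `omega`.
#'
#' @param x,y Numeric vectors of equal dimension.
#' @param omega,sigma Kernel shape and width.
#' @return Kernel value in `(0, 1]`.
#' @export
puk_kernel <- function(x, y, omega = 1, sigma = 1) {
  if (length(x) != length(y)) {
    stop_stroopfc("dimension mismatch: ", length(x), " vs ", length(y))
  }
  d <- sqrt(sum((x - y)^2))
  1 / (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^omega
}

# Vectorised PUK Gram matrix between the rows of X and Y; identical to
# puk_kernel applied pairwise but computed from squared distances in one
# set of matrix operations.
puk_gram <- function(X, Y, omega = 1, sigma = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) +
    outer(rep(1, nrow(X)), rowSums(Y^2)) - 2 * X %*% t(Y)
  d2[d2 < 0] <- 0
  (1 + (4 * (2^(1 / omega) - 1) / sigma^2) * d2)^(-omega)
}

#' Fit a feature standardization transform on training rows
#'
#' z-scoring with means and standard deviations estimated on the training
#' rows only, so held-out rows never leak into the transform.
#' Zero-variance features are centred but not divided (scale 1, with a
#' warning).
#'
#' @param train Numeric matrix of training rows.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(train) {
  train <- as.matrix(train)
  center <- colMeans(train)
  scale <- apply(train, 2, stats::sd)
  if (any(scale == 0 | is.na(scale))) {
    warning("zero-variance feature(s): centred but not scaled")
    scale[scale == 0 | is.na(scale)] <- 1
  }
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' Apply a fitted standardization transform
#' @param scaler A [fit_scaler()] result.
#' @param rows Numeric matrix to transform.
#' @return Transformed matrix `(x - center) / scale`.
#' @export
apply_scaler <- function(scaler, rows) {
  rows <- as.matrix(rows)
  sweep(sweep(rows, 2, scaler$center, `-`), 2, scaler$scale, `/`)
}

# --- linear discriminant analysis ---------------------------------------
# Classic pooled-covariance (Fisher/Bayes) form with a small ridge so that
# degenerate training folds (e.g. one subject per class) still fit; the
# ridge case is warned about. Cross-checked against MASS::lda in tests.

lda_fit <- function(x, y, ridge = 1e-8) {
  lv <- levels(y)
  p <- ncol(x)
  means <- t(vapply(lv, function(cl) colMeans(x[y == cl, , drop = FALSE]),
                    numeric(p)))
  n <- nrow(x)
  sw <- matrix(0, p, p)
  for (cl in lv) {
    xs <- x[y == cl, , drop = FALSE]
    if (nrow(xs) > 1) {
      centred <- sweep(xs, 2, means[cl, ])
      sw <- sw + crossprod(centred)
    }
  }
  denom <- max(n - length(lv), 1L)
  sw <- sw / denom
  scale0 <- mean(diag(sw))
  if (scale0 <= 0) {
    warning("no within-class variance; pooled covariance replaced by ridge")
    scale0 <- 1
  }
  sw <- sw + ridge * scale0 * diag(p)
  inv <- tryCatch(solve(sw), error = function(e) {
    warning("singular pooled covariance; ridge increased")
    solve(sw + 1e-4 * scale0 * diag(p))
  })
  list(levels = lv, means = means, inv_cov = inv,
       prior = table(y)[lv] / n)
}

lda_predict <- function(fit, x) {
  disc <- vapply(fit$levels, function(cl) {
    mu <- fit$means[cl, ]
    drop(x %*% (fit$inv_cov %*% mu)) - 0.5 * sum(mu * (fit$inv_cov %*% mu)) +
      log(as.numeric(fit$prior[cl]))
  }, numeric(nrow(x)))
  if (!is.matrix(disc)) disc <- matrix(disc, nrow = nrow(x))
  factor(fit$levels[max.col(disc, ties.method = "first")], levels = fit$levels)
}

# --- Gaussian naive Bayes ------------------------------------------------
# Authored rather than wrapped: the variance floor and tie-break need to
# be explicit, and the fit is a handful of per-class moments.

gnb_fit <- function(x, y, var_floor_rel = 1e-9) {
  lv <- levels(y)
  rng <- apply(x, 2, function(col) diff(range(col)))
  floor_ <- var_floor_rel * pmax(rng, .Machine$double.eps)^2
  stats_by_class <- lapply(lv, function(cl) {
    xs <- x[y == cl, , drop = FALSE]
    v <- if (nrow(xs) > 1) apply(xs, 2, stats::var) else rep(0, ncol(xs))
    list(n = nrow(xs), mean = colMeans(xs), var = pmax(v, floor_))
  })
  names(stats_by_class) <- lv
  list(levels = lv, prior = table(y)[lv] / length(y), stats = stats_by_class)
}

gnb_log_posterior <- function(fit, x) {
  lp <- matrix(NA_real_, nrow(x), length(fit$levels),
               dimnames = list(NULL, fit$levels))
  for (cl in fit$levels) {
    s <- fit$stats[[cl]]
    ll <- log(as.numeric(fit$prior[cl]))
    for (j in seq_len(ncol(x))) {
      ll <- ll + stats::dnorm(x[, j], s$mean[j], sqrt(s$var[j]), log = TRUE)
    }
    lp[, cl] <- ll
  }
  lp
}

gnb_predict <- function(fit, x, type = c("class", "posterior")) {
  type <- match.arg(type)
  lp <- gnb_log_posterior(fit, x)
  if (type == "class") {
    factor(fit$levels[max.col(lp, ties.method = "first")], levels = fit$levels)
  } else {
    post <- exp(lp - apply(lp, 1, max))
    post / rowSums(post)
  }
}

#' Train a classifier
#'
#' @param x Numeric feature matrix (rows = subjects).
#' @param y Class labels (factor or character).
#' @param algorithm `"nb"` (Gaussian naive Bayes), `"lda"` (linear
#'   discriminant analysis with pooled covariance), or `"svm"`
#'   (one-vs-one soft-margin SVM with the PUK kernel, trained by SMO).
#' @param params [puk_params()] used by the SVM.
#' @param standardize z-score features using training statistics
#'   (default `TRUE`; the three features live on very different scales).
#' @param svm_tolerance SMO convergence tolerance (default 1e-8, tight
#'   enough that refits are deterministic to test precision).
#' @return An object of class `stroopfc_model`.
#' @export
fit_classifier <- function(x, y, algorithm = c("nb", "lda", "svm"),
                           params = puk_params(), standardize = TRUE,
                           svm_tolerance = 1e-8) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop_stroopfc("need at least 2 classes to fit")
  scaler <- NULL
  if (standardize) {
    scaler <- fit_scaler(x)
    x <- apply_scaler(scaler, x)
  }
  fit <- switch(algorithm,
    nb = gnb_fit(x, y),
    lda = lda_fit(x, y),
    svm = svm_fit(x, y, params, tol = svm_tolerance)
  )
  structure(
    list(algorithm = algorithm, fit = fit, levels = levels(y),
         scaler = scaler, params = params, n_features = ncol(x)),
    class = "stroopfc_model"
  )
}

#' Predict class labels
#'
#' @param object A fitted [fit_classifier()] model.
#' @param newdata Numeric feature matrix with the training dimensionality.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row; deterministic.
#' @export
predict.stroopfc_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$n_features) {
    stop_stroopfc("feature dimensionality mismatch: model expects ",
                  object$n_features, ", got ", ncol(x))
  }
  if (!is.null(object$scaler)) x <- apply_scaler(object$scaler, x)
  pred <- switch(object$algorithm,
    nb = gnb_predict(object$fit, x),
    lda = lda_predict(object$fit, x),
    svm = svm_predict(object$fit, x)
  )
  factor(as.character(pred), levels = object$levels)
}
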