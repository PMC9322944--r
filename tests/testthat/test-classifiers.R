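test_that("PUK kernel matches its closed form and is a valid kernel", {
  x <- c(1, 2, 3)
  expect_equal(puk_kernel(x, x), 1)
  # omega = sigma = 1, distance 0.5: K = 1 / (1 + 4 * 0.25) = 0.5
  expect_equal(puk_kernel(c(0, 0), c(0.3, 0.4)), 0.5)
  expect_error(puk_kernel(1:2, 1:3), "dimension mismatch")

  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4)
    om <- runif(1, 0.5, 3); sg <- runif(1, 0.5, 3)
    expect_equal(puk_kernel(a, b, om, sg), puk_kernel(b, a, om, sg))
  }

  pts <- matrix(rnorm(30 * 3), 30)
  gram <- stroopfc:::puk_gram(pts, pts)
  # vectorised Gram equals the scalar kernel pairwise
  for (i in c(1, 7, 30)) for (j in c(2, 15)) {
    expect_equal(gram[i, j], puk_kernel(pts[i, ], pts[j, ]), tolerance = 1e-12)
  }
  expect_gt(min(eigen(gram, symmetric = TRUE)$values), -1e-10)
})

test_that("all three algorithms separate well-separated blobs perfectly", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, mean = 0, sd = 0.3), 20, 2),
             matrix(rnorm(40, mean = 4, sd = 0.3), 20, 2))
  y <- factor(rep(c("HC", "SCZ"), each = 20))
  for (alg in c("nb", "lda", "svm")) {
    m <- fit_classifier(x, y, alg)
    expect_identical(as.character(predict(m, x)), as.character(y))
  }
})

test_that("naive Bayes posterior is half at the symmetry midpoint and matches e1071", {
  set.seed(8)
  pts <- matrix(rnorm(60, mean = 2, sd = 0.7), 30, 2)
  x <- rbind(pts, -pts)
  y <- factor(rep(c("a", "b"), each = 30))
  fit <- stroopfc:::gnb_fit(x, y)
  post <- stroopfc:::gnb_predict(fit, matrix(0, 1, 2), type = "posterior")
  expect_equal(unname(post[1, 1]), 0.5, tolerance = 1e-9)

  xt <- matrix(rnorm(40), 20, 2)
  ours <- stroopfc:::gnb_predict(fit, xt)
  ref <- e1071::naiveBayes(x, y)
  theirs <- predict(ref, xt)
  expect_identical(as.character(ours), as.character(theirs))
})

test_that("SMO dual solutions match an interior-point QP oracle", {
  set.seed(91)
  for (rep in 1:5) {
    n <- 8
    x <- matrix(rnorm(n * 2), n, 2)
    y <- rep(c(-1, 1), each = n / 2)
    x[y == 1, ] <- x[y == 1, ] + 1.2       # overlapping classes
    C <- 10
    K <- stroopfc:::puk_gram(x, x)
    fit <- stroopfc:::smo_binary(K, y, C = C, tol = 1e-10)
    qp <- kernlab::ipop(c = rep(-1, n), H = (y %o% y) * K,
                        A = matrix(y, 1), b = 0, l = rep(0, n),
                        u = rep(C, n), r = 0, sigf = 12, maxiter = 400)
    expect_equal(fit$alpha, kernlab::primal(qp), tolerance = 1e-6,
                 ignore_attr = TRUE)
    # equality constraint and box respected
    expect_lt(abs(sum(fit$alpha * y)), 1e-10)
    expect_true(all(fit$alpha >= 0 & fit$alpha <= C))
  }
  # the documented 4-point fixture
  x4 <- matrix(c(-2, -0.8, 0.9, 2.1, 0.3, -0.4, 0.2, -0.1), 4, 2)
  y4 <- c(-1, -1, 1, 1)
  K4 <- stroopfc:::puk_gram(x4, x4)
  fit4 <- stroopfc:::smo_binary(K4, y4, C = 10, tol = 1e-10)
  qp4 <- kernlab::ipop(c = rep(-1, 4), H = (y4 %o% y4) * K4,
                       A = matrix(y4, 1), b = 0, l = rep(0, 4),
                       u = rep(10, 4), r = 0, sigf = 12, maxiter = 200)
  expect_equal(fit4$alpha, kernlab::primal(qp4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("standardization uses training statistics only", {
  set.seed(3)
  train <- matrix(rnorm(40, mean = 5, sd = 3), 20, 2)
  sc <- fit_scaler(train)
  z <- apply_scaler(sc, train)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(1, 1), tolerance = 1e-12)

  held <- matrix(c(1, 2), 1, 2)
  manual <- (held - colMeans(train)) / apply(train, 2, sd)
  expect_equal(apply_scaler(sc, held), manual, ignore_attr = TRUE)

  const <- cbind(rnorm(10), rep(7, 10))
  expect_warning(sc2 <- fit_scaler(const), "zero-variance")
  expect_equal(apply_scaler(sc2, const)[, 2], rep(0, 10))
})

test_that("predictions are deterministic, row-wise, and order invariant", {
  f <- small_features()
  x <- as.matrix(f[, c("ge_cm", "ge_dm", "cq")])
  y <- f$label
  for (alg in c("nb", "lda", "svm")) {
    m1 <- fit_classifier(x, y, alg)
    m2 <- fit_classifier(x, y, alg)
    p1 <- predict(m1, x)
    expect_identical(p1, predict(m2, x))
    perm <- rev(seq_len(nrow(x)))
    expect_identical(predict(m1, x[perm, ]), p1[perm])
    dup <- predict(m1, x[c(1, 1), ])
    expect_identical(dup[1], dup[2])
    expect_error(predict(m1, x[, 1:2]), "dimensionality mismatch")
  }
})

test_that("pooled-covariance LDA agrees with the classic reference implementation", {
  set.seed(12)
  x <- matrix(rnorm(240), 80, 3)
  x[21:40, 1] <- x[21:40, 1] + 2
  x[41:60, 2] <- x[41:60, 2] + 2
  x[61:80, 3] <- x[61:80, 3] + 2
  y <- factor(rep(CLASS_LEVELS, each = 20))
  ours <- fit_classifier(x, y, "lda", standardize = FALSE)
  ref <- MASS::lda(x, grouping = y)
  xt <- matrix(rnorm(60), 20, 3)
  expect_identical(as.character(predict(ours, xt)),
                   as.character(predict(ref, xt)$class))
})

test_that("LDA survives singleton classes via the ridge fallback", {
  x <- matrix(c(0, 0, 1, 1, 5, 5.2, 9, 9.1), 4, 2)
  y <- factor(c("HC", "HC", "MIG", "OCD"), levels = CLASS_LEVELS)
  m <- fit_classifier(x, y, "lda", standardize = FALSE)
  expect_identical(as.character(predict(m, x[3, , drop = FALSE])), "MIG")
})

test_that("LDA predictions are invariant under per-feature affine maps", {
  f <- small_features()
  x <- as.matrix(f[, c("ge_cm", "ge_dm", "cq")])
  y <- f$label
  m <- fit_classifier(x, y, "lda")
  x2 <- sweep(sweep(x, 2, c(10, 0.2, 3), `*`), 2, c(-1, 5, 100), `+`)
  m2 <- fit_classifier(x2, y, "lda")
  expect_identical(predict(m, x), predict(m2, x2))
})
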