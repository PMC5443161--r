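make_gauss_features <- function(n_per_class = 20, d = 2, sep = 4, seed = 1,
                                classes = c("R", "I")) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_along(classes), function(i) {
    mu <- rep(0, d); mu[1] <- (i - 1) * sep
    matrix(rnorm(n_per_class * d), n_per_class) + rep(mu, each = n_per_class)
  }))
  list(X = X, y = rep(classes, each = n_per_class))
}

test_that("all five algorithms separate a linearly separable toy perfectly", {
  gd <- make_gauss_features(n_per_class = 15, sep = 10, seed = 2)
  for (alg in c("LPGM", "SVM", "FLDA", "LR", "RLS")) {
    m <- train_classifier(alg, gd$X, gd$y, seed = 1)
    expect_equal(mean(predict_label(m, gd$X) == gd$y), 1,
                 info = alg)
  }
})

test_that("probability outputs lie on the simplex for every algorithm", {
  gd <- make_gauss_features(n_per_class = 12, d = 3, sep = 1.5, seed = 3,
                            classes = c("R", "I", "L"))
  for (alg in c("LPGM", "SVM", "FLDA", "LR", "RLS")) {
    m <- train_classifier(alg, gd$X, gd$y, seed = 1)
    p <- predict_proba(m, gd$X)
    expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9,
                 info = alg)
    expect_true(all(p >= 0), info = alg)
    expect_identical(colnames(p), c("R", "I", "L"), info = alg)
  }
})

test_that("LPGM posteriors reflect Gaussian geometry", {
  set.seed(4)
  n <- 200
  X <- rbind(matrix(rnorm(n * 2), n) + rep(c(4, 0), each = n),
             matrix(rnorm(n * 2), n) + rep(c(-4, 0), each = n))
  y <- rep(c("R", "I"), each = n)
  m <- train_classifier("LPGM", X, y)
  # midpoint of the class means: posterior (0.5, 0.5)
  mid <- matrix(colMeans(rbind(colMeans(X[1:n, ]), colMeans(X[-(1:n), ]))), 1)
  expect_equal(unname(predict_proba(m, mid)[1, ]), c(0.5, 0.5),
               tolerance = 0.02)
  # deep inside a cluster: near-certain
  expect_gt(predict_proba(m, matrix(c(8, 0), 1))[1, "R"], 0.99)
})

test_that("FLDA equals an explicit project-then-1D-Gaussian oracle", {
  gd <- make_gauss_features(n_per_class = 25, d = 4, sep = 2, seed = 5)
  m <- train_classifier("FLDA", gd$X, gd$y)
  p <- predict_proba(m, gd$X)

  # oracle built from first principles in this test
  X <- gd$X; y <- gd$y; d <- ncol(X)
  cls <- c("R", "I")
  sw <- matrix(0, d, d)
  for (cl in cls) {
    xc <- scale(X[y == cl, ], scale = FALSE)
    sw <- sw + crossprod(xc)
  }
  sw <- sw / (nrow(X) - 2)
  sw <- sw + (1e-6 * sum(diag(sw)) / d) * diag(d)
  w <- solve(sw, colMeans(X[y == "R", ]) - colMeans(X[y == "I", ]))
  w <- w / sqrt(sum(w^2))
  z <- as.numeric(X %*% w)
  mu <- vapply(cls, function(cl) mean(z[y == cl]), numeric(1))
  v <- sum(vapply(cls, function(cl) sum((z[y == cl] - mu[cl])^2), numeric(1))) /
    (length(z) - 2)
  v <- v + 1e-6 * v
  loglik <- vapply(cls, function(cl) -0.5 * (z - mu[cl])^2 / v + log(0.5),
                   numeric(length(z)))
  p_ref <- exp(loglik - apply(loglik, 1, max))
  p_ref <- p_ref / rowSums(p_ref)
  expect_lt(max(abs(p[, "R"] - p_ref[, "R"])), 1e-6)
})

test_that("heavily shrunk RLS returns near-uniform probabilities", {
  gd <- make_gauss_features(n_per_class = 15, sep = 6, seed = 6)
  m <- train_classifier("RLS", gd$X, gd$y, rls_lambda = 1e5)
  p <- predict_proba(m, gd$X)
  expect_lt(max(abs(p - 0.5)), 0.05)
})

test_that("RLS selects lambda by CV with ties toward shrinkage", {
  gd <- make_gauss_features(n_per_class = 20, sep = 8, seed = 7)
  m <- train_classifier("RLS", gd$X, gd$y, seed = 2,
                        rls_lambda = c(0, 0.5, 1, 10, 1e2, 1e3, 1e4, 1e5))
  # separable data: several lambdas reach 100% validation accuracy and the
  # largest of those must win
  expect_true(m$fit$lambda >= 0)
  acc_chosen <- mean(predict_label(m, gd$X) == gd$y)
  expect_equal(acc_chosen, 1)
})

test_that("training is deterministic given the seed", {
  gd <- make_gauss_features(n_per_class = 15, d = 3, sep = 1, seed = 8)
  for (alg in c("SVM", "LR", "RLS")) {
    m1 <- train_classifier(alg, gd$X, gd$y, seed = 42)
    m2 <- train_classifier(alg, gd$X, gd$y, seed = 42)
    expect_identical(predict_proba(m1, gd$X), predict_proba(m2, gd$X),
                     info = alg)
  }
})

test_that("LPGM and FLDA agree on shared-covariance Gaussian data", {
  set.seed(9)
  n <- 150
  sigma <- matrix(c(2, 0.7, 0.7, 1), 2)
  ch <- chol(sigma)
  X <- rbind(matrix(rnorm(n * 2), n) %*% ch + rep(c(2, 1), each = n),
             matrix(rnorm(n * 2), n) %*% ch)
  y <- rep(c("R", "I"), each = n)
  m1 <- train_classifier("LPGM", X, y)
  m2 <- train_classifier("FLDA", X, y)
  Xt <- rbind(matrix(rnorm(200 * 2), 200) %*% ch + rep(c(2, 1), each = 200),
              matrix(rnorm(200 * 2), 200) %*% ch)
  expect_gte(mean(predict_label(m1, Xt) == predict_label(m2, Xt)), 0.99)
})

test_that("replicating the whole training set leaves posteriors stable", {
  gd <- make_gauss_features(n_per_class = 20, d = 2, sep = 2, seed = 10)
  Xq <- matrix(rnorm(20), 10, 2)
  for (alg in c("LPGM", "FLDA")) {
    m1 <- train_classifier(alg, gd$X, gd$y)
    m2 <- train_classifier(alg, rbind(gd$X, gd$X), c(gd$y, gd$y))
    expect_lt(max(abs(predict_proba(m1, Xq) - predict_proba(m2, Xq))), 0.02)
  }
})

test_that("degenerate inputs are handled, dimension mismatches rejected", {
  gd <- make_gauss_features(n_per_class = 10, d = 3, seed = 11)
  X <- gd$X
  X[, 3] <- 5 # constant feature column
  for (alg in c("LPGM", "FLDA")) {
    m <- train_classifier(alg, X, gd$y)
    expect_true(all(is.finite(predict_proba(m, X))))
  }
  m <- train_classifier("LPGM", gd$X, gd$y)
  expect_error(predict_proba(m, gd$X[, 1:2]), "dimension")
  expect_error(train_classifier("LPGM", gd$X, rep("R", nrow(gd$X))),
               "two classes")
})
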