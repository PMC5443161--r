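test_that("scatter matrices vanish in the designed degenerate cases", {
  nc <- 3; nt <- 8
  base <- matrix(rnorm(nc * nt), nc, nt)
  # two classes, epochs symmetric around the SAME mean -> S_b = 0
  d1 <- matrix(rnorm(nc * nt), nc, nt)
  d2 <- matrix(rnorm(nc * nt), nc, nt)
  data <- array(c(base + d1, base - d1, base + d2, base - d2),
                c(nc, nt, 4))
  es <- epoch_set(data, c("L", "L", "R", "R"), paste0("c", 1:nc), 100)
  sc <- compute_scatter(es)
  expect_equal(max(abs(sc$scatter$S_b)), 0, tolerance = 1e-12)
  expect_gt(max(abs(sc$scatter$S_w)), 0)
  # every epoch equals its class mean -> S_w = 0
  m1 <- matrix(1, nc, nt); m2 <- matrix(-1, nc, nt)
  es2 <- epoch_set(array(c(m1, m1, m2, m2), c(nc, nt, 4)),
                   c("L", "L", "R", "R"), paste0("c", 1:nc), 100)
  sc2 <- compute_scatter(es2)
  expect_equal(max(abs(sc2$scatter$S_w)), 0, tolerance = 1e-12)
  expect_error(compute_scatter(subset_epochs(es, 1:2)), "2 classes")
})

test_that("scatter matches a brute-force double-loop oracle", {
  set.seed(8)
  nc <- 4; nt <- 10
  labels <- rep(c("R", "I", "L"), times = c(3, 4, 5))
  k <- length(labels)
  data <- array(rnorm(nc * nt * k), c(nc, nt, k))
  es <- epoch_set(data, labels, paste0("c", 1:nc), 100)
  sc <- compute_scatter(es)

  # independent oracle: literal loops over the defining sums
  cls <- c("R", "I", "L")
  means <- lapply(cls, function(cl) {
    idx <- which(labels == cl)
    acc <- matrix(0, nc, nt)
    for (i in idx) acc <- acc + data[, , i]
    acc / length(idx)
  })
  names(means) <- cls
  grand <- matrix(0, nc, nt)
  for (i in seq_len(k)) grand <- grand + data[, , i]
  grand <- grand / k
  s_b <- matrix(0, nc, nc)
  for (cl in cls) {
    p <- sum(labels == cl) / k
    d <- means[[cl]] - grand
    s_b <- s_b + p * d %*% t(d)
  }
  s_w <- matrix(0, nc, nc)
  for (cl in cls) {
    for (i in which(labels == cl)) {
      d <- data[, , i] - means[[cl]]
      s_w <- s_w + d %*% t(d)
    }
  }
  expect_equal(unname(sc$scatter$S_b), s_b, tolerance = 1e-10)
  expect_equal(unname(sc$scatter$S_w), s_w, tolerance = 1e-10)
  expect_equal(sc$stats$grand_mean, grand, tolerance = 1e-12)
  expect_equal(sum(sc$stats$class_priors), 1)
})

test_that("beamformer solves the axis-aligned discriminant exactly", {
  s_w <- diag(2)
  s_b <- matrix(c(4, 0, 0, 0), 2, 2) # class mean difference along channel 1
  m <- fit_beamformer(list(S_b = s_b, S_w = s_w), gamma = 0)
  expect_equal(m$W, c(1, 0), tolerance = 1e-12)
  expect_equal(sqrt(sum(m$W^2)), 1)
})

test_that("beamformer matches a dense generalized-eigendecomposition oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    sp <- random_scatter_pair(n)
    m <- fit_beamformer(sp, gamma = 0)
    # independent oracle: eigenvectors of solve(S_w) %*% S_b
    eg <- eigen(solve(sp$S_w) %*% sp$S_b)
    w_ref <- Re(eg$vectors[, which.max(Re(eg$values))])
    expect_gt(abs(cosine(m$W, w_ref)), 1 - 1e-8)
    expect_equal(max(m$eigenvalues), m$eigenvalues[1])
  }
})

test_that("large regularization converges to the leading eigenvector of S_b", {
  set.seed(5)
  sp <- random_scatter_pair(5)
  gamma <- 1e6 * norm(sp$S_w, "2")
  m <- fit_beamformer(sp, gamma)
  wb <- eigen(sp$S_b, symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(cosine(m$W, wb)), 0.999)
})

test_that("applying the beamformer is exact matrix projection", {
  m <- structure(list(W = c(1, 0, 0), gamma = 0, eigenvalues = 1),
                 class = "beamformer_model")
  x <- matrix(rnorm(3 * 7), 3, 7)
  expect_equal(apply_beamformer(x, m), x[1, ])
  expect_equal(apply_beamformer(matrix(0, 3, 5), m), rep(0, 5))
  expect_error(apply_beamformer(matrix(0, 4, 5), m), "channels")
  # rank-1 epoch with planted source: output proportional to the source
  s <- sin(seq(0, 3, length.out = 40))
  w <- c(0.2, -0.5, 0.8)
  x1 <- w %*% t(s)
  m2 <- structure(list(W = w / sqrt(sum(w^2)), gamma = 0, eigenvalues = 1),
                  class = "beamformer_model")
  expect_equal(abs(cor(apply_beamformer(x1, m2), s)), 1, tolerance = 1e-12)
})

test_that("beamformer is permutation-equivariant and scale-invariant", {
  set.seed(13)
  es <- make_toy_epochs(k_per_class = 6, nc = 5, nt = 12, classes = c("R", "I"))
  sc <- compute_scatter(es)$scatter
  m <- fit_beamformer(sc, gamma = 1)
  # permute channels
  perm <- c(3, 1, 5, 2, 4)
  es_p <- es
  es_p$data <- es$data[perm, , , drop = FALSE]
  sc_p <- compute_scatter(es_p)$scatter
  m_p <- fit_beamformer(sc_p, gamma = 1)
  expect_equal(abs(m_p$W), abs(m$W[perm]), tolerance = 1e-8)
  expect_equal(abs(cosine(apply_beamformer(es$data[, , 1], m),
                          apply_beamformer(es_p$data[, , 1], m_p))),
               1, tolerance = 1e-8)
  # scaling all data by c > 0 leaves the filter unchanged (gamma scaled too)
  es_s <- es
  es_s$data <- es$data * 3
  sc_s <- compute_scatter(es_s)$scatter
  m_s <- fit_beamformer(sc_s, gamma = 9)
  expect_equal(m_s$W, m$W, tolerance = 1e-8)
})

test_that("the returned filter maximizes the Fisher quotient (Monte Carlo)", {
  set.seed(99)
  sp <- random_scatter_pair(6)
  m <- fit_beamformer(sp, gamma = 0)
  j_star <- rpbci:::fisher_quotient(m$W, sp)
  vs <- matrix(rnorm(6 * 1000), 6)
  j_rand <- apply(vs, 2, function(v) rpbci:::fisher_quotient(v / sqrt(sum(v^2)), sp))
  expect_true(all(j_star >= j_rand - 1e-10))
})

test_that("beamformer recovers a planted spatial pattern at high SNR", {
  set.seed(17)
  nc <- 6; nt <- 30; kpc <- 40
  a <- c(1, 0.8, 0.3, 0, 0, 0); a <- a / sqrt(sum(a^2))
  labels <- rep(c("R", "I"), each = kpc)
  data <- array(rnorm(nc * nt * 2 * kpc, sd = 0.05), c(nc, nt, 2 * kpc))
  for (i in seq_len(kpc)) {
    s <- -seq(0, 1, length.out = nt) * (1 + 0.1 * rnorm(1))
    data[, , i] <- data[, , i] + a %*% t(s) # class R carries the source
  }
  es <- epoch_set(data, labels, paste0("c", 1:nc), 100)
  sc <- compute_scatter(es)$scatter
  m <- fit_beamformer(sc, gamma = 1e-6)
  # filter aligns with the within-class-whitened pattern
  target <- solve(sc$S_w + 1e-6 * diag(nc), a)
  expect_gt(abs(cosine(m$W, target)), 0.9)
})
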