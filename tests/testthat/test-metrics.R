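test_that("pairwise separation is the mean Euclidean distance over samples", {
  A <- matrix(rnorm(40), 4, 10)
  expect_equal(pairwise_separation(A, A), 0)

  u <- matrix(0, 2, 6)
  v <- matrix(c(3, 4), 2, 6)
  expect_equal(pairwise_separation(u, v), 5)

  B <- matrix(rnorm(40), 4, 10)
  expect_equal(pairwise_separation(A, B), pairwise_separation(B, A))
  expect_error(pairwise_separation(A, matrix(0, 4, 9)),
               class = "esndisc_config_error")
})

test_that("linear_separation_rank matches an SVD oracle", {
  Q <- qr.Q(qr(matrix(rnorm(100 * 5), 100, 5)))
  expect_equal(linear_separation_rank(Q), 5L)

  one <- matrix(rnorm(20), 20, 1)
  rep5 <- one[, rep(1, 5)]
  expect_equal(linear_separation_rank(rep5), 1L)

  set.seed(41)
  for (i in 1:5) {
    N <- sample(30:80, 1); m <- sample(2:8, 1)
    M <- matrix(rnorm(N * m), N, m)  # independent Gaussian columns
    expect_equal(linear_separation_rank(M), m)  # rank saturates at m
    expect_lte(linear_separation_rank(M), min(dim(M)))
    oracle <- sum(svd(M)$d > max(dim(M)) * .Machine$double.eps * svd(M)$d[1])
    expect_equal(linear_separation_rank(M), oracle)
  }
  expect_equal(linear_separation_rank(matrix(0, 4, 3)), 0L)
})

test_that("scatter traces agree with explicit scatter matrices", {
  # 1-D, two classes at means 0 and 2, equal priors: global mean 1,
  # tr(S_b) = 0.5*1 + 0.5*1 = 1
  d <- labeled_dynamics(matrix(c(0, 2), 2, 1), c("a", "b"))
  s <- scatter_summary(d)
  expect_equal(s$S_b_trace, 1)
  expect_equal(s$S_w_trace, 0)

  same <- labeled_dynamics(matrix(1, 4, 3), c("a", "a", "b", "b"))
  s0 <- scatter_summary(same)
  expect_equal(s0$S_b_trace, 0)
  expect_equal(s0$S_w_trace, 0)

  # brute-force oracle: materialize S_b and S_w on small random data
  set.seed(42)
  for (rep in 1:5) {
    L <- sample(2:4, 1); D <- sample(2:10, 1)
    n_k <- sample(2:5, L, replace = TRUE)
    X <- matrix(rnorm(sum(n_k) * D), sum(n_k), D)
    labels <- rep(sprintf("c%d", seq_len(L)), n_k)
    ld <- labeled_dynamics(X, labels)
    got <- scatter_summary(ld)

    P <- table(labels)[sort(unique(labels))] / length(labels)
    mus <- t(sapply(sort(unique(labels)), function(c)
      colMeans(X[labels == c, , drop = FALSE])))
    mu_g <- colSums(mus * as.numeric(P))
    Sb <- matrix(0, D, D); Sw <- matrix(0, D, D)
    for (k in seq_len(L)) {
      diff <- mus[k, ] - mu_g
      Sb <- Sb + as.numeric(P[k]) * tcrossprod(diff)
      Sw <- Sw + as.numeric(P[k]) * stats::cov(X[labels == sort(unique(labels))[k], ])
    }
    expect_equal(got$S_b_trace, sum(diag(Sb)), tolerance = 1e-10)
    expect_equal(got$S_w_trace, sum(diag(Sw)), tolerance = 1e-10)
    expect_equal(got$DR, sum(diag(Sb)) / sum(diag(Sw)), tolerance = 1e-10)
  }
})

test_that("between-class scatter is translation invariant and monotone", {
  set.seed(43)
  X <- matrix(rnorm(12 * 6), 12, 6)
  labels <- rep(c("a", "b", "c"), each = 4)
  base <- scatter_summary(labeled_dynamics(X, labels))
  shifted <- scatter_summary(labeled_dynamics(
    sweep(X, 2, rnorm(6), `+`), labels))
  expect_equal(base$S_b_trace, shifted$S_b_trace, tolerance = 1e-10)
  expect_equal(base$S_w_trace, shifted$S_w_trace, tolerance = 1e-10)

  # moving one centroid radially away from the global mean cannot
  # decrease tr(S_b)
  prev <- base$S_b_trace
  for (scale in c(1.5, 3, 10)) {
    X2 <- X
    mu_a <- colMeans(X[labels == "a", ])
    mu_g <- colMeans(X)
    X2[labels == "a", ] <- sweep(X[labels == "a", ], 2,
                                 (scale - 1) * (mu_a - mu_g), `+`)
    cur <- scatter_summary(labeled_dynamics(X2, labels))$S_b_trace
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("single-class and degenerate inputs are handled", {
  expect_warning(s <- scatter_summary(labeled_dynamics(matrix(1:4, 4, 1),
                                                       rep("a", 4))))
  expect_equal(s$S_b_trace, 0)
  # zero within-class variance: DR guarded by eps, stays finite
  two <- labeled_dynamics(rbind(c(0, 0), c(1, 1)), c("a", "b"))
  expect_true(is.finite(scatter_summary(two)$DR))
})

test_that("kernel_quality_D follows the rank formula", {
  expect_equal(kernel_quality_D(20, 20), 0)
  expect_equal(kernel_quality_D(20, 0), 1)
  expect_equal(kernel_quality_D(10, 4), 0.6)
  expect_error(kernel_quality_D(0, 0), class = "esndisc_config_error")
})

test_that("vectorize_rates uses neuron-major order and round-trips", {
  M <- matrix(1:6, 2, 3)  # neuron 1: 1,3,5; neuron 2: 2,4,6
  v <- vectorize_rates(M)
  expect_equal(v, c(1, 3, 5, 2, 4, 6))
  expect_equal(matrix(v, nrow = 2, byrow = TRUE), M)
  expect_equal(vectorize_rates(matrix(0, 3, 4)), numeric(12))
})

test_that("pca_project preserves planar geometry and matches eigenvalues", {
  set.seed(44)
  # points on a 2-D plane embedded in 100-D: projection is an isometry
  basis <- qr.Q(qr(matrix(rnorm(100 * 2), 100, 2)))
  coords <- matrix(rnorm(30 * 2), 30, 2)
  X <- coords %*% t(basis)
  proj <- pca_project(labeled_dynamics(X, rep("a", 30)))
  expect_equal(as.matrix(dist(proj)), as.matrix(dist(coords)),
               tolerance = 1e-9)

  # duplicating the dataset leaves the projection unchanged
  X2 <- rbind(X, X)
  proj2 <- pca_project(labeled_dynamics(X2, rep("a", 60)))
  expect_equal(abs(unclass(proj2[1:30, ])), abs(unclass(proj)),
               ignore_attr = TRUE, tolerance = 1e-8)

  # reconstruction error from 2 components = sum of trailing eigenvalues
  Y <- matrix(rnorm(40 * 8), 40, 8)
  ld <- labeled_dynamics(Y, rep("a", 40))
  pr <- pca_project(ld)
  ev <- eigen(stats::cov(Y))$values
  Yc <- scale(Y, scale = FALSE)
  V <- stats::prcomp(Y)$rotation[, 1:2]
  resid <- Yc - Yc %*% V %*% t(V)
  expect_equal(sum(resid^2) / (nrow(Y) - 1), sum(ev[-(1:2)]),
               tolerance = 1e-8)
  expect_error(pca_project(labeled_dynamics(matrix(1, 1, 3), "a")),
               class = "esndisc_config_error")
})
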