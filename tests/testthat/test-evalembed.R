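# ANOVA-decomposition oracle for the Calinski-Harabasz index: per-dimension
# between/within sums of squares via stats::aov, traced over dimensions
oracle_chi <- function(X, labels) {
  g <- factor(labels)
  ssb <- 0; ssw <- 0
  for (j in seq_len(ncol(X))) {
    tab <- summary(stats::aov(X[, j] ~ g))[[1]]
    ssb <- ssb + tab["g", "Sum Sq"]
    ssw <- ssw + tab["Residuals", "Sum Sq"]
  }
  k <- nlevels(g); n <- nrow(X)
  (ssb / (k - 1)) / (ssw / (n - k))
}

test_that("displacement distances behave as Euclidean norms", {
  set.seed(1)
  B <- matrix(rnorm(50), 10, 5)
  expect_equal(displacement_distribution(B, B), rep(0, 10))
  shift <- matrix(rep(c(3, 4, 0, 0, 0), each = 10), 10)
  expect_equal(displacement_distribution(B, B + shift), rep(5, 10))
  expect_error(displacement_distribution(B, B[, 1:3]), "mismatch")
})

test_that("Gaussian displacement matches the chi-distribution mean", {
  set.seed(2)
  n <- 600L; D <- 6L; sigma <- 1.3
  B <- matrix(rnorm(n * D), n, D)
  A <- B + matrix(rnorm(n * D, sd = sigma), n, D)
  d <- displacement_distribution(B, A)
  mu <- sigma * sqrt(2) * gamma((D + 1) / 2) / gamma(D / 2)
  se <- stats::sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - mu), 3 * se)
})

test_that("conserved KNN proportion is 1 under isometry", {
  set.seed(3)
  B <- matrix(rnorm(40 * 4), 40)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  A <- 2.5 * B %*% Q + matrix(rep(rnorm(4), each = 40), 40)
  for (K in c(1L, 5L, 10L))
    expect_equal(knn_conservation(B, A, K)$proportion, 1.0)
  expect_error(knn_conservation(B, A, 40L), "K <= n - 1")
})

test_that("conserved KNN matches a hand-enumerated 4-point example", {
  # points on a line at 0, 1, 2.2, 3; after: swap the outer two gaps
  B <- cbind(c(0, 1, 2.2, 3), 0)
  A <- cbind(c(0, 2.0, 1.0, 3), 0)
  # K=1 before: nn(1)=2, nn(2)=1, nn(3)=4, nn(4)=3
  # K=1 after:  nn(1)=3, nn(2)=3 (tie 3/4 -> index), nn(3)=1 (tie 1/2),
  #             nn(4)=2 -> overlap 0 everywhere
  expect_equal(knn_conservation(B, A, 1L)$proportion, 0)
  # K=2 before: {2,3},{1,3},{4,2},{3,2}; after: {3,2},{3,4},{1,2},{2,3}
  # overlaps 2,1,1,2 -> mean/2 = 0.75
  expect_equal(knn_conservation(B, A, 2L)$proportion, 0.75)
})

test_that("independent clouds conserve ~1/(n-1) first neighbours", {
  set.seed(4)
  n <- 40L
  props <- replicate(60, {
    knn_conservation(matrix(rnorm(n * 3), n),
                     matrix(rnorm(n * 3), n), 1L)$proportion
  })
  expect_lt(abs(mean(props) - 1 / (n - 1)), 3 * sd(props) / sqrt(60))
})

test_that("ARI matches the closed-form contingency computation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  # 6-point worked example: partitions (112233) vs (111223)
  a <- c(1, 1, 2, 2, 3, 3); b <- c(1, 1, 1, 2, 2, 3)
  # contingency: [2,0,0; 1,1,0; 0,1,1]; sum_ij C(n_ij,2) = 1
  # sum_a = 3*C(2,2)=3, sum_b = C(3,2)+C(2,2)+0 = 4, C(6,2)=15
  # expected = 12/15 = 0.8; max = 3.5; ARI = (1-0.8)/(3.5-0.8)
  expect_equal(adjusted_rand_index(a, b), (1 - 0.8) / (3.5 - 0.8))
  expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
})

test_that("ARI agrees with the reference implementation on random cases", {
  set.seed(5)
  for (rep in 1:20) {
    a <- sample(4, 30, replace = TRUE)
    b <- sample(3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-8)
  }
  # null expectation ~ 0 for shuffled labels
  set.seed(6)
  aris <- replicate(50, adjusted_rand_index(sample(rep(1:4, each = 25)),
                                            rep(1:4, each = 25)))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("CHI matches hand computation and the ANOVA oracle", {
  X <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c("a", "a", "b", "b")
  # centroids (0,.5),(10,.5); trW = 4*0.25 = 1; trB = 4*25 = 100
  # CHI = (100/1)/(1/2) = 200
  expect_equal(calinski_harabasz(X, lab), 200)
  expect_equal(calinski_harabasz(X, lab), oracle_chi(X, lab),
               tolerance = 1e-8)
  set.seed(7)
  Xr <- matrix(rnorm(60 * 5), 60)
  labr <- sample(3, 60, replace = TRUE)
  expect_equal(calinski_harabasz(Xr, labr), oracle_chi(Xr, labr),
               tolerance = 1e-8)
  expect_error(calinski_harabasz(X, rep("a", 4)), "2 labels")
  expect_error(calinski_harabasz(rbind(c(0, 0), c(0, 0)), c("a", "b")),
               "dispersion")
})

test_that("CHI grows with cluster separation and is ~1 under the null", {
  set.seed(8)
  base <- matrix(rnorm(80 * 3), 80)
  lab <- rep(1:2, each = 40)
  sep1 <- base; sep1[lab == 2, 1] <- sep1[lab == 2, 1] + 4
  sep2 <- base; sep2[lab == 2, 1] <- sep2[lab == 2, 1] + 8
  expect_gt(calinski_harabasz(sep2, lab), calinski_harabasz(sep1, lab))
  # single Gaussian cloud with shuffled labels: F-statistic analogy, E ~ 1
  chis <- replicate(150, calinski_harabasz(matrix(rnorm(200), 50),
                                           sample(2, 50, replace = TRUE)))
  expect_lt(abs(mean(chis) - 1), 0.3)
})

test_that("cluster_ari recovers planted blobs and rejects bad input", {
  set.seed(9)
  centers <- matrix(rnorm(4 * 6, sd = 30), 4)
  X <- centers[rep(1:4, each = 15), ] + matrix(rnorm(60 * 6, sd = 0.1), 60)
  lab <- rep(letters[1:4], each = 15)
  rep1 <- cluster_ari(X, lab, seed = 3)
  expect_equal(rep1$ari, 1.0)
  expect_equal(rep1$n_clusters, 4L)
  rep2 <- cluster_ari(X, lab, reduce_2d = TRUE, seed = 3)
  expect_equal(rep2$ari, 1.0)
  expect_equal(rep2$reduction, "2d")
  # permuted labels on many points: ARI near 0
  set.seed(10)
  rep3 <- cluster_ari(X, sample(lab), seed = 3)
  expect_lt(abs(rep3$ari), 0.1)
  expect_error(cluster_ari(X[1:3, ], lab[1:3], n_clusters = 4L), "fewer")
})

test_that("KNN conservation is invariant to rigid transforms of either set", {
  set.seed(11)
  B <- matrix(rnorm(30 * 4), 30)
  A <- matrix(rnorm(30 * 4), 30)
  Q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  p0 <- knn_conservation(B, A, 5L)$proportion
  expect_equal(knn_conservation(B %*% Q * 3, A, 5L)$proportion, p0)
  expect_equal(knn_conservation(B, A %*% Q * 0.2, 5L)$proportion, p0)
})
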