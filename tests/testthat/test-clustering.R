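# k-means, elbow diagnostics, PCA, assignment and concordance.

two_clouds <- function(n = 100, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n, 0, sd), ncol = 2),
             matrix(rnorm(2 * n, sep, sd), ncol = 2))
  rownames(x) <- sprintf("c%03d", seq_len(2 * n))
  list(x = x, truth = rep(c(2L, 1L), each = n))  # cluster 1 = larger sum
}

test_that("well-separated clouds are recovered with full purity and a
           recomputable within-cluster sum of squares", {
  d <- two_clouds()
  km <- km_cluster(d$x, 2, seed = 5L, n_init = 10L)
  expect_equal(unname(km$labels), d$truth)
  # wss recomputed from labels and centers reproduces the reported value
  wss <- sum((d$x - km$centers[km$labels, ])^2)
  expect_equal(km$wss, wss, tolerance = 1e-9)
  # centers equal member means
  for (k in 1:2) {
    expect_equal(unname(km$centers[k, ]),
                 unname(colMeans(d$x[km$labels == k, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("k = 1 returns the grand mean and the total sum of squares", {
  d <- two_clouds(n = 30)
  km <- km_cluster(d$x, 1, seed = 2L, n_init = 5L)
  expect_equal(unname(km$centers[1, ]), unname(colMeans(d$x)),
               tolerance = 1e-12)
  expect_equal(km$wss, sum(scale(d$x, scale = FALSE)^2), tolerance = 1e-9)
  expect_error(km_cluster(d$x[1:3, ], 5, seed = 1),
               class = "ca1quant_sizing_error")
})

test_that("clustering is deterministic at a fixed seed and highly pure on
           6-sd-separated clouds across seeds", {
  d <- two_clouds(n = 40)
  a <- km_cluster(d$x, 2, seed = 9L)
  b <- km_cluster(d$x, 2, seed = 9L)
  expect_identical(a, b)
  purities <- vapply(1:25, function(s) {
    dd <- two_clouds(n = 30, sep = 6, sd = 1, seed = 100 + s)
    km <- km_cluster(dd$x, 2, seed = s, n_init = 10L)
    mean(km$labels == dd$truth)
  }, numeric(1))
  expect_gte(mean(purities), 0.99)
})

test_that("the elbow curve is non-increasing with its largest relative drop
           at the true k", {
  d <- two_clouds(n = 60, sep = 8)
  ew <- elbow_wss(d$x, k_max = 5, seed = 3L, n_init = 10L)
  expect_true(all(diff(ew$wss) <= 1e-9))
  drops <- ew$wss[-nrow(ew)] / pmax(ew$wss[-1], 1e-12)
  expect_equal(which.max(drops) + 1L, 2L)

  same <- matrix(1, nrow = 10, ncol = 2)
  ew0 <- elbow_wss(same, k_max = 3, seed = 1L, n_init = 2L)
  expect_true(all(ew0$wss < 1e-12))
  expect_error(elbow_wss(d$x, k_max = 1), class = "ca1quant_sizing_error")
})

test_that("PCA scores honour the variance, reconstruction and sign
           conventions", {
  # collinear 2D data: one component carries all variance
  set.seed(4)
  t <- rnorm(50)
  lin <- cbind(a = 2 * t + 3, b = -t + 1)
  sc <- zscore_pca(lin, n_components = 2)
  expect_equal(attr(sc, "var_explained")[1], 1, tolerance = 1e-12)

  # full-rank round trip: scores %*% t(loadings) = z-scored input
  x <- matrix(rnorm(200), ncol = 8)
  colnames(x) <- paste0("f", 1:8)
  sc8 <- zscore_pca(x, n_components = 8)
  recon <- sc8 %*% t(attr(sc8, "loadings"))
  expect_equal(unname(recon), unname(scale(x)[, ]), tolerance = 1e-9)

  # permutation equivariance over rows
  perm <- sample(nrow(x))
  sc_perm <- zscore_pca(x[perm, ], n_components = 3)
  expect_equal(c(unname(sc_perm)), c(unname(sc8[perm, 1:3])),
               tolerance = 1e-9)

  # column order changes nothing (given the sign convention)
  sc_shuf <- zscore_pca(x[, c(3, 1, 2, 8, 5, 4, 7, 6)], n_components = 3)
  expect_equal(c(abs(unname(sc_shuf))), c(abs(unname(sc8[, 1:3]))),
               tolerance = 1e-9)

  # zero-variance columns are flagged and removed
  xz <- cbind(x, const = 1)
  expect_warning(zscore_pca(xz, 2), "zero-variance")
})

test_that("new points go to the nearest centre, ties to the lower index", {
  d <- two_clouds(n = 30)
  km <- km_cluster(d$x, 2, seed = 1L)
  expect_equal(assign_new(km$centers[2, ], km), 2L)
  mid <- colMeans(km$centers)
  expect_equal(assign_new(mid, km), 1L)
  expect_error(assign_new(c(1, 2, 3), km), class = "ca1quant_shape_error")
  # synthetic confirmed-positive cells deep in the high-score quadrant
  high <- km$centers[1, ] + matrix(rnorm(8, 0, 0.2), ncol = 2)
  expect_true(all(assign_new(high, km) == 1L))
})

test_that("concordance pairs clusters by majority match and degrades with
           label noise", {
  a <- stats::setNames(rep(1:2, each = 10), sprintf("c%02d", 1:20))
  expect_equal(concordance(a, a)$agreement, 1.0)
  flipped <- stats::setNames(3L - a, names(a))
  expect_equal(concordance(a, flipped)$agreement, 1.0)  # relabelling only

  expect_error(concordance(a, a[-1]), class = "ca1quant_join_error")

  # agreement decreases monotonically as labels are scrambled
  agree_at_noise <- function(p_flip) {
    mean(vapply(1:20, function(s) {
      set.seed(700 + s)
      b <- ifelse(runif(length(a)) < p_flip,
                  sample(1:2, length(a), replace = TRUE), a)
      concordance(a, stats::setNames(b, names(a)))$agreement
    }, numeric(1)))
  }
  ag <- vapply(c(0, 0.4, 0.9), agree_at_noise, numeric(1))
  expect_true(all(diff(ag) < 0))
})

test_that("rows with missing features are dropped and recorded", {
  df <- data.frame(cell_id = c("a", "b", "c"), f1 = c(1, NA, 3),
                   f2 = c(2, 5, 6))
  m <- feature_matrix(df, id_col = "cell_id")
  expect_equal(rownames(m), c("a", "c"))
  expect_equal(attr(m, "dropped"), "b")
})
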