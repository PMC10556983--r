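make_blobs <- function(n_per = 20, d = 5, sep = 8, seed = 41) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
  })
  colnames(X) <- paste0("f", seq_len(d))
  rownames(X) <- paste0("s", seq_len(2 * n_per))
  list(X = X, groups = rep(c("A", "B"), each = n_per))
}

test_that("k-means on leading PCs recovers well-separated groups", {
  b <- make_blobs()
  km <- kmeans_groups(b$X, k = 2, n_pcs = 3, seed = 1)
  ari <- mclust::adjustedRandIndex(km$groups, b$groups)
  expect_equal(ari, 1)
  km1 <- kmeans_groups(b$X, k = 1, n_pcs = 3, seed = 1)
  expect_true(is.finite(km1$bic))
  expect_error(kmeans_groups(b$X, k = 100), "exceed")
})

test_that("DAPC separates groups, fixes orientation, and matches MASS::lda", {
  b <- make_blobs(sep = 6)
  fit <- dapc_fit(b$X, b$groups, n_pcs = 4)
  # complete training separation, first level negative
  sA <- fit$scores[b$groups == "A", 1]
  sB <- fit$scores[b$groups == "B", 1]
  expect_lt(max(sA), min(sB))
  expect_lt(mean(sA), 0)
  # unit norm in the whitened (within-covariance) metric is scale-free for
  # classification: assignments agree with the reference LDA implementation
  proj <- dapc_project(fit, b$X)
  ref <- MASS::lda(b$X, grouping = b$groups, prior = c(0.5, 0.5))
  ref_cls <- predict(ref, b$X)$class
  expect_equal(as.character(proj$assigned), as.character(ref_cls))
  # held-out accuracy grows with separation
  acc <- vapply(c(1, 3, 6), function(s) {
    tr <- make_blobs(sep = s, seed = 43)
    te <- make_blobs(sep = s, seed = 44)
    fit <- dapc_fit(tr$X, tr$groups, n_pcs = 4)
    mean(dapc_project(fit, te$X)$assigned == te$groups)
  }, numeric(1))
  expect_true(all(diff(acc) >= 0))
  expect_gt(acc[3], 0.99)
})

test_that("DAPC degenerate inputs take the ridge path and posteriors are sane", {
  X <- rbind(matrix(1:10, 5, 2), matrix(1:10, 5, 2))
  X <- cbind(X, X)  # duplicated features -> singular within-covariance
  colnames(X) <- paste0("f", 1:4)
  groups <- rep(c("A", "B"), each = 5)
  X[groups == "B", ] <- X[groups == "B", ] + 3
  fit <- suppressMessages(dapc_fit(X, groups, n_pcs = 3))
  expect_true(fit$ridge_used)
  # a sample at a group mean is assigned to that group
  b <- make_blobs()
  fit2 <- dapc_fit(b$X, b$groups, n_pcs = 3)
  mA <- colMeans(b$X[b$groups == "A", , drop = FALSE])
  mB <- colMeans(b$X[b$groups == "B", , drop = FALSE])
  pr <- dapc_project(fit2, rbind(mA, (mA + mB) / 2))
  expect_gt(pr$posterior[1, "A"], 0.5)
  expect_equal(unname(pr$posterior[2, "A"]), 0.5, tolerance = 1e-6)
  expect_error(dapc_project(fit2, b$X[, 1:3]), "missing features|dimension")
})

test_that("plasticity is the absolute z-score reaction norm, cluster-wise", {
  # cluster with scores exactly (0, 2): z = -0.707, +0.707 (n-1 SD)
  meta1 <- tibble::tibble(
    sample = c("s1", "s2"), accession = "a1", cluster = "k",
    site = c("inland", "coastal"), replicate = 1)
  pl1 <- plasticity(c(0, 2), meta1, c(k = "inland"))
  expect_equal(pl1$z_native, -0.7071068, tolerance = 1e-6)
  expect_equal(pl1$plasticity, 2 / sqrt(2), tolerance = 1e-6)

  meta <- tibble::tibble(
    sample = paste0("s", 1:4),
    accession = c("a1", "a1", "a2", "a2"), cluster = "k",
    site = rep(c("inland", "coastal"), 2), replicate = 1)
  scores <- c(0, 2, 2, 0)
  pl <- plasticity(scores, meta, c(k = "inland"))
  expect_equal(pl$plasticity,
               rep(abs(2 / sd(scores)), 2))
  # identical scores at both sites -> zero plasticity
  pl0 <- plasticity(c(1, 1, 5, 5), meta, c(k = "inland"))
  expect_equal(pl0$plasticity, c(0, 0))
  # location shifts of a cluster's scores cancel in the z-transform only
  # through the difference: adding a constant leaves plasticity unchanged
  pl_shift <- plasticity(scores + 7, meta, c(k = "inland"))
  expect_equal(pl_shift$plasticity, pl$plasticity)
})

test_that("z-transform inside plasticity uses the n-1 SD convention", {
  meta <- tibble::tibble(
    sample = paste0("s", 1:4),
    accession = c("a1", "a1", "a2", "a2"), cluster = "k",
    site = rep(c("inland", "coastal"), 2), replicate = 1)
  scores <- c(0, 0, 2, 2)  # cluster mean 1, sd (n-1) = 1.1547
  pl <- plasticity(scores, meta, c(k = "inland"))
  z2 <- (2 - 1) / sd(scores)
  expect_equal(unname(pl$z_native[pl$accession == "a2"]), z2)
  expect_equal(z2, 1 / 1.154701, tolerance = 1e-6)
})

test_that("plasticity ANOVA detects cluster differences and degenerates to p=1", {
  withr::with_seed(47, {
    pl <- tibble::tibble(
      plasticity = c(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1)),
      cluster = rep(c("A", "B"), each = 10))
  })
  pt <- plasticity_test(pl)
  expect_lt(pt$anova$p.value, 1e-6)
  expect_lt(pt$tukey$adj.p.value[1], 1e-6)
  flat <- plasticity_test(tibble::tibble(
    plasticity = rep(2, 8), cluster = rep(c("A", "B"), each = 4)))
  expect_equal(flat$anova$p.value, 1)
  expect_true(all(flat$tukey$adj.p.value == 1))
  # Tukey-adjusted p is never below the unadjusted pairwise t-test p
  withr::with_seed(48, {
    pl3 <- tibble::tibble(
      plasticity = c(rnorm(8), rnorm(8, 1), rnorm(8, 2)),
      cluster = rep(c("A", "B", "C"), each = 8))
  })
  pt3 <- plasticity_test(pl3)
  tt <- t.test(pl3$plasticity[pl3$cluster == "B"],
               pl3$plasticity[pl3$cluster == "A"], var.equal = TRUE)
  expect_gte(pt3$tukey$adj.p.value[pt3$tukey$contrast == "B-A"],
             tt$p.value - 1e-10)
})
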