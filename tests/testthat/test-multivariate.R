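test_that("PCA recovers rank structure with a fixed sign convention", {
  # rank-1 data: single component carries all variance
  set.seed(10)
  u <- rnorm(12)
  v <- rnorm(6)
  m <- toy_matrix(outer(u, v) + 0.5, nrow = 12, space = "log2")
  m <- m + matrix(rnorm(72, sd = 1e-9), 12)  # break exact ties only
  p <- run_pca(m, n_components = 3)
  expect_gt(p$explained_variance_ratio[1], 1 - 1e-12)
  # ratios non-increasing, sum <= 1
  set.seed(11)
  m2 <- toy_matrix(rnorm(200), nrow = 20, space = "log2")
  p2 <- run_pca(m2)
  expect_true(all(diff(p2$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p2$explained_variance_ratio), 1 + 1e-12)
  # full-rank reconstruction
  Xc <- t(m2 - rowMeans(m2))
  rec <- p2$scores %*% t(p2$loadings)
  expect_lt(sqrt(sum((rec - Xc)^2)), 1e-8)
  # sign convention: largest-|loading| entry positive
  for (a in seq_len(ncol(p2$loadings)))
    expect_gt(p2$loadings[which.max(abs(p2$loadings[, a])), a], 0)
  expect_error(run_pca(toy_matrix(c(1, 1, 1, 2, 1, 3), nrow = 2)),
               "constant")
})

test_that("two orthogonal design blocks are captured by two components", {
  blockA <- rep(c(1, -1), each = 6)
  blockB <- rep(c(1, -1, 1, -1), each = 3)
  m <- rbind(outer(rep(1, 5), blockA), outer(rep(1, 5), blockB))
  m <- m + matrix(rnorm(120, sd = 1e-6), 10)
  rownames(m) <- paste0("f", 1:10)
  colnames(m) <- paste0("s", 1:12)
  p <- run_pca(m, n_components = 2)
  expect_equal(sum(p$explained_variance_ratio[1:2]), 1, tolerance = 1e-9)
})

test_that("ASCA effect matrices decompose the centered data", {
  b <- default_gc_bundle()
  lg <- normalize_abundance(b$proteins, "total_intensity", to_log2 = TRUE)
  a <- run_asca(lg, b$meta)
  Xc <- lg - rowMeans(lg)
  recon <- Reduce(`+`, a$effects) + a$residual
  expect_lt(sqrt(sum((recon - Xc)^2)) / sqrt(sum(Xc^2)), 1e-9)
  # a two-level factor gives a rank-1 effect matrix: PC1 carries 100%
  expect_equal(a$effect_pca$fraction$pc1_percent, 100, tolerance = 1e-9)
  expect_error(run_asca(lg, transform(b$meta, fraction = "GCM")),
               "fewer than 2")
})

test_that("balanced designs give an exact orthogonal SS decomposition", {
  # balanced 2x5 with 6 replicates everywhere
  cfg <- gc_sim_config(reduced_cells = list())
  b <- generate_gc_multiomic(cfg, seed = 3)
  lg <- normalize_abundance(b$proteins, "total_intensity", to_log2 = TRUE)
  a <- run_asca(lg, b$meta)
  ss <- a$ss
  expect_equal(ss[["total"]],
               ss[["fraction"]] + ss[["stage"]] + ss[["fraction:stage"]] +
                 ss[["residual"]],
               tolerance = 1e-9)
  for (pair in list(c("fraction", "stage"),
                    c("fraction", "fraction:stage"),
                    c("stage", "fraction:stage"))) {
    E1 <- a$effects[[pair[1]]]
    E2 <- a$effects[[pair[2]]]
    expect_lt(abs(sum(E1 * E2)),
              1e-9 * sqrt(sum(E1^2)) * sqrt(sum(E2^2)))
  }
  # all-equal group means: effect matrices vanish
  flat <- toy_matrix(rep(c(5, 7), 5), nrow = 2, space = "log2")
  meta <- data.frame(sample_id = colnames(flat),
                     g = rep(c("a", "b"), 5))
  a0 <- run_asca(flat + 0, meta, factors = "g", with_interaction = FALSE)
  expect_lt(sqrt(sum(a0$effects$g^2)), 1e-9)
})

test_that("PLS VIP normalization and degenerate fits behave as defined", {
  # all-equal weights: every VIP is 1
  y <- c(0, 1, 2, 3, 4, 2, 1, 3)
  X <- rbind(y, y, y, y)
  rownames(X) <- paste0("f", 1:4)
  colnames(X) <- paste0("s", 1:8)
  fit <- pls_stage_model(X, y, ncomp = 1, autoscale = FALSE)
  expect_equal(unname(fit$vip), rep(1, 4), tolerance = 1e-9)
  # a copy of the response is a perfect single-component predictor
  set.seed(12)
  X2 <- rbind(y, matrix(rnorm(3 * 8, sd = 1e-6), 3))
  X2 <- X2 - rowMeans(X2)
  rownames(X2) <- paste0("f", 1:4)
  colnames(X2) <- paste0("s", 1:8)
  fit2 <- pls_stage_model(X2, y, ncomp = 1, autoscale = FALSE)
  expect_gte(fit2$R2, 0.999)
  # sum VIP^2 = p on a real model
  gcres <- default_gc_results()
  vip <- gcres$pls$vip
  expect_equal(sum(vip^2), length(vip), tolerance = 1e-9 * length(vip))
  expect_true(gcres$pls$accuracy >= 0 && gcres$pls$accuracy <= 1)
  # more components than the rank supports
  expect_error(pls_stage_model(X, y, ncomp = 3, autoscale = FALSE), "rank")
})

test_that("NIPALS agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(13)
  X <- toy_matrix(rnorm(15 * 30), nrow = 15, space = "log2")
  y <- rnorm(30) + 2 * colMeans(X[1:3, ])
  fit <- pls_stage_model(X, y, ncomp = 3)
  Xs <- scale(t(X))
  m <- mixOmics::pls(Xs, y, ncomp = 3, mode = "regression", scale = FALSE)
  pred <- predict(m, Xs)$predict[, 1, 3]
  expect_equal(unname(fit$fitted), unname(pred), tolerance = 1e-10)
  expect_equal(unname(fit$vip), unname(mixOmics::vip(m)[, 3]),
               tolerance = 1e-10)
})

test_that("PLS stage model recovers the planted trend proteins", {
  gcres <- default_gc_results()
  b <- gcres$bundle
  planted <- c(b$truth$trend_proteins_pos, b$truth$trend_proteins_neg)
  vipset <- names(gcres$pls$vip)[gcres$pls$vip > 2]
  expect_gt(length(vipset), 0)
  expect_gte(mean(vipset %in% planted), 0.8)
  expect_gt(gcres$pls$R2, gcres$pls$Q2)
})

test_that("Ward clustering separates fractions and scores purity", {
  # two well-separated blobs
  set.seed(14)
  m <- cbind(matrix(rnorm(40, 0), 4), matrix(rnorm(40, 10), 4))
  rownames(m) <- paste0("f", 1:4)
  colnames(m) <- paste0("s", 1:20)
  cl <- hierarchical_cluster(m, k = 2, labels = rep(c("a", "b"), each = 10))
  expect_equal(cl$purity, 100)
  # k = n: trivially pure
  cln <- hierarchical_cluster(m, k = 20, labels = rep(c("a", "b"), each = 10))
  expect_equal(cln$purity, 100)
  expect_error(hierarchical_cluster(m, k = 1), "between 2")
  expect_error(hierarchical_cluster(m, k = 21), "between 2")
  # the profiled design: 100% fraction purity at k = 2
  gcres <- default_gc_results()
  expect_equal(gcres$ward$purity, 100)
})

test_that("k-means split separates early from late development", {
  # planted 1-D two-mean data
  set.seed(15)
  x <- toy_matrix(c(rnorm(10, 0), rnorm(10, 10)), nrow = 1, space = "log2")
  ords <- rep(c(0, 4), each = 10)
  km <- kmeans_split(x, ords, seed = 2)
  expect_equal(unname(km$assignments), rep(c("early", "late"), each = 10))
  # degenerate input
  const <- toy_matrix(rep(1, 6), nrow = 2, space = "log2")
  expect_warning(km0 <- kmeans_split(const, c(0, 1, 2)), "identical")
  expect_equal(km0$k, 1)
  # the profiled lipidome groups E18/P0 against P3-P9
  gcres <- default_gc_results()
  b <- gcres$bundle
  gcm <- b$meta$fraction == "GCM"
  split <- split(b$meta$stage[gcm], gcres$kmeans$assignments)
  expect_setequal(unique(split$early), c("E18", "P0"))
  expect_setequal(unique(split$late), c("P3", "P6", "P9"))
  # deterministic given the seed
  lip <- normalize_abundance(
    normalize_abundance(b$lipids, "total_intensity", to_log2 = TRUE)[, gcm],
    "autoscale")
  k1 <- kmeans_split(lip, b$meta$stage_ordinal[gcm], seed = 9)
  k2 <- kmeans_split(lip, b$meta$stage_ordinal[gcm], seed = 9)
  expect_identical(k1$assignments, k2$assignments)
})

test_that("sample correlation matrix matches the direct formula", {
  set.seed(16)
  m <- toy_matrix(rnorm(50), nrow = 10, space = "log2")
  cc <- sample_correlation_matrix(m)
  manual <- matrix(1, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    x <- m[, i] - mean(m[, i])
    y <- m[, j] - mean(m[, j])
    manual[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  expect_equal(unname(cc), manual, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(diag(cc)), rep(1, 5))
  # duplicated and negated samples
  m2 <- cbind(m, dup = m[, 1], neg = -m[, 1])
  cc2 <- sample_correlation_matrix(m2)
  expect_equal(unname(cc2["dup", "s1"]), 1)
  expect_equal(unname(cc2["neg", "s1"]), -1)
  # constant profile flagged
  m3 <- cbind(m, flat = rep(2, 10))
  cc3 <- sample_correlation_matrix(m3)
  expect_identical(attr(cc3, "undefined_samples"), "flat")
  expect_error(sample_correlation_matrix(m[1, , drop = FALSE]), "2 features")
})
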