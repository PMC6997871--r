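#' Principal component analysis of samples
#'
#' SVD-based PCA treating samples (columns) as observations. Features are
#' expected to be centered or autoscaled; rows are re-centered defensively.
#' A deterministic sign convention is applied: within each component the
#' loading entry of largest magnitude is made positive.
#'
#' @param mat features x samples matrix (centered or autoscaled).
#' @param n_components number of components to keep (default
#'   `min(dim)`).
#' @return object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance_ratio` (over
#'   all components of the data, truncated to the kept ones).
#' @export
run_pca <- function(mat, n_components = NULL) {
  sdv <- apply(mat, 1, stats::sd)
  if (any(sdv == 0))
    stop("constant feature(s) present; remove before PCA: ",
         paste(utils::head(rownames(mat)[sdv == 0], 5), collapse = ", "))
  X <- t(mat - rowMeans(mat))
  k_max <- min(dim(X))
  if (is.null(n_components)) n_components <- k_max
  if (n_components > k_max)
    stop("n_components exceeds min(dim) = ", k_max)
  s <- svd(X)
  evr <- s$d^2 / sum(s$d^2)
  keep <- seq_len(n_components)
  scores <- s$u[, keep, drop = FALSE] %*% diag(s$d[keep], n_components)
  loadings <- s$v[, keep, drop = FALSE]
  for (a in keep) {
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(colnames(mat), paste0("PC", keep))
  dimnames(loadings) <- list(rownames(mat), paste0("PC", keep))
  res <- list(scores = scores, loadings = loadings,
              explained_variance_ratio = evr[keep])
  class(res) <- "pca_result"
  res
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", nrow(x$loadings), "features\n")
  cat("  variance ratios:",
      paste(sprintf("%.3f", utils::head(x$explained_variance_ratio, 5)),
            collapse = " "), "\n")
  invisible(x)
}

#' ANOVA-simultaneous component analysis
#'
#' Partitions the feature-centered data matrix into per-factor effect
#' matrices (level-mean deviations broadcast to samples), an optional
#' interaction matrix (cell means minus main effects) and a residual, then
#' runs PCA on each effect matrix. On a balanced design the decomposition is
#' exact and the effect matrices are pairwise orthogonal; the residual is
#' always defined as the remainder so the identity
#' `centered = sum(effects) + residual` holds by construction.
#'
#' @param mat features x samples matrix (any space; rows are centered
#'   internally).
#' @param meta sample metadata with one column per factor, rows aligned
#'   with (or named by) the sample columns.
#' @param factors character vector of factor column names (default
#'   `c("fraction", "stage")`).
#' @param with_interaction include the pairwise interaction of the first two
#'   factors.
#' @return object of class `asca_result`: `effects` (named list of effect
#'   matrices, features x samples), `residual`, `ss` (named sums of
#'   squares incl. `total`), `ss_share`, and `effect_pca` — per effect, the
#'   PCA variance ratios of the effect matrix (its PC1 share is the
#'   "percent of an effect's variation on PC1" statistic).
#' @export
run_asca <- function(mat, meta, factors = c("fraction", "stage"),
                     with_interaction = TRUE) {
  if (!is.null(meta$sample_id)) {
    idx <- match(colnames(mat), meta$sample_id)
    if (anyNA(idx)) stop("metadata does not cover all samples")
    meta <- meta[idx, , drop = FALSE]
  }
  miss <- setdiff(factors, names(meta))
  if (length(miss))
    stop("metadata lacks factor column(s): ", paste(miss, collapse = ", "))
  Xc <- mat - rowMeans(mat)
  n_s <- ncol(Xc)
  effects <- list()
  for (f in factors) {
    lev <- as.factor(meta[[f]])
    if (nlevels(lev) < 2)
      stop("factor '", f, "' has fewer than 2 levels")
    means <- sapply(levels(lev), function(l)
      rowMeans(Xc[, lev == l, drop = FALSE]))
    effects[[f]] <- means[, as.character(lev), drop = FALSE]
    colnames(effects[[f]]) <- colnames(Xc)
  }
  if (with_interaction && length(factors) >= 2) {
    f1 <- as.factor(meta[[factors[1]]])
    f2 <- as.factor(meta[[factors[2]]])
    cell <- interaction(f1, f2, drop = TRUE)
    cmeans <- sapply(levels(cell), function(l)
      rowMeans(Xc[, cell == l, drop = FALSE]))
    inter <- cmeans[, as.character(cell), drop = FALSE] -
      effects[[factors[1]]] - effects[[factors[2]]]
    colnames(inter) <- colnames(Xc)
    effects[[paste(factors[1], factors[2], sep = ":")]] <- inter
  }
  residual <- Xc - Reduce(`+`, effects)
  ss <- c(vapply(effects, function(E) sum(E^2), numeric(1)),
          residual = sum(residual^2), total = sum(Xc^2))
  effect_pca <- lapply(effects, function(E) {
    d2 <- svd(t(E), nu = 0, nv = 0)$d^2
    ratios <- d2 / sum(d2)
    list(variance_ratios = ratios, pc1_percent = 100 * ratios[1])
  })
  res <- list(effects = effects, residual = residual, ss = ss,
              ss_share = ss[names(ss) != "total"] / ss[["total"]],
              effect_pca = effect_pca)
  class(res) <- "asca_result"
  res
}

#' @export
print.asca_result <- function(x, ...) {
  cat("ASCA decomposition\n")
  for (nm in names(x$effects))
    cat(sprintf("  %-16s SS share %.3f, effect PC1 %.1f%%\n", nm,
                x$ss_share[[nm]], x$effect_pca[[nm]]$pc1_percent))
  cat(sprintf("  %-16s SS share %.3f\n", "residual",
              x$ss_share[["residual"]]))
  invisible(x)
}

#' PLS regression of developmental stage with VIP scores
#'
#' Single-response PLS (NIPALS with deflation) of the stage ordinal on
#' autoscaled features, reporting fitted variance explained (R2),
#' cross-validated Q2 (`1 - PRESS/TSS` under stage-stratified k-fold CV with
#' in-fold re-scaling), rounded-prediction stage accuracy, and
#' variable-importance-in-projection scores
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` (weights normalized
#' per component), which satisfy `sum(VIP^2) = p`.
#'
#' @param mat features x samples matrix (raw/log2; autoscaled internally
#'   unless `autoscale = FALSE`).
#' @param stage_ordinal numeric response per sample (e.g. E18=0 .. P9=4).
#' @param ncomp number of latent components.
#' @param cv_folds folds for Q2 (default 7, stratified by stage).
#' @param autoscale standardize features before fitting.
#' @return object of class `pls_model` with `weights`, `scores`,
#'   `loadings`, `y_loadings`, `coefficients`, `fitted`, `R2`, `Q2`,
#'   `accuracy`, `vip`.
#' @export
pls_stage_model <- function(mat, stage_ordinal, ncomp = 2, cv_folds = 7,
                            autoscale = TRUE) {
  if (length(stage_ordinal) != ncol(mat))
    stop("stage_ordinal must have one value per sample")
  if (ncomp < 1) stop("ncomp must be >= 1")
  Xs <- if (autoscale) normalize_abundance(mat, "autoscale") else mat
  fit <- pls1_nipals(t(Xs), stage_ordinal, ncomp)
  vip <- pls_vip(fit)
  acc <- mean(pmin(pmax(round(fit$fitted), min(stage_ordinal)),
                   max(stage_ordinal)) == stage_ordinal)
  q2 <- pls_q2(mat, stage_ordinal, ncomp, cv_folds, autoscale)
  res <- c(fit, list(vip = vip, accuracy = acc, Q2 = q2, ncomp = ncomp))
  class(res) <- "pls_model"
  res
}

# NIPALS PLS1. X: samples x features (scaled by the caller; column-centered
# here, the standard PLS convention), y: numeric response.
pls1_nipals <- function(X, y, ncomp) {
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  X <- sweep(X, 2, x_center)
  y_mean <- mean(y)
  yc <- y - y_mean
  tss <- sum(yc^2)
  E <- X
  f <- yc
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12)
      stop("requested components exceed the rank of the data")
    w <- w / wn
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[a] * t_
    W[, a] <- w
    P[, a] <- p_
    Tm[, a] <- t_
  }
  ssy <- q^2 * colSums(Tm^2)
  coef <- W %*% solve(crossprod(P, W), q)
  fitted <- drop(X %*% coef) + y_mean
  list(weights = W, loadings = P, scores = Tm, y_loadings = q,
       coefficients = drop(coef), y_mean = y_mean, x_center = x_center,
       fitted = fitted, ssy = ssy,
       R2 = 1 - sum(f^2) / tss,
       feature_ids = colnames(X))
}

pls_vip <- function(fit) {
  p <- nrow(fit$weights)
  w2 <- fit$weights^2  # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% fit$ssy) / sum(fit$ssy))
  names(vip) <- fit$feature_ids
  vip
}

pls_q2 <- function(mat, y, ncomp, folds, autoscale) {
  n <- ncol(mat)
  folds <- min(folds, n)
  # stratified by response level so every fold spans the stage range
  idx <- unlist(lapply(split(seq_len(n), y), function(ix)
    ix[order(seq_along(ix))]), use.names = FALSE)
  fold_of <- integer(n)
  fold_of[idx] <- rep_len(seq_len(folds), n)
  press <- tss <- 0
  for (k in seq_len(folds)) {
    test <- fold_of == k
    Xtr <- mat[, !test, drop = FALSE]
    Xte <- mat[, test, drop = FALSE]
    if (autoscale) {
      mu <- rowMeans(Xtr)
      sdv <- apply(Xtr, 1, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 1, mu, "-"), 1, sdv, "/")
      Xte <- sweep(sweep(Xte, 1, mu, "-"), 1, sdv, "/")
    }
    fit <- pls1_nipals(t(Xtr), y[!test], ncomp)
    pred <- drop(sweep(t(Xte), 2, fit$x_center) %*% fit$coefficients) +
      fit$y_mean
    press <- press + sum((y[test] - pred)^2)
    tss <- tss + sum((y[test] - mean(y[!test]))^2)
  }
  1 - press / tss
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf(
    "PLS stage model: %d components, R2 = %.4f, Q2 = %.4f, accuracy = %.4f\n",
    x$ncomp, x$R2, x$Q2, x$accuracy))
  cat(sprintf("  features with VIP > 2: %d of %d\n", sum(x$vip > 2),
              length(x$vip)))
  invisible(x)
}

cluster_purity <- function(assignments, labels) {
  tab <- table(assignments, labels)
  100 * sum(apply(tab, 1, max)) / length(assignments)
}

#' Hierarchical (Ward) clustering of samples with purity
#'
#' Agglomerative clustering of samples with Euclidean distance and Ward
#' linkage (`hclust` method `ward.D2`, i.e. Ward on squared Euclidean
#' increments), cut into `k` clusters. Purity is the percentage of samples
#' falling in clusters whose majority label matches their own.
#'
#' @param mat features x samples matrix (autoscale first for the standard
#'   heatmap-style analysis).
#' @param k number of clusters, `2 <= k <= n samples`.
#' @param labels per-sample labels for the purity computation (optional).
#' @param linkage `hclust` linkage method.
#' @return object of class `cluster_result`: `assignments`, `method`, `k`,
#'   `purity` (NA when no labels given), `hclust` tree.
#' @export
hierarchical_cluster <- function(mat, k, labels = NULL,
                                 linkage = "ward.D2") {
  n <- ncol(mat)
  if (k < 2 || k > n) stop("k must be between 2 and the sample count")
  hc <- stats::hclust(stats::dist(t(mat)), method = linkage)
  assignments <- stats::cutree(hc, k = k)
  purity <- if (is.null(labels)) NA_real_ else
    cluster_purity(assignments, labels)
  res <- list(assignments = assignments, method = linkage, k = k,
              purity = purity, hclust = hc)
  class(res) <- "cluster_result"
  res
}

#' Two-means early/late partition of samples
#'
#' k-means (50 random restarts under the given seed) with k = 2 on samples
#' in autoscaled feature space; the cluster whose samples have the lower
#' mean stage ordinal is labeled `"early"`, the other `"late"`.
#'
#' @param mat features x samples matrix (autoscaled species space).
#' @param stage_ordinal numeric stage ordinal per sample.
#' @param seed RNG seed for the restarts.
#' @return object of class `cluster_result` with `assignments` taking values
#'   `"early"`/`"late"` and `stage_split` listing the stages per side.
#' @export
kmeans_split <- function(mat, stage_ordinal, seed = 1) {
  if (ncol(mat) < 2) stop("need at least 2 samples")
  pts <- t(mat)
  if (nrow(unique(pts)) < 2) {
    warning("all samples identical; returning a single cluster")
    assignments <- stats::setNames(rep("early", ncol(mat)), colnames(mat))
    res <- list(assignments = assignments, method = "kmeans", k = 1,
                purity = NA_real_, stage_split = NULL)
    class(res) <- "cluster_result"
    return(res)
  }
  km <- with_seed(seed, stats::kmeans(pts, centers = 2, nstart = 50))
  mean_ord <- tapply(stage_ordinal, km$cluster, mean)
  early_cluster <- as.integer(names(which.min(mean_ord)))
  assignments <- ifelse(km$cluster == early_cluster, "early", "late")
  names(assignments) <- colnames(mat)
  res <- list(assignments = assignments, method = "kmeans", k = 2,
              purity = NA_real_,
              stage_split = split(stage_ordinal, assignments))
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("clustering (", x$method, "), k = ", x$k, sep = "")
  if (!is.na(x$purity)) cat(sprintf(", purity %.1f%%", x$purity))
  cat("\n")
  invisible(x)
}

#' Pearson correlation matrix between samples
#'
#' @param mat features x samples matrix with >= 2 features.
#' @return symmetric samples x samples Pearson matrix with unit diagonal;
#'   samples with constant profiles yield NA entries and are listed in the
#'   `"undefined_samples"` attribute.
#' @export
sample_correlation_matrix <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 features")
  sdv <- apply(mat, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(mat))
  diag(cc) <- 1
  attr(cc, "undefined_samples") <- colnames(mat)[sdv == 0]
  cc
}
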