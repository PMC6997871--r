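#' Empirical-Bayes batch correction (location and scale)
#'
#' Parametric empirical-Bayes adjustment of per-batch location and scale:
#' features are standardized against the batch-size-weighted grand mean and
#' pooled variance; per-batch per-feature means and variances are shrunk
#' toward normal / inverse-gamma priors with method-of-moments
#' hyperparameters by iterated posterior updates (tolerance 1e-4, at most
#' 100 iterations); data are then adjusted and rescaled. After adjustment
#' each feature is re-centered to its pre-adjustment mean, so batch
#' correction never moves a feature's grand mean. With a single batch the
#' adjustment is the identity.
#'
#' @param mat features x samples matrix in log2 space.
#' @param batch batch label per sample (aligned with columns or named by
#'   sample id); every batch needs >= 2 samples.
#' @param tol relative convergence tolerance of the posterior iteration.
#' @param max_iter iteration cap per batch.
#' @return list with `adjusted` (matrix, same dimnames/space) and
#'   `adjustment`: `gamma_hat`, `delta_hat`, `gamma_star`, `delta_star`
#'   (features x batches), `stand_mean`, `pooled_var`, `iterations`,
#'   `converged`.
#' @export
combat_adjust <- function(mat, batch, tol = 1e-4, max_iter = 100) {
  if (abundance_space(mat) == "raw")
    stop("combat_adjust expects log2-space abundances")
  if (!is.null(names(batch))) batch <- batch[colnames(mat)]
  batch <- as.factor(batch)
  if (length(batch) != ncol(mat))
    stop("batch must have one label per sample")
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("every batch needs >= 2 samples; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  n_b <- nlevels(batch)
  p <- nrow(mat)
  if (n_b == 1) {
    zero <- matrix(0, p, 1, dimnames = list(rownames(mat), levels(batch)))
    one <- zero + 1
    return(list(adjusted = mat,
                adjustment = list(gamma_hat = zero, delta_hat = one,
                                  gamma_star = zero, delta_star = one,
                                  stand_mean = rowMeans(mat),
                                  pooled_var = apply(mat, 1, stats::var),
                                  iterations = 0L, converged = TRUE)))
  }
  n <- ncol(mat)
  batch_means <- sapply(levels(batch), function(b)
    rowMeans(mat[, batch == b, drop = FALSE]))
  grand_mean <- drop(batch_means %*% (as.numeric(sizes) / n))
  fitted <- batch_means[, as.integer(batch), drop = FALSE]
  pooled_var <- rowMeans((mat - fitted)^2)
  if (any(pooled_var == 0))
    stop("feature(s) with zero residual variance: ",
         paste(utils::head(rownames(mat)[pooled_var == 0], 5),
               collapse = ", "))
  Z <- (mat - grand_mean) / sqrt(pooled_var)

  gamma_hat <- sapply(levels(batch), function(b)
    rowMeans(Z[, batch == b, drop = FALSE]))
  delta_hat <- sapply(levels(batch), function(b)
    apply(Z[, batch == b, drop = FALSE], 1, stats::var))
  gamma_bar <- colMeans(gamma_hat)
  t2 <- apply(gamma_hat, 2, stats::var)
  a_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
  })
  b_prior <- apply(delta_hat, 2, function(d) {
    m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
  })

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iters <- integer(n_b)
  converged <- logical(n_b)
  for (i in seq_len(n_b)) {
    sel <- batch == levels(batch)[i]
    ni <- sum(sel)
    g_old <- gamma_hat[, i]
    d_old <- delta_hat[, i]
    for (it in seq_len(max_iter)) {
      g_new <- (t2[i] * ni * gamma_hat[, i] + d_old * gamma_bar[i]) /
        (t2[i] * ni + d_old)
      sum2 <- rowSums((Z[, sel, drop = FALSE] - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[i]) / (ni / 2 + a_prior[i] - 1)
      change <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                    abs(d_new - d_old) / (abs(d_old) + 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
    }
    iters[i] <- it
    converged[i] <- change < tol
    gamma_star[, i] <- g_old
    delta_star[, i] <- d_old
  }

  Zadj <- (Z - gamma_star[, as.integer(batch), drop = FALSE]) /
    sqrt(delta_star[, as.integer(batch), drop = FALSE])
  adjusted <- Zadj * sqrt(pooled_var) + grand_mean
  # re-center so each feature's grand mean is exactly preserved
  adjusted <- adjusted + (rowMeans(mat) - rowMeans(adjusted))
  dimnames(adjusted) <- dimnames(mat)
  attr(adjusted, "space") <- attr(mat, "space")
  list(adjusted = adjusted,
       adjustment = list(gamma_hat = gamma_hat, delta_hat = delta_hat,
                         gamma_star = gamma_star, delta_star = delta_star,
                         stand_mean = grand_mean, pooled_var = pooled_var,
                         iterations = iters, converged = all(converged)))
}

midrank_auc <- function(x_pos, x_neg) {
  r <- rank(c(x_pos, x_neg))
  n1 <- length(x_pos)
  n2 <- length(x_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

best_threshold <- function(x_pos, x_neg, direction) {
  v <- sort(unique(c(x_pos, x_neg)))
  cuts <- if (length(v) == 1) v else (v[-1] + v[-length(v)]) / 2
  cuts <- c(min(v) - 1, cuts, max(v) + 1)
  best <- list(j = -Inf)
  for (cut in cuts) {
    if (direction == "up") {
      sens <- mean(x_pos > cut)
      spec <- mean(x_neg <= cut)
    } else {
      sens <- mean(x_pos < cut)
      spec <- mean(x_neg >= cut)
    }
    j <- sens + spec - 1
    if (j > best$j)
      best <- list(j = j, cut = cut, sens = sens, spec = spec,
                   accuracy = (sens * length(x_pos) +
                                 spec * length(x_neg)) /
                     (length(x_pos) + length(x_neg)))
  }
  best
}

#' ROC-based ranking of species for regeneration vs control
#'
#' Midrank Mann-Whitney AUC per feature (ties get half credit),
#' orientation-corrected to >= 0.5 with the direction recorded, plus the
#' classification accuracy at the Youden-optimal threshold.
#'
#' @param mat features x samples matrix.
#' @param labels per-sample group label (aligned with columns or named).
#' @param positive label of the positive (regeneration) class.
#' @return data.frame sorted by decreasing AUC: `feature_id`, `auc`,
#'   `direction` (`up` = higher in positives), `accuracy`, `threshold`,
#'   `n_pos`, `n_neg`.
#' @export
roc_rank <- function(mat, labels, positive = "regeneration") {
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  pos <- labels == positive
  neg <- !pos
  if (!sum(pos) || !sum(neg)) stop("both groups must be non-empty")
  rows <- lapply(rownames(mat), function(f) {
    xp <- mat[f, pos]
    xn <- mat[f, neg]
    a <- midrank_auc(xp, xn)
    dir <- if (a >= 0.5) "up" else "down"
    a_or <- max(a, 1 - a)
    bt <- best_threshold(xp, xn, dir)
    data.frame(feature_id = f, auc = a_or, direction = dir,
               accuracy = bt$accuracy, threshold = bt$cut,
               n_pos = sum(pos), n_neg = sum(neg),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auc, out$feature_id), ]
  rownames(out) <- NULL
  out
}

#' Shared significant ontology terms between two enrichment analyses
#'
#' Intersects the terms enriched (q below threshold) in a development arm
#' and a regeneration arm computed over compatible term universes, and
#' attaches per-arm annotation counts for supplied feature sets.
#'
#' @param dev_enrichment,regen_enrichment results of [fisher_enrich()].
#' @param q_thr significance threshold applied to both arms.
#' @param dev_sets,regen_sets optional named lists of feature-id sets to
#'   count per shared term (see [term_annotation_counts()]).
#' @param dev_terms,regen_terms the term collections the two enrichments
#'   were computed over (needed for the counts).
#' @return data.frame of shared terms: `term_id`, `q_dev`, `q_regen`, plus
#'   count columns prefixed `dev.` / `regen.` when sets are supplied.
#' @export
common_signatures <- function(dev_enrichment, regen_enrichment,
                              q_thr = 0.05,
                              dev_sets = NULL, regen_sets = NULL,
                              dev_terms = NULL, regen_terms = NULL) {
  if (!length(intersect(dev_enrichment$term_id, regen_enrichment$term_id)))
    stop("disjoint term universes; enrichments are not comparable")
  shared <- intersect(dev_enrichment$term_id[dev_enrichment$q < q_thr],
                      regen_enrichment$term_id[regen_enrichment$q < q_thr])
  out <- data.frame(
    term_id = shared,
    q_dev = dev_enrichment$q[match(shared, dev_enrichment$term_id)],
    q_regen = regen_enrichment$q[match(shared, regen_enrichment$term_id)],
    stringsAsFactors = FALSE)
  if (length(shared) && !is.null(dev_sets) && !is.null(dev_terms)) {
    cnt <- term_annotation_counts(dev_sets, dev_terms, shared)
    names(cnt)[-1] <- paste0("dev.", names(cnt)[-1])
    out <- merge(out, cnt, by = "term_id", sort = FALSE)
  }
  if (length(shared) && !is.null(regen_sets) && !is.null(regen_terms)) {
    cnt <- term_annotation_counts(regen_sets, regen_terms, shared)
    names(cnt)[-1] <- paste0("regen.", names(cnt)[-1])
    out <- merge(out, cnt, by = "term_id", sort = FALSE)
  }
  out[order(pmax(out$q_dev, out$q_regen)), , drop = FALSE]
}
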