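welch_t_rows <- function(A, B) {
  nA <- ncol(A)
  nB <- ncol(B)
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  vA <- apply(A, 1, stats::var)
  vB <- apply(B, 1, stats::var)
  se2 <- vA / nA + vB / nB
  diff <- mA - mB
  t <- diff / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  # degenerate zero-variance features: no evidence when means agree,
  # certainty when they differ
  zero <- se2 == 0
  t[zero] <- ifelse(diff[zero] == 0, 0, Inf * sign(diff[zero]))
  df[zero] <- nA + nB - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[zero & diff == 0] <- 1
  p[zero & diff != 0] <- 0
  list(diff = diff, t = t, df = df, p = p)
}

#' Two-group differential abundance (volcano statistics)
#'
#' Welch (unequal-variance) t-test per feature on log2 abundances with
#' Benjamini-Hochberg correction. log2 fold change is the difference of
#' group means in log2 space (group A minus group B). A feature is flagged
#' significant under the joint gate `q < q_thr` and
#' `|log2FC| > log2(fc_thr)`.
#'
#' @param mat features x samples matrix in log2 space.
#' @param labels group label per sample (aligned with columns or named by
#'   sample id).
#' @param group_a,group_b the two labels to compare (A - B).
#' @param fc_thr fold-change threshold on the raw scale (default 2).
#' @param q_thr BH-adjusted p threshold (default 0.05).
#' @return data.frame: `feature_id`, `log2FC`, `t`, `df`, `p`, `q`,
#'   `significant`, with the thresholds attached as attributes.
#' @export
two_group_diff <- function(mat, labels, group_a, group_b,
                           fc_thr = 2, q_thr = 0.05) {
  if (abundance_space(mat) == "raw")
    stop("two_group_diff expects log2-space abundances")
  if (!is.null(names(labels))) labels <- labels[colnames(mat)]
  selA <- labels == group_a
  selB <- labels == group_b
  if (sum(selA) < 2 || sum(selB) < 2)
    stop("both groups need >= 2 samples")
  w <- welch_t_rows(mat[, selA, drop = FALSE], mat[, selB, drop = FALSE])
  q <- stats::p.adjust(w$p, method = "BH")
  out <- data.frame(feature_id = rownames(mat), log2FC = w$diff, t = w$t,
                    df = w$df, p = w$p, q = q,
                    significant = q < q_thr & abs(w$diff) > log2(fc_thr),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "thresholds") <- list(fc_thr = fc_thr, q_thr = q_thr,
                                  group_a = group_a, group_b = group_b)
  out
}

#' Linear stage-trend filtering
#'
#' Pearson correlation of each feature's abundance with the developmental
#' stage ordinal; two-sided p from the t distribution with n-2 df, BH q
#' across tested features, and a direction call under the joint gate
#' `p < p_thr` and `|r| > r_thr`. Constant features are excluded with a
#' reason rather than tested.
#'
#' @param mat features x samples matrix.
#' @param stage_ordinal numeric ordinal per sample (E18=0 .. P9=4).
#' @param r_thr correlation magnitude threshold (default 0.7).
#' @param p_thr p-value threshold (default 0.01).
#' @return data.frame: `feature_id`, `r`, `p`, `q`, `direction`
#'   (increasing/decreasing/none). Excluded features are reported in the
#'   `"excluded"` attribute (`feature_id`, `reason`).
#' @export
stage_trend <- function(mat, stage_ordinal, r_thr = 0.7, p_thr = 0.01) {
  if (length(stage_ordinal) != ncol(mat))
    stop("stage_ordinal must have one value per sample")
  if (length(unique(stage_ordinal)) < 2)
    stop("all samples are at a single stage; no trend is estimable")
  n <- ncol(mat)
  sdv <- apply(mat, 1, stats::sd)
  excluded <- data.frame(feature_id = rownames(mat)[sdv == 0],
                         reason = rep("zero variance", sum(sdv == 0)),
                         stringsAsFactors = FALSE)
  keep <- sdv > 0
  r <- drop(stats::cor(t(mat[keep, , drop = FALSE]), stage_ordinal))
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  p[abs(r) == 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  direction <- rep("none", sum(keep))
  hit <- p < p_thr & abs(r) > r_thr
  direction[hit & r > 0] <- "increasing"
  direction[hit & r < 0] <- "decreasing"
  out <- data.frame(feature_id = rownames(mat)[keep], r = r, p = p, q = q,
                    direction = direction, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  attr(out, "thresholds") <- list(r_thr = r_thr, p_thr = p_thr)
  out
}

#' Per-class treatment/timepoint tests against control
#'
#' For each requested (treatment, day) contrast, Welch t-test of every lipid
#' class against the control group, with significance tiers `*` (p < 0.05)
#' and `***` (p < 0.001).
#'
#' @param class_mat classes x samples matrix (log2 recommended).
#' @param meta sample metadata with `sample_id`, `treatment`, `day`.
#' @param contrasts list of `c(treatment, day)` pairs (day may be NA to pool
#'   a treatment's days).
#' @param control label of the control group (default `"control"`).
#' @return data.frame: `class_code`, `treatment`, `day`, `mean_difference`
#'   (contrast minus control), `t`, `p`, `tier`.
#' @export
class_timepoint_tests <- function(class_mat, meta, contrasts,
                                  control = "control") {
  idx <- match(colnames(class_mat), meta$sample_id)
  if (anyNA(idx)) stop("metadata does not cover all samples")
  meta <- meta[idx, , drop = FALSE]
  ctrl <- meta$treatment == control
  if (sum(ctrl) < 2) stop("control group missing or too small")
  rows <- lapply(contrasts, function(ct) {
    trt <- ct[[1]]
    day <- suppressWarnings(as.numeric(ct[[2]]))
    sel <- meta$treatment == trt
    if (!is.na(day)) sel <- sel & !is.na(meta$day) & meta$day == day
    if (sum(sel) < 2)
      stop("contrast group too small or absent: ", trt, " day ", ct[[2]])
    w <- welch_t_rows(class_mat[, sel, drop = FALSE],
                      class_mat[, ctrl, drop = FALSE])
    tier <- ifelse(w$p < 0.001, "***", ifelse(w$p < 0.05, "*", ""))
    data.frame(class_code = rownames(class_mat), treatment = trt, day = day,
               mean_difference = w$diff, t = w$t, p = w$p, tier = tier,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
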