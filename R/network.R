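#' Protein-lipid Pearson correlation matrix
#'
#' Correlates every lipid (species or class) profile with every protein
#' profile over the intersection of their sample ids, returning matched r
#' and p matrices (two-sided, t distribution with n-2 df).
#'
#' @param protein_mat proteins x samples matrix (log2 recommended).
#' @param lipid_mat lipids x samples matrix.
#' @return object of class `pl_correlation`: `r` and `p`
#'   (lipids x proteins), `n_samples`, `constant_features` (profiles with
#'   zero variance, whose entries are NA).
#' @export
pl_correlation <- function(protein_mat, lipid_mat) {
  shared <- intersect(colnames(protein_mat), colnames(lipid_mat))
  if (length(shared) < 3)
    stop("need >= 3 shared samples; found ", length(shared))
  P <- protein_mat[, shared, drop = FALSE]
  L <- lipid_mat[, shared, drop = FALSE]
  const <- c(rownames(P)[apply(P, 1, stats::sd) == 0],
             rownames(L)[apply(L, 1, stats::sd) == 0])
  r <- suppressWarnings(stats::cor(t(L), t(P)))
  n <- length(shared)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) == 1] <- 0
  res <- list(r = r, p = p, n_samples = n, constant_features = const)
  class(res) <- "pl_correlation"
  res
}

#' @export
print.pl_correlation <- function(x, ...) {
  cat("protein-lipid correlation:", nrow(x$r), "lipids x", ncol(x$r),
      "proteins over", x$n_samples, "samples\n")
  invisible(x)
}

#' Dual-requirement protein-protein edge filtering
#'
#' Retains an interaction edge iff (1) both endpoints are in the detected
#' proteome and (2) the endpoints' abundance profiles significantly
#' correlate with each other across the supplied samples (Pearson, two-sided
#' p below `p_thr`, either sign).
#'
#' @param edges data.frame with `protein_a`, `protein_b` (and optionally
#'   `score`).
#' @param mat proteins x samples abundance matrix supplying the profiles.
#' @param detected detected protein ids (default: all rows of `mat`).
#' @param p_thr correlation significance threshold (default 0.01).
#' @param strict error (rather than drop) on edges referencing ids absent
#'   from `mat`.
#' @return the edge table, canonically ordered and de-duplicated, with
#'   columns `r`, `p` and `retained`; dropped-unknown edges are counted in
#'   the `"n_unknown_dropped"` attribute.
#' @export
filter_pp_edges <- function(edges, mat, detected = rownames(mat),
                            p_thr = 0.01, strict = FALSE) {
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  edges <- edges[a != b, , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$protein_a, edges$protein_b)), ,
                 drop = FALSE]
  known <- edges$protein_a %in% rownames(mat) &
    edges$protein_b %in% rownames(mat)
  if (any(!known)) {
    if (strict)
      stop("edge(s) reference unknown protein ids, e.g. ",
           edges$protein_a[!known][1])
    message("dropping ", sum(!known), " edge(s) with unknown endpoints")
  }
  edges <- edges[known, , drop = FALSE]
  n <- ncol(mat)
  r <- p <- numeric(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    x <- mat[edges$protein_a[i], ]
    y <- mat[edges$protein_b[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      r[i] <- NA_real_
      p[i] <- 1
      next
    }
    r[i] <- stats::cor(x, y)
    tstat <- r[i] * sqrt((n - 2) / max(1 - r[i]^2, .Machine$double.eps))
    p[i] <- if (abs(r[i]) == 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  }
  edges$r <- r
  edges$p <- p
  edges$retained <- edges$protein_a %in% detected &
    edges$protein_b %in% detected & p < p_thr
  attr(edges, "n_unknown_dropped") <- sum(!known)
  attr(edges, "p_thr") <- p_thr
  rownames(edges) <- NULL
  edges
}

#' Combine correlations by Fisher r-to-Z-to-r transformation
#'
#' Averages correlations on the `atanh` (Fisher Z) scale and back-transforms
#' with `tanh`. Inputs are clipped to +/-(1 - 1e-6) so the transform stays
#' finite. The result is order-invariant, bounded in (-1, 1), equals the
#' input on singletons and is monotone in each argument.
#'
#' @param r numeric vector of Pearson correlations.
#' @param clip magnitude at which inputs are clipped before `atanh`.
#' @return the combined correlation (scalar).
#' @export
fisher_combine <- function(r, clip = 1 - 1e-6) {
  r <- r[!is.na(r)]
  if (!length(r)) stop("no correlations to combine")
  r <- pmin(pmax(r, -clip), clip)
  tanh(mean(atanh(r)))
}

#' Combine protein-lipid correlations per lipid class
#'
#' For each protein, Fisher-combines its correlations with all species of
#' each lipid class — the per-protein "combined protein-lipid correlation"
#' used to annotate interaction networks.
#'
#' @param plcorr result of [pl_correlation()] at species level.
#' @param annotation data.frame `species_id`, `class_code` covering the rows
#'   of `plcorr$r`.
#' @return proteins x classes matrix of combined correlations.
#' @export
combine_pl_by_class <- function(plcorr, annotation) {
  idx <- match(rownames(plcorr$r), annotation$species_id)
  if (anyNA(idx)) stop("annotation does not cover all lipid species")
  cls <- annotation$class_code[idx]
  out <- sapply(sort(unique(cls)), function(cl)
    apply(plcorr$r[cls == cl, , drop = FALSE], 2, fisher_combine))
  matrix(out, ncol = length(unique(cls)),
         dimnames = list(colnames(plcorr$r), sort(unique(cls))))
}

#' Annotate protein complexes with developmental-stage correlations
#'
#' Attaches each detected member's stage-trend correlation to its complex
#' and summarizes the complex by the Fisher-combined member correlation.
#' Complexes with fewer than two detected members are flagged rather than
#' summarized.
#'
#' @param complexes GMT-style named list (`description`, `members`).
#' @param trend_results data.frame from [stage_trend()] over the detected
#'   proteome.
#' @return object of class `complex_annotation`: data.frame `summary`
#'   (`complex_id`, `n_members`, `n_detected`, `combined_r`, `flagged`) and
#'   list `members` of per-member data.frames (`protein_id`, `r`).
#' @export
annotate_complexes <- function(complexes, trend_results) {
  r_of <- stats::setNames(trend_results$r, trend_results$feature_id)
  members <- lapply(names(complexes), function(id) {
    m <- complexes[[id]]$members
    data.frame(protein_id = m, r = unname(r_of[m]),
               detected = m %in% names(r_of), stringsAsFactors = FALSE)
  })
  names(members) <- names(complexes)
  summary <- do.call(rbind, lapply(names(complexes), function(id) {
    det <- members[[id]][members[[id]]$detected, ]
    flagged <- nrow(det) < 2
    data.frame(complex_id = id,
               n_members = nrow(members[[id]]),
               n_detected = nrow(det),
               combined_r = if (flagged) NA_real_ else
                 fisher_combine(det$r),
               flagged = flagged, stringsAsFactors = FALSE)
  }))
  res <- list(summary = summary, members = members)
  class(res) <- "complex_annotation"
  res
}

#' @export
print.complex_annotation <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
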