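#' Normalize an abundance matrix
#'
#' Column (sample) normalization for intensity tables, with optional log2
#' transform. `total_intensity` rescales every sample to the mean column sum;
#' `median` equalizes column medians; `autoscale` standardizes each feature
#' (row) to zero mean and unit variance, the conventional preprocessing for
#' PCA/PLS/Ward analyses of omics matrices.
#'
#' @param mat features x samples matrix.
#' @param method `"total_intensity"`, `"median"` or `"autoscale"`.
#' @param to_log2 apply `log2(x + pseudocount)` after scaling (ignored for
#'   `autoscale`, which already leaves raw space).
#' @param pseudocount added before the log (default 1).
#' @return normalized matrix with an updated `"space"` attribute.
#' @export
normalize_abundance <- function(mat,
                                method = c("total_intensity", "median",
                                           "autoscale"),
                                to_log2 = FALSE, pseudocount = 1) {
  method <- match.arg(method)
  if (method %in% c("total_intensity", "median") &&
      abundance_space(mat) != "raw")
    stop(method, " normalization requires a raw-space matrix")
  out <- switch(method,
    total_intensity = {
      cs <- colSums(mat)
      if (any(cs == 0))
        stop("zero column sum in sample(s): ",
             paste(colnames(mat)[cs == 0], collapse = ", "))
      sweep(mat, 2, cs, "/") * mean(cs)
    },
    median = {
      cm <- apply(mat, 2, stats::median)
      if (any(cm == 0))
        stop("zero column median in sample(s): ",
             paste(colnames(mat)[cm == 0], collapse = ", "))
      sweep(mat, 2, cm, "/") * mean(cm)
    },
    autoscale = {
      mu <- rowMeans(mat)
      sdv <- apply(mat, 1, stats::sd)
      if (any(sdv == 0))
        stop("constant feature(s) cannot be autoscaled: ",
             paste(utils::head(rownames(mat)[sdv == 0], 5), collapse = ", "))
      sweep(sweep(mat, 1, mu, "-"), 1, sdv, "/")
    })
  attr(out, "space") <- attr(mat, "space")
  if (method == "autoscale") {
    abundance_space(out) <- "autoscaled"
  } else if (to_log2) {
    out <- log2(out + pseudocount)
    abundance_space(out) <- "log2"
  } else {
    abundance_space(out) <- "raw"
  }
  out
}

#' Per-group coefficients of variation
#'
#' Computes CV = sd/mean (n-1 standard deviation) per feature within each
#' sample group on raw intensities, the standard replicate-reproducibility
#' check for MS data, and compares within-group against between-group
#' dispersion.
#'
#' @param mat features x samples matrix in raw space.
#' @param grouping factor/character of group per sample (aligned with
#'   columns, or named by sample id).
#' @return object of class `cv_report`: list with `cv` (features x groups
#'   matrix), `group_median`, `median_cv`, `overall_cv` (per-feature CV over
#'   all samples pooled), `within_less_than_between` (fraction of features
#'   whose mean within-group CV is below their pooled across-group CV).
#' @export
compute_cv <- function(mat, grouping) {
  if (abundance_space(mat) != "raw")
    stop("CV is defined on raw intensities; got a ", abundance_space(mat),
         "-space matrix")
  if (!is.null(names(grouping)))
    grouping <- grouping[colnames(mat)]
  grouping <- as.factor(grouping)
  if (length(grouping) != ncol(mat))
    stop("grouping length does not match sample count")
  sizes <- table(grouping)
  if (any(sizes < 2))
    stop("every group needs >= 2 samples; offending: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  groups <- levels(grouping)
  cv <- vapply(groups, function(g) {
    sub <- mat[, grouping == g, drop = FALSE]
    apply(sub, 1, stats::sd) / rowMeans(sub)
  }, numeric(nrow(mat)))
  cv <- matrix(cv, nrow = nrow(mat),
               dimnames = list(rownames(mat), groups))
  # inter-group dispersion: CV over all samples pooled; replicate noise
  # alone makes it match the within-group CV, group structure inflates it
  overall_cv <- apply(mat, 1, stats::sd) / rowMeans(mat)
  res <- list(
    cv = cv,
    group_median = apply(cv, 2, stats::median),
    median_cv = stats::median(cv),
    overall_cv = overall_cv,
    within_less_than_between = mean(rowMeans(cv) < overall_cv)
  )
  class(res) <- "cv_report"
  res
}

#' @export
print.cv_report <- function(x, ...) {
  cat("CV report:", nrow(x$cv), "features x", ncol(x$cv), "groups\n")
  cat(sprintf("  median within-group CV: %.4f (%.1f%%)\n",
              x$median_cv, 100 * x$median_cv))
  cat(sprintf("  within < between for %.1f%% of features\n",
              100 * x$within_less_than_between))
  invisible(x)
}

known_lipid_classes <- c(
  "PC", "PE", "PS", "PI", "PG", "PA", "Cer", "SM", "CerG1", "TG", "DG",
  "MG", "ChE", "ZyE", "So", "CL", "LPC", "LPE", "LPS", "LPG", "LPI",
  "SQDG")

#' Parse lipid shorthand names
#'
#' Parses `CLASS(chain[/chain...])` shorthand, e.g. `Cer(d18:1/24:0)` or
#' `TG(16:0/18:1/18:2)`. Chains are `carbons:double_bonds` with an optional
#' `d`/`t` long-chain-base hydroxylation prefix; 1-4 chains are accepted.
#' Unknown class codes pass through verbatim and are flagged rather than
#' rejected.
#'
#' @param names character vector of species names.
#' @return data.frame with one row per species: `species_id`, `class_code`,
#'   `n_chains`, `total_carbons`, `total_double_bonds`, `known_class`, and a
#'   list-column `chains` of per-chain data.frames
#'   (`carbons`, `double_bonds`, `prefix`).
#' @export
parse_lipid_name <- function(names) {
  chain_re <- "[dt]?[0-9]+:[0-9]+"
  full_re <- sprintf("^([A-Za-z0-9]+)\\((%s(?:/%s){0,3})\\)$",
                     chain_re, chain_re)
  ok <- grepl(full_re, names)
  if (any(!ok))
    stop("unparseable lipid name(s): ",
         paste(utils::head(names[!ok], 5), collapse = ", "))
  class_code <- sub(full_re, "\\1", names)
  body <- sub(full_re, "\\2", names)
  chains <- lapply(strsplit(body, "/", fixed = TRUE), function(ch) {
    prefix <- ifelse(grepl("^[dt]", ch), substr(ch, 1, 1), "none")
    core <- sub("^[dt]", "", ch)
    parts <- strsplit(core, ":", fixed = TRUE)
    data.frame(
      carbons = as.integer(vapply(parts, `[`, character(1), 1L)),
      double_bonds = as.integer(vapply(parts, `[`, character(1), 2L)),
      prefix = prefix,
      stringsAsFactors = FALSE)
  })
  out <- data.frame(
    species_id = names,
    class_code = class_code,
    n_chains = vapply(chains, nrow, integer(1)),
    total_carbons = vapply(chains, function(d) sum(d$carbons), integer(1)),
    total_double_bonds = vapply(chains, function(d) sum(d$double_bonds),
                                integer(1)),
    known_class = class_code %in% known_lipid_classes,
    stringsAsFactors = FALSE)
  out$chains <- chains
  out
}

#' Format a lipid annotation back to shorthand
#'
#' Inverse of [parse_lipid_name()]; `parse_lipid_name(format_lipid_name(a))`
#' reproduces `a` for any annotation produced by the parser.
#'
#' @param annotation data.frame as returned by [parse_lipid_name()].
#' @return character vector of species names.
#' @export
format_lipid_name <- function(annotation) {
  vapply(seq_len(nrow(annotation)), function(i) {
    ch <- annotation$chains[[i]]
    pre <- ifelse(ch$prefix == "none", "", ch$prefix)
    body <- paste0(pre, ch$carbons, ":", ch$double_bonds, collapse = "/")
    paste0(annotation$class_code[i], "(", body, ")")
  }, character(1))
}

#' Aggregate lipid species into class abundances
#'
#' Class abundance per sample is the sum of its member species' raw
#' intensities, so per-sample totals are conserved exactly.
#'
#' @param mat species x samples matrix in raw space.
#' @param annotation data.frame with `species_id` and `class_code` covering
#'   every row of `mat` (e.g. from [parse_lipid_name()]).
#' @return classes x samples matrix in raw space.
#' @export
aggregate_lipid_classes <- function(mat, annotation) {
  if (abundance_space(mat) != "raw")
    stop("class aggregation sums raw intensities; got ",
         abundance_space(mat), " space")
  idx <- match(rownames(mat), annotation$species_id)
  if (anyNA(idx))
    stop("unannotated species: ",
         paste(utils::head(rownames(mat)[is.na(idx)], 5), collapse = ", "))
  cls <- annotation$class_code[idx]
  out <- rowsum(mat, group = cls)
  out <- out[order(rownames(out)), , drop = FALSE]
  abundance_space(out) <- "raw"
  out
}
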