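#' @title Abundance matrix I/O and space flags
#' @name abundance-io
#' @description
#' Abundance matrices are plain numeric matrices with features as rows and
#' samples as columns, carrying a `"space"` attribute (`"raw"`, `"log2"` or
#' `"autoscaled"`). On disk they are TSV files whose first column is
#' `feature_id`; lines starting with `#` are treated as comments (used for
#' provenance headers) and CRLF line endings are tolerated.
NULL

#' Get or set the measurement space of an abundance matrix
#'
#' @param mat numeric matrix, features x samples.
#' @return `"raw"`, `"log2"` or `"autoscaled"`; a matrix with no flag is
#'   assumed to be in raw intensity space.
#' @export
abundance_space <- function(mat) {
  sp <- attr(mat, "space")
  if (is.null(sp)) "raw" else sp
}

#' @rdname abundance_space
#' @param value new space flag.
#' @export
`abundance_space<-` <- function(mat, value) {
  value <- match.arg(value, c("raw", "log2", "autoscaled"))
  attr(mat, "space") <- value
  mat
}

new_abundance_matrix <- function(values, feature_ids, sample_ids,
                                 space = "raw") {
  if (anyDuplicated(feature_ids))
    stop("duplicate feature ids: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  m <- matrix(values, nrow = length(feature_ids),
              dimnames = list(feature_ids, sample_ids))
  if (space == "raw" && any(m < 0))
    stop("raw-space abundance matrix must be non-negative")
  abundance_space(m) <- space
  m
}

#' Read an abundance matrix from TSV
#'
#' @param path TSV file, first column `feature_id`, remaining columns samples.
#' @param space space flag to attach (`"raw"` by default).
#' @return numeric matrix with a `"space"` attribute.
#' @export
read_abundance_tsv <- function(path, space = "raw") {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  new_abundance_matrix(m, rownames(m), colnames(m), space = space)
}

#' Write an abundance matrix to TSV
#'
#' @param mat features x samples matrix.
#' @param path output file.
#' @param header optional character vector of provenance lines, written as
#'   `#`-prefixed comments before the table.
#' @export
write_abundance_tsv <- function(mat, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header))
    writeLines(paste0("# ", header), con)
  df <- data.frame(feature_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Metadata is one row per sample with a `sample_id` column plus any of
#' `fraction`, `stage`, `replicate`, `treatment`, `day`, `batch`.
#'
#' @param path TSV file.
#' @return data.frame with `sample_id` first.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("metadata lacks a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in metadata")
  df
}

#' @rdname read_sample_meta
#' @param meta data.frame of sample metadata.
#' @param header optional provenance comment lines.
#' @export
write_sample_meta <- function(meta, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene/lipid set collections in GMT format
#'
#' One set per line: `name TAB description TAB member TAB member ...`.
#'
#' @param path GMT file.
#' @return named list of term sets; each element is a list with `description`
#'   and `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[parts[1]]] <- list(description = parts[2], members = parts[-(1:2)])
  }
  if (anyDuplicated(names(out))) stop("duplicate term ids in GMT")
  out
}

#' @rdname read_gmt
#' @param terms named list as returned by [read_gmt()].
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    t <- terms[[id]]
    paste(c(id, t$description, t$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a protein-protein edge list
#'
#' STRING-like TSV with columns `protein_a`, `protein_b`, `score`.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_edge_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("protein_a", "protein_b", "score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("edge table lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @rdname read_edge_tsv
#' @param edges data.frame with `protein_a`, `protein_b`, `score`.
#' @export
write_edge_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
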