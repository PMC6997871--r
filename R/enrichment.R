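#' Lipid class to ontology-style term table
#'
#' Static mapping from lipid class codes to biophysical/chemical membrane
#' property terms (storage vs membrane lipids, headgroup charge, lateral
#' diffusion, bilayer thickness, intrinsic curvature, transition
#' temperature). This is a packaged stand-in table for a lipid ontology;
#' it encodes the class-level associations the analyses probe.
#'
#' @return data.frame with columns `term_id`, `description`, `class_code`.
#' @export
lipid_class_term_table <- function() {
  map <- list(
    lipid_storage = list("lipid storage",
                         c("TG", "DG", "MG", "ChE", "ZyE")),
    lipid_droplet = list("lipid droplet", c("TG", "DG", "MG", "ChE")),
    triacylglycerol = list("triacylglycerol", "TG"),
    glycerolipid = list("glycerolipid", c("TG", "DG", "MG")),
    neutral_headgroup = list("headgroups with neutral charge",
                             c("TG", "DG", "MG", "ChE", "ZyE", "Cer")),
    sterol_lipids = list("sterol lipids", c("ChE", "ZyE")),
    sphingolipid = list("sphingolipid", c("Cer", "SM", "CerG1", "So")),
    glycerophospholipid = list("glycerophospholipid",
                               c("PC", "PE", "PS", "PI", "PG", "PA", "CL")),
    lysolipid = list("lysolipid", c("LPC", "LPE", "LPS", "LPG", "LPI")),
    membrane = list("membrane component",
                    c("PC", "PE", "PS", "PI", "PG", "PA", "CL", "SM",
                      "CerG1", "LPC", "LPS", "LPG")),
    low_lateral_diffusion = list("low lateral diffusion",
                                 c("TG", "DG", "MG", "ChE", "ZyE", "So",
                                   "Cer", "SM")),
    high_lateral_diffusion = list("high lateral diffusion",
                                  c("LPC", "LPS", "LPG", "CerG1")),
    high_bilayer_thickness = list("high bilayer thickness",
                                  c("ChE", "ZyE", "TG", "DG", "MG", "SM")),
    low_bilayer_thickness = list("below average bilayer thickness",
                                 c("LPC", "LPS", "LPG", "CerG1")),
    positive_intrinsic_curvature = list("positive intrinsic curvature",
                                        c("TG", "DG", "MG", "ChE", "ZyE",
                                          "So")),
    negative_intrinsic_curvature = list("negative intrinsic curvature",
                                        c("LPC", "LPS", "LPG", "CerG1")),
    high_transition_temperature = list("above average transition temperature",
                                       c("ChE", "ZyE", "TG", "DG", "MG",
                                         "Cer", "SM")),
    low_transition_temperature = list("below average transition temperature",
                                      c("LPC", "LPS", "LPG", "CerG1")))
  do.call(rbind, lapply(names(map), function(id)
    data.frame(term_id = id, description = map[[id]][[1]],
               class_code = map[[id]][[2]], stringsAsFactors = FALSE)))
}

#' Build species-level term sets from a lipid annotation
#'
#' Expands the class-level table of [lipid_class_term_table()] to species
#' membership, and adds unsaturation terms computed from the parsed chain
#' composition (`fa_saturated`, `fa_2_double_bonds`,
#' `fa_gt3_double_bonds`) when the annotation carries
#' `total_double_bonds`.
#'
#' @param annotation data.frame with `species_id`, `class_code` and
#'   optionally `total_double_bonds` (see [parse_lipid_name()]).
#' @return GMT-style named list: each term is a list with `description` and
#'   `members` (species ids). Terms with no members are dropped.
#' @export
build_class_term_sets <- function(annotation) {
  tab <- lipid_class_term_table()
  terms <- list()
  for (id in unique(tab$term_id)) {
    sub <- tab[tab$term_id == id, ]
    members <- annotation$species_id[annotation$class_code %in%
                                       sub$class_code]
    if (length(members))
      terms[[id]] <- list(description = sub$description[1], members = members)
  }
  if ("total_double_bonds" %in% names(annotation)) {
    db <- annotation$total_double_bonds
    extra <- list(
      fa_saturated = list("fully saturated fatty acids", db == 0),
      fa_2_double_bonds = list("fatty acids with 2 double bonds", db == 2),
      fa_gt3_double_bonds = list("fatty acids with more than 3 double bonds",
                                 db > 3))
    for (id in names(extra)) {
      members <- annotation$species_id[extra[[id]][[2]]]
      if (length(members))
        terms[[id]] <- list(description = extra[[id]][[1]],
                            members = members)
    }
  }
  terms
}

#' Fisher exact term enrichment
#'
#' One-sided hypergeometric (upper-tail) enrichment of a selected feature
#' set against a detection background, per term, with Benjamini-Hochberg
#' correction across terms. The complementary (depletion) tail is also
#' reported.
#'
#' @param selected character vector of selected feature ids (subset of
#'   `background`).
#' @param background character vector: the detected-feature universe.
#' @param terms GMT-style named list (`description`, `members`).
#' @param q_thr BH-adjusted significance threshold for the `enriched` flag.
#' @return data.frame per term: `term_id`, `description`, `overlap` (k),
#'   `selected_n` (n), `term_size` (K, after intersection with the
#'   background), `background_n` (N), `odds_ratio`, `p`, `p_deplete`, `q`,
#'   `enriched`.
#' @export
fisher_enrich <- function(selected, background, terms, q_thr = 0.05) {
  selected <- unique(selected)
  background <- unique(background)
  if (!length(selected)) stop("empty selection")
  if (!all(selected %in% background))
    stop("selected features must be a subset of the background")
  N <- length(background)
  n <- length(selected)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(terms[[id]]$members, background)
    K <- length(members)
    k <- length(intersect(members, selected))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    p_dep <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(term_id = id, description = terms[[id]]$description,
               overlap = k, selected_n = n, term_size = K, background_n = N,
               odds_ratio = or, p = p, p_deplete = p_dep,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$q < q_thr
  out[order(out$p), ]
}

#' Count term annotations within labeled feature sets
#'
#' For each significantly enriched term, counts how many members of each
#' labeled feature set are annotated to it — the per-term annotation bar
#' quantities used to compare early vs late development or development vs
#' regeneration.
#'
#' @param feature_sets named list of feature-id vectors.
#' @param terms GMT-style named list.
#' @param significant_terms term ids to count (must exist in `terms`).
#' @return data.frame: `term_id`, one count column per feature set.
#' @export
term_annotation_counts <- function(feature_sets, terms, significant_terms) {
  unknown <- setdiff(significant_terms, names(terms))
  if (length(unknown))
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  counts <- sapply(feature_sets, function(set)
    vapply(significant_terms, function(id)
      length(intersect(terms[[id]]$members, set)), integer(1)))
  counts <- matrix(counts, nrow = length(significant_terms),
                   dimnames = list(significant_terms, names(feature_sets)))
  data.frame(term_id = significant_terms, counts, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
}
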