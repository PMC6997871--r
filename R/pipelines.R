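#' Configuration for the pipeline drivers
#'
#' A run is driven either by a simulate block (generator config + seed) or
#' by input file paths; thresholds default to the analysis gates
#' (fold change 2, q 0.05, trend r 0.7, trend/edge p 0.01).
#'
#' @param simulate list with `config` (generator settings) and `seed`, or
#'   NULL when reading from files.
#' @param inputs named list of file paths (`proteins`, `lipids`, `meta`,
#'   `edges`, `complexes`, `terms`), or NULL when simulating.
#' @param outdir output directory (created if needed); NULL returns results
#'   without writing.
#' @param fc_thr,q_thr,r_thr,p_thr analysis thresholds.
#' @param pls_components,cv_folds PLS stage-model settings.
#' @param normalization column-normalization method before log2 (growth-cone
#'   pipeline).
#' @param regen_normalization normalization for the regeneration pipeline;
#'   defaults to `"median"` because regeneration shifts whole lipid classes
#'   several-fold, which breaks the constant-column-sum assumption behind
#'   total-intensity scaling, while the column median is robust to it.
#' @return config list for [run_gc_pipeline()] / [run_regen_pipeline()].
#' @export
pipeline_config <- function(simulate = list(config = NULL, seed = 1),
                            inputs = NULL, outdir = NULL,
                            fc_thr = 2, q_thr = 0.05, r_thr = 0.7,
                            p_thr = 0.01, pls_components = 2, cv_folds = 7,
                            normalization = "total_intensity",
                            regen_normalization = "median") {
  if (is.null(simulate) == is.null(inputs))
    stop("configuration error: provide exactly one of simulate / inputs")
  stopifnot(fc_thr >= 1, q_thr >= 0, q_thr <= 1, r_thr >= 0, r_thr <= 1,
            p_thr >= 0, p_thr <= 1)
  as.list(environment())
}

provenance <- function(config, seed) {
  c(paste0("generated_by: gcmultiomics ",
           as.character(utils::packageVersion("gcmultiomics"))),
    paste0("seed: ", seed),
    paste0("config_hash: ", sum(utils::object.size(config))))
}

write_result_tsv <- function(df, dir, name, header) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  con <- file(path, "w")
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Run the growth-cone development pipeline
#'
#' Orchestrates preprocessing (normalization, CV QC), multivariate analysis
#' (PCA, ASCA, PLS stage model, Ward clustering, sample correlations,
#' k-means early/late split of the GCM lipidome), differential analysis
#' (GCM-vs-GCP volcano, per-fraction stage trends, lipid class trends),
#' lipid term enrichment of the early/late species signatures, and the
#' protein-lipid correlation network (edge filtering, Fisher-combined
#' per-class correlations, complex annotation). Writes result tables with
#' provenance headers when `config$outdir` is set.
#'
#' @param config from [pipeline_config()].
#' @return invisibly, a list of all stage results plus a `report` (sample
#'   counts, seeds, thresholds, warnings).
#' @export
run_gc_pipeline <- function(config = pipeline_config()) {
  seed <- if (!is.null(config$simulate)) config$simulate$seed else NA
  if (!is.null(config$simulate)) {
    gen_cfg <- config$simulate$config
    if (is.null(gen_cfg)) gen_cfg <- gc_sim_config()
    bundle <- generate_gc_multiomic(gen_cfg, seed = seed)
    knowledge <- generate_knowledge_tables(bundle, seed = seed)
  } else {
    inp <- config$inputs
    bundle <- list(
      proteins = read_abundance_tsv(inp$proteins),
      lipids = read_abundance_tsv(inp$lipids),
      meta = read_sample_meta(inp$meta),
      truth = NULL)
    knowledge <- list(
      edges = if (!is.null(inp$edges)) read_edge_tsv(inp$edges),
      complexes = if (!is.null(inp$complexes)) read_gmt(inp$complexes),
      terms = if (!is.null(inp$terms)) read_gmt(inp$terms))
  }
  meta <- bundle$meta
  ord <- meta$stage_ordinal
  if (is.null(ord)) ord <- match(meta$stage, GC_STAGES) - 1

  ## preprocess
  prot_log2 <- normalize_abundance(bundle$proteins, config$normalization,
                                   to_log2 = TRUE)
  lip_log2 <- normalize_abundance(bundle$lipids, config$normalization,
                                  to_log2 = TRUE)
  cell <- paste(meta$fraction, meta$stage, sep = ".")
  cv_prot <- compute_cv(bundle$proteins, stats::setNames(cell,
                                                         meta$sample_id))
  cv_lip <- compute_cv(bundle$lipids, stats::setNames(cell, meta$sample_id))
  annotation <- parse_lipid_name(rownames(bundle$lipids))
  class_mat <- aggregate_lipid_classes(bundle$lipids, annotation)
  class_log2 <- log2(class_mat)
  abundance_space(class_log2) <- "log2"

  ## multivariate
  prot_scaled <- normalize_abundance(prot_log2, "autoscale")
  pca_all <- run_pca(prot_scaled, n_components = min(5, ncol(prot_scaled)))
  asca <- run_asca(prot_log2, meta, factors = c("fraction", "stage"))
  pls <- pls_stage_model(prot_log2, ord, ncomp = config$pls_components,
                         cv_folds = config$cv_folds)
  ward <- hierarchical_cluster(prot_scaled, k = 2, labels = meta$fraction)
  sample_cor <- sample_correlation_matrix(prot_log2)
  gcm <- meta$fraction == "GCM"
  lip_gcm_scaled <- normalize_abundance(
    lip_log2[, gcm, drop = FALSE], "autoscale")
  km <- kmeans_split(lip_gcm_scaled, ord[gcm],
                     seed = if (is.na(seed)) 1 else seed)

  ## differential
  volcano <- two_group_diff(prot_log2, stats::setNames(meta$fraction,
                                                       meta$sample_id),
                            "GCM", "GCP", fc_thr = config$fc_thr,
                            q_thr = config$q_thr)
  trends <- lapply(stats::setNames(GC_FRACTIONS, GC_FRACTIONS),
                   function(fr) {
    sel <- meta$fraction == fr
    stage_trend(prot_log2[, sel, drop = FALSE], ord[sel],
                r_thr = config$r_thr, p_thr = config$p_thr)
  })
  class_trend_gcm <- stage_trend(class_log2[, gcm, drop = FALSE], ord[gcm],
                                 r_thr = config$r_thr, p_thr = config$p_thr)

  ## enrichment of the early/late species signatures against lipid terms
  species_trend <- stage_trend(lip_log2[, gcm, drop = FALSE], ord[gcm],
                               r_thr = config$r_thr, p_thr = config$p_thr)
  early_species <- species_trend$feature_id[species_trend$direction ==
                                              "decreasing"]
  late_species <- species_trend$feature_id[species_trend$direction ==
                                             "increasing"]
  enr <- NULL
  if (!is.null(knowledge$terms) && length(early_species)) {
    enr <- list(
      early = fisher_enrich(early_species, rownames(bundle$lipids),
                            knowledge$terms, q_thr = config$q_thr),
      late = if (length(late_species))
        fisher_enrich(late_species, rownames(bundle$lipids),
                      knowledge$terms, q_thr = config$q_thr))
  }

  ## network
  plcorr <- pl_correlation(prot_log2[, gcm, drop = FALSE],
                           lip_log2[, gcm, drop = FALSE])
  combined_by_class <- combine_pl_by_class(plcorr, annotation)
  net <- NULL
  if (!is.null(knowledge$edges)) {
    net <- filter_pp_edges(knowledge$edges,
                           prot_log2[, gcm, drop = FALSE],
                           detected = rownames(bundle$proteins),
                           p_thr = config$p_thr)
  }
  cplx <- NULL
  if (!is.null(knowledge$complexes)) {
    cplx <- annotate_complexes(knowledge$complexes, trends$GCM)
  }

  report <- list(
    n_samples = nrow(meta),
    n_samples_per_fraction = as.list(table(meta$fraction)),
    n_proteins = nrow(bundle$proteins),
    n_lipid_species = nrow(bundle$lipids),
    seed = seed,
    thresholds = config[c("fc_thr", "q_thr", "r_thr", "p_thr")],
    normalization = config$normalization,
    median_cv_protein = cv_prot$median_cv,
    median_cv_lipid = cv_lip$median_cv,
    asca_fraction_pc1_percent = asca$effect_pca$fraction$pc1_percent,
    pls = list(R2 = pls$R2, Q2 = pls$Q2, accuracy = pls$accuracy),
    ward_fraction_purity = ward$purity,
    n_volcano_significant = sum(volcano$significant))

  results <- list(bundle = bundle, knowledge = knowledge,
                  prot_log2 = prot_log2, lip_log2 = lip_log2,
                  class_log2 = class_log2,
                  cv = list(protein = cv_prot, lipid = cv_lip),
                  annotation = annotation, pca = pca_all, asca = asca,
                  pls = pls, ward = ward, sample_cor = sample_cor,
                  kmeans = km, volcano = volcano, trends = trends,
                  class_trend_gcm = class_trend_gcm,
                  species_trend = species_trend,
                  early_species = early_species,
                  late_species = late_species,
                  enrichment = enr, pl_correlation = plcorr,
                  pl_combined_by_class = combined_by_class,
                  edges = net, complexes = cplx, report = report)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance(config, seed)
    write_result_tsv(volcano, config$outdir, "volcano_gcm_vs_gcp.tsv", hdr)
    for (fr in names(trends))
      write_result_tsv(trends[[fr]], config$outdir,
                       paste0("stage_trend_", fr, ".tsv"), hdr)
    write_result_tsv(class_trend_gcm, config$outdir,
                     "class_stage_trend_gcm.tsv", hdr)
    write_result_tsv(
      data.frame(feature_id = names(pls$vip), vip = pls$vip,
                 row.names = NULL), config$outdir, "pls_vip.tsv", hdr)
    if (!is.null(net))
      write_result_tsv(net, config$outdir, "pp_edges_filtered.tsv", hdr)
    if (!is.null(cplx))
      write_result_tsv(cplx$summary, config$outdir,
                       "complex_summary.tsv", hdr)
    if (!is.null(enr)) {
      write_result_tsv(enr$early, config$outdir,
                       "enrichment_early_species.tsv", hdr)
      if (!is.null(enr$late))
        write_result_tsv(enr$late, config$outdir,
                         "enrichment_late_species.tsv", hdr)
    }
    jsonlite::write_json(report, file.path(config$outdir,
                                           "gc_run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}

#' Run the optic-nerve regeneration pipeline
#'
#' Orchestrates normalization, empirical-Bayes batch correction of the
#' merged regeneration lipidome, the crush-vs-control volcano, per-class
#' treatment/timepoint tests, ROC ranking of species for regeneration vs
#' control, term enrichment of the regeneration-elevated species, and (when
#' a development arm's enrichment is supplied) the shared-signature
#' intersection.
#'
#' @param config from [pipeline_config()].
#' @param dev_enrichment optional [fisher_enrich()] result from the GC
#'   development arm (its `early` signature) for [common_signatures()].
#' @param dev_terms,dev_sets term collection and labeled feature sets of the
#'   development arm, passed through to the shared-signature counts.
#' @return invisibly, a list of stage results plus a `report`.
#' @export
run_regen_pipeline <- function(config = pipeline_config(
                                 simulate = list(config = NULL, seed = 42)),
                               dev_enrichment = NULL, dev_terms = NULL,
                               dev_sets = NULL) {
  seed <- if (!is.null(config$simulate)) config$simulate$seed else NA
  if (!is.null(config$simulate)) {
    gen_cfg <- config$simulate$config
    if (is.null(gen_cfg)) gen_cfg <- regen_sim_config()
    bundle <- generate_regen_lipidome(gen_cfg, seed = seed)
  } else {
    inp <- config$inputs
    bundle <- list(lipids = read_abundance_tsv(inp$lipids),
                   meta = read_sample_meta(inp$meta), truth = NULL)
  }
  meta <- bundle$meta
  if (is.null(meta$batch)) stop("regeneration metadata lacks batch labels")

  lip_log2 <- normalize_abundance(bundle$lipids, config$regen_normalization,
                                  to_log2 = TRUE)
  cb <- combat_adjust(lip_log2, stats::setNames(meta$batch, meta$sample_id))
  adjusted <- cb$adjusted

  crush_diff <- two_group_diff(
    adjusted, stats::setNames(meta$treatment, meta$sample_id),
    "crush_saline", "control", fc_thr = config$fc_thr,
    q_thr = config$q_thr)

  annotation <- parse_lipid_name(rownames(bundle$lipids))
  class_mat <- aggregate_lipid_classes(bundle$lipids, annotation)
  class_log2 <- log2(class_mat)
  abundance_space(class_log2) <- "log2"
  class_adj <- combat_adjust(class_log2,
                             stats::setNames(meta$batch,
                                             meta$sample_id))$adjusted
  contrasts <- list(c("wnt3a", 7), c("wnt3a", 15),
                    c("zymosan", 7), c("zymosan", 15))
  class_tests <- class_timepoint_tests(class_adj, meta, contrasts)

  is_regen <- meta$treatment %in% c("wnt3a", "zymosan")
  roc_labels <- ifelse(is_regen, "regeneration",
                       ifelse(meta$treatment == "control", "control", NA))
  roc_mat <- adjusted[, !is.na(roc_labels), drop = FALSE]
  abundance_space(roc_mat) <- "log2"
  roc <- roc_rank(roc_mat, stats::setNames(roc_labels, meta$sample_id))

  regen_diff <- two_group_diff(
    roc_mat,
    stats::setNames(roc_labels[!is.na(roc_labels)],
                    meta$sample_id[!is.na(roc_labels)]),
    "regeneration", "control", fc_thr = config$fc_thr,
    q_thr = config$q_thr)
  ## the ontology signature keeps all significantly elevated species; the
  ## fold-change gate belongs to the volcano, not to term enrichment
  up_species <- regen_diff$feature_id[regen_diff$q < config$q_thr &
                                        regen_diff$log2FC > 0]
  terms <- build_class_term_sets(annotation)
  regen_enr <- if (length(up_species))
    fisher_enrich(up_species, rownames(bundle$lipids), terms,
                  q_thr = config$q_thr)
  shared <- NULL
  if (!is.null(dev_enrichment) && !is.null(regen_enr)) {
    shared <- common_signatures(
      dev_enrichment, regen_enr, q_thr = config$q_thr,
      dev_sets = dev_sets, regen_sets = list(regeneration = up_species),
      dev_terms = dev_terms, regen_terms = terms)
  }

  report <- list(
    n_samples = nrow(meta),
    groups = as.list(table(meta$treatment)),
    seed = seed,
    thresholds = config[c("fc_thr", "q_thr", "r_thr", "p_thr")],
    combat = list(iterations = cb$adjustment$iterations,
                  converged = cb$adjustment$converged),
    n_crush_significant = sum(crush_diff$significant),
    top_roc = roc$feature_id[1],
    top_auc = roc$auc[1])

  results <- list(bundle = bundle, lip_log2 = lip_log2, adjusted = adjusted,
                  combat = cb, crush_diff = crush_diff,
                  class_tests = class_tests, roc = roc,
                  regen_diff = regen_diff, up_species = up_species,
                  terms = terms, enrichment = regen_enr, shared = shared,
                  report = report)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance(config, seed)
    write_result_tsv(crush_diff, config$outdir,
                     "crush_vs_control_volcano.tsv", hdr)
    write_result_tsv(class_tests, config$outdir, "class_timepoint_tests.tsv",
                     hdr)
    write_result_tsv(roc, config$outdir, "roc_ranking.tsv", hdr)
    if (!is.null(regen_enr))
      write_result_tsv(regen_enr, config$outdir,
                       "enrichment_regeneration.tsv", hdr)
    if (!is.null(shared))
      write_result_tsv(shared, config$outdir, "shared_signatures.tsv", hdr)
    write_abundance_tsv(adjusted, file.path(config$outdir,
                                            "lipids_batch_adjusted.tsv"),
                        header = hdr)
    jsonlite::write_json(report, file.path(config$outdir,
                                           "regen_run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(results)
}
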