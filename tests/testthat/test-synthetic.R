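test_that("growth-cone bundle reproduces the study design", {
  b <- default_gc_bundle()
  expect_equal(nrow(b$meta), 58)
  expect_equal(as.vector(table(b$meta$fraction)), c(29, 29))
  counts <- table(b$meta$fraction, b$meta$stage)
  expect_equal(counts["GCM", "E18"], 5)
  expect_equal(counts["GCP", "P9"], 5)
  expect_true(all(counts[counts != 5] == 6))
  expect_identical(colnames(b$proteins), b$meta$sample_id)
  expect_identical(colnames(b$lipids), b$meta$sample_id)
  expect_equal(nrow(b$proteins), 600)
  expect_equal(nrow(b$lipids), 200)
})

test_that("generation is deterministic given (config, seed)", {
  b1 <- generate_gc_multiomic(gc_sim_config(), seed = 11)
  b2 <- generate_gc_multiomic(gc_sim_config(), seed = 11)
  expect_identical(b1, b2)
  b3 <- generate_gc_multiomic(gc_sim_config(), seed = 12)
  expect_false(identical(b1$proteins, b3$proteins))
  r1 <- generate_regen_lipidome(regen_sim_config(), seed = 5)
  r2 <- generate_regen_lipidome(regen_sim_config(), seed = 5)
  expect_identical(r1, r2)
  # determinism survives serialization to disk
  p1 <- tempfile(fileext = ".tsv")
  p2 <- tempfile(fileext = ".tsv")
  write_abundance_tsv(b1$proteins, p1)
  write_abundance_tsv(b2$proteins, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("truth references only existing features and disjoint class sets", {
  b <- default_gc_bundle()
  tr <- b$truth
  expect_true(all(c(tr$trend_proteins_pos, tr$trend_proteins_neg,
                    tr$fraction_effect_features,
                    tr$pl_coupled_pairs$protein_id) %in%
                    rownames(b$proteins)))
  expect_true(all(tr$pl_coupled_pairs$lipid_class %in%
                    tr$lipid_annotation$class_code))
  expect_length(intersect(tr$early_classes, tr$late_classes), 0)
  expect_gt(tr$noise_cv, 0)
  expect_length(intersect(tr$trend_proteins_pos, tr$trend_proteins_neg), 0)
})

test_that("noise calibration hits the target CV band", {
  b <- default_gc_bundle()
  cell <- paste(b$meta$fraction, b$meta$stage, sep = ".")
  grouping <- stats::setNames(cell, b$meta$sample_id)
  for (m in list(b$proteins, b$lipids)) {
    cv <- compute_cv(m, grouping)
    expect_gte(cv$median_cv, 0.06)
    expect_lte(cv$median_cv, 0.10)
    expect_gt(cv$within_less_than_between, 0.5)
  }
})

test_that("zero-effect data yield no volcano discoveries in >= 95% of seeds", {
  cfg <- gc_sim_config(trend_slope_sd = 0, fraction_shift_log2 = 0,
                       class_switch_sd = 0, coupling_sd = 0)
  clean <- 0
  for (s in 1:100) {
    b <- generate_gc_multiomic(cfg, seed = 1000 + s)
    lg <- normalize_abundance(b$proteins, "total_intensity", to_log2 = TRUE)
    d <- two_group_diff(lg, stats::setNames(b$meta$fraction,
                                            b$meta$sample_id),
                        "GCM", "GCP")
    clean <- clean + (sum(d$significant) == 0)
  }
  expect_gte(clean, 95)
})

test_that("regeneration bundle reproduces the study design", {
  b <- default_regen_bundle()
  expect_equal(nrow(b$meta), 53)
  tab <- table(b$meta$treatment)
  expect_equal(as.vector(tab[c("control", "crush_saline", "wnt3a",
                               "zymosan")]), c(21, 16, 6, 10))
  expect_true(b$truth$marker_species %in% rownames(b$lipids))
  expect_true(all(b$truth$crush_depleted_species %in% rownames(b$lipids)))
  expect_true(all(!is.na(b$meta$batch)))
  expect_true(all(is.na(b$meta$day[b$meta$treatment == "control"])))
})

test_that("configuration errors are raised for invalid settings", {
  expect_error(gc_sim_config(n_proteins = -5), "configuration")
  expect_error(gc_sim_config(noise_cv = 0), "configuration")
  expect_error(gc_sim_config(early_classes = c("TG"),
                             late_classes = c("TG")), "disjoint")
  expect_error(regen_sim_config(n_wnt3a = 1), "configuration")
})

test_that("zero marker separation gives chance-level AUC across seeds", {
  cfg <- regen_sim_config(marker_sep_sd = 0,
                          class_effects = list(`7` = numeric(0),
                                               `15` = numeric(0)))
  aucs <- vapply(1:200, function(s) {
    b <- generate_regen_lipidome(cfg, seed = 3000 + s)
    lab <- b$meta$treatment %in% c("wnt3a", "zymosan") |
      b$meta$treatment == "control"
    x <- log2(b$lipids[b$truth$marker_species, lab])
    pos <- b$meta$treatment[lab] %in% c("wnt3a", "zymosan")
    a <- brute_auc(x[pos], x[!pos])
    max(a, 1 - a)
  }, numeric(1))
  # orientation-corrected AUC of a null feature concentrates just above 0.5
  expect_lt(mean(aucs), 0.60)
  expect_gt(mean(aucs), 0.50)
})

test_that("knowledge tables contain the planted edges plus decoys", {
  b <- default_gc_bundle()
  kn <- generate_knowledge_tables(b, seed = 1)
  planted <- kn$edges[kn$edges$planted, ]
  expect_equal(nrow(kn$edges), 6 * nrow(planted))
  expect_true(all(planted$protein_a %in% b$truth$pl_coupled_pairs$protein_id))
  kn0 <- generate_knowledge_tables(b, seed = 1, decoy_factor = 0)
  expect_equal(nrow(kn0$edges), nrow(planted))
  expect_true(all(kn0$edges$planted))
  # complexes drawn from the coupled proteins
  expect_true(all(unlist(lapply(kn$complexes, `[[`, "members")) %in%
                    b$truth$pl_coupled_pairs$protein_id))
  bad <- b
  bad$truth$pl_coupled_pairs <- NULL
  expect_error(generate_knowledge_tables(bad), "coupled")
})

test_that("term tables round-trip through the GMT writer/reader", {
  b <- default_gc_bundle()
  kn <- generate_knowledge_tables(b, seed = 1)
  path <- tempfile(fileext = ".gmt")
  write_gmt(kn$terms, path)
  back <- read_gmt(path)
  expect_identical(back, kn$terms)
})
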