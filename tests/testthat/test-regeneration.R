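test_that("batch adjustment is the identity on a single batch", {
  set.seed(40)
  m <- toy_matrix(rnorm(200, 10), nrow = 20, space = "log2")
  out <- combat_adjust(m, rep("b1", 10))
  expect_lt(max(abs(out$adjusted - m)), 1e-8)
  expect_true(out$adjustment$converged)
})

test_that("batch adjustment removes planted additive shifts", {
  set.seed(41)
  m <- toy_matrix(rnorm(50 * 20, 12, 0.5), nrow = 50, space = "log2")
  batch <- rep(c("b1", "b2"), each = 10)
  shifted <- m
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 1.0
  out <- combat_adjust(shifted, batch)
  gap <- function(x) abs(rowMeans(x[, batch == "b1"]) -
                           rowMeans(x[, batch == "b2"]))
  expect_gte(1 - stats::median(gap(out$adjusted)) /
               stats::median(gap(shifted)), 0.9)
  # grand mean preserved per feature on the balanced design
  expect_lt(max(abs(rowMeans(out$adjusted) - rowMeans(shifted)) /
                  abs(rowMeans(shifted))), 1e-6)
  expect_error(combat_adjust(shifted, c("b1", rep("b2", 19))), ">= 2")
})

test_that("identical-distribution batches are barely perturbed", {
  set.seed(42)
  sd_noise <- 0.2
  m <- toy_matrix(rnorm(100 * 16, 10, sd_noise), nrow = 100, space = "log2")
  out <- combat_adjust(m, rep(c("b1", "b2"), each = 8))
  expect_lt(stats::median(abs(out$adjusted - m)), sd_noise)
})

test_that("batch adjustment agrees with the reference EB implementation", {
  skip_if_not_installed("sva")
  b <- default_regen_bundle(seed = 7)
  lg <- normalize_abundance(b$lipids, "median", to_log2 = TRUE)
  batch <- stats::setNames(b$meta$batch, b$meta$sample_id)
  mine <- combat_adjust(lg, batch)$adjusted
  ref <- suppressMessages(sva::ComBat(lg, batch = factor(batch)))
  expect_lt(stats::median(abs(mine - ref)), 0.01)
  expect_lt(max(abs(mine - ref)), 0.05)
})

test_that("AUC matches brute-force pair counting for small groups", {
  set.seed(43)
  for (i in 1:40) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    # rounding forces ties so the half-credit rule is exercised
    pos <- round(rnorm(n1, 0.5), 1)
    neg <- round(rnorm(n2), 1)
    m <- toy_matrix(c(pos, neg), nrow = 1, space = "log2")
    lab <- c(rep("regeneration", n1), rep("control", n2))
    got <- roc_rank(m, lab)
    a <- brute_auc(pos, neg)
    expect_equal(got$auc, max(a, 1 - a), tolerance = 1e-12)
    # duality of the two orientations
    expect_equal(brute_auc(pos, neg) + brute_auc(neg, pos), 1,
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and handles edge cases", {
  m <- toy_matrix(c(2.5, 4, 1, 2, 3), nrow = 1, space = "log2")
  lab <- c("regeneration", "regeneration", "control", "control", "control")
  expect_equal(roc_rank(m, lab)$auc, 5 / 6, tolerance = 1e-12)
  m2 <- m
  m2[1, ] <- exp(m2[1, ])
  expect_equal(roc_rank(m2, lab)$auc, 5 / 6, tolerance = 1e-12)
  # complete separation: AUC 1, accuracy 1
  sep <- toy_matrix(c(5, 6, 1, 2, 3), nrow = 1, space = "log2")
  got <- roc_rank(sep, lab)
  expect_equal(got$auc, 1)
  expect_equal(got$accuracy, 1)
  # identical distributions: AUC 0.5
  tie <- toy_matrix(c(1, 2, 1, 2, 1.5), nrow = 1, space = "log2")
  expect_equal(roc_rank(toy_matrix(c(1, 2, 1, 2), 1, space = "log2"),
                        c("regeneration", "regeneration", "control",
                          "control"))$auc, 0.5)
  expect_error(roc_rank(m, rep("control", 5)), "non-empty")
})

test_that("AUC agrees with the pROC reference on real-sized data", {
  skip_if_not_installed("pROC")
  res <- default_regen_results()
  b <- res$bundle
  lab <- ifelse(b$meta$treatment %in% c("wnt3a", "zymosan"),
                "regeneration",
                ifelse(b$meta$treatment == "control", "control", NA))
  keep <- !is.na(lab)
  for (f in rownames(res$adjusted)[1:25]) {
    mine <- roc_rank(toy_matrix(res$adjusted[f, keep], 1, space = "log2",
                                features = f, samples = colnames(
                                  res$adjusted)[keep]),
                     lab[keep])$auc
    ref <- suppressMessages(as.numeric(pROC::auc(
      lab[keep] == "regeneration", res$adjusted[f, keep],
      direction = "auto")))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("the planted marker tops the ROC ranking with full separation", {
  res <- default_regen_results()
  expect_identical(res$roc$feature_id[1], res$bundle$truth$marker_species)
  expect_equal(res$roc$auc[1], 1)
  expect_equal(res$roc$accuracy[1], 1)
  expect_equal(res$roc$direction[1], "up")
  expect_true(all(res$roc$auc >= 0.5 & res$roc$auc <= 1))
})

test_that("shared-signature intersection behaves on constructed inputs", {
  enr <- data.frame(term_id = c("a", "b", "c"), q = c(0.001, 0.2, 0.01))
  # identical arms: the full significant set
  out <- common_signatures(enr, enr)
  expect_setequal(out$term_id, c("a", "c"))
  # disjoint significant sets: empty intersection
  enr2 <- data.frame(term_id = c("a", "b", "c"), q = c(0.9, 0.01, 0.8))
  expect_equal(nrow(common_signatures(enr, enr2)), 0)
  # disjoint universes: error
  enr3 <- data.frame(term_id = c("x", "y"), q = c(0.01, 0.01))
  expect_error(common_signatures(enr, enr3), "disjoint")
})

test_that("development and regeneration share the planted storage terms", {
  gcres <- default_gc_results()
  res <- default_regen_results()
  shared <- common_signatures(gcres$enrichment$early, res$enrichment)
  expect_true(all(c("lipid_storage", "lipid_droplet", "triacylglycerol",
                    "glycerolipid", "neutral_headgroup") %in%
                    shared$term_id))
})
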