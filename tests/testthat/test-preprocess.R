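test_that("total-intensity normalization equalizes column sums", {
  # hand-worked case: column sums 6 and 3, mean 4.5, so sample 2 is scaled
  # by twice the factor of sample 1
  m <- toy_matrix(c(2, 4, 1, 2), nrow = 2)
  out <- normalize_abundance(m, "total_intensity")
  expect_equal(unname(out[, 1]), c(1.5, 3))
  expect_equal(unname(out[, 2]), c(1.5, 3))
  # equal column sums: identity
  m2 <- toy_matrix(c(1, 3, 2, 2), nrow = 2)
  expect_equal(unname(normalize_abundance(m2, "total_intensity")),
               unname(m2))
  # property on random data
  set.seed(4)
  m3 <- toy_matrix(stats::rgamma(60, 2), nrow = 10)
  cs <- colSums(normalize_abundance(m3, "total_intensity"))
  expect_lt(diff(range(cs)) / mean(cs), 1e-9)
  expect_error(normalize_abundance(toy_matrix(c(0, 0, 1, 2), 2),
                                   "total_intensity"), "s1")
})

test_that("median normalization equalizes column medians", {
  set.seed(5)
  m <- toy_matrix(stats::rgamma(50, 2), nrow = 10)
  out <- normalize_abundance(m, "median")
  med <- apply(out, 2, stats::median)
  expect_lt(diff(range(med)) / mean(med), 1e-9)
})

test_that("autoscaling gives zero-mean unit-variance rows", {
  set.seed(6)
  m <- toy_matrix(stats::rnorm(80), nrow = 8, space = "log2")
  out <- normalize_abundance(m, "autoscale")
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, stats::var) - 1)), 1e-9)
  expect_identical(abundance_space(out), "autoscaled")
  const <- toy_matrix(rbind(rep(1, 3), c(2, 3, 4)), nrow = 2)
  expect_error(normalize_abundance(const, "autoscale"), "constant")
})

test_that("log2 transform is applied after scaling with the pseudocount", {
  m <- toy_matrix(c(3, 1), nrow = 1, samples = c("a", "b"))
  out <- normalize_abundance(m, "median", to_log2 = TRUE, pseudocount = 1)
  expect_equal(unname(out[1, ]), log2(c(3, 1) / c(3, 1) * 2 + 1),
               ignore_attr = TRUE)
  expect_identical(abundance_space(out), "log2")
})

test_that("CV computation matches the n-1 definition and guards its input", {
  m <- toy_matrix(c(90, 100, 110, 5, 5, 5), nrow = 1,
                  samples = paste0("s", 1:6))
  grouping <- c(rep("g1", 3), rep("g2", 3))
  cv <- compute_cv(m, grouping)
  expect_equal(unname(cv$cv[1, "g1"]), 0.10)
  expect_equal(unname(cv$cv[1, "g2"]), 0)
  lg <- m
  abundance_space(lg) <- "log2"
  expect_error(compute_cv(lg, grouping), "raw")
  expect_error(compute_cv(m, c(rep("g1", 5), "g2")), ">= 2")
})

test_that("lipid shorthand parsing extracts class, chains and totals", {
  a <- parse_lipid_name("Cer(d18:1/24:0)")
  expect_equal(a$class_code, "Cer")
  expect_equal(a$n_chains, 2)
  expect_equal(a$total_carbons, 42)
  expect_equal(a$total_double_bonds, 1)
  expect_equal(a$chains[[1]]$prefix, c("d", "none"))

  b <- parse_lipid_name("TG(16:0/18:1/18:2)")
  expect_equal(b$class_code, "TG")
  expect_equal(b$n_chains, 3)
  expect_equal(b$total_carbons, 52)
  expect_equal(b$total_double_bonds, 3)

  z <- parse_lipid_name("PC(0:0/0:0)")
  expect_equal(z$total_carbons, 0)
  expect_equal(z$total_double_bonds, 0)

  u <- parse_lipid_name("XYZ(12:0)")
  expect_false(u$known_class)
  expect_equal(u$class_code, "XYZ")

  expect_error(parse_lipid_name("not a lipid"), "not a lipid")
})

test_that("parse and format are inverse on generated species names", {
  b <- default_gc_bundle()
  ann <- parse_lipid_name(rownames(b$lipids))
  expect_identical(format_lipid_name(ann), rownames(b$lipids))
  expect_identical(ann$class_code, b$truth$lipid_annotation$class_code)
})

test_that("class aggregation sums members and conserves totals", {
  m <- toy_matrix(c(1, 3, 2, 4), nrow = 2,
                  features = c("PC(16:0/18:1)", "PC(18:0/18:1)"))
  ann <- parse_lipid_name(rownames(m))
  out <- aggregate_lipid_classes(m, ann)
  expect_equal(unname(out["PC", ]), c(4, 6))

  b <- default_gc_bundle()
  ann2 <- parse_lipid_name(rownames(b$lipids))
  cls <- aggregate_lipid_classes(b$lipids, ann2)
  expect_lt(max(abs(colSums(cls) - colSums(b$lipids)) / colSums(b$lipids)),
            1e-9)
  # one species per class: aggregation is the identity up to row order
  single <- toy_matrix(c(1, 2, 3, 4), nrow = 2,
                       features = c("TG(16:0/18:1/18:2)", "Cer(d18:1/24:0)"))
  agg <- aggregate_lipid_classes(single, parse_lipid_name(rownames(single)))
  expect_equal(unname(agg["TG", ]), unname(single[1, ]))
  expect_error(aggregate_lipid_classes(
    toy_matrix(1:2, 1, features = "PC(16:0/18:1)", samples = c("a", "b")),
    data.frame(species_id = "other", class_code = "PC")), "unannotated")
})

test_that("TSV readers tolerate comment headers and CRLF endings", {
  m <- toy_matrix(c(1.5, 2, 3, 4.25), nrow = 2)
  path <- tempfile(fileext = ".tsv")
  write_abundance_tsv(m, path, header = c("seed: 1", "note: fixture"))
  back <- read_abundance_tsv(path)
  expect_equal(unname(back), unname(m), ignore_attr = TRUE)
  expect_identical(dimnames(back), dimnames(m))
  # CRLF variant
  crlf <- tempfile(fileext = ".tsv")
  writeLines(paste0(readLines(path), "\r"), crlf, sep = "\n")
  back2 <- read_abundance_tsv(crlf)
  expect_equal(unname(back2), unname(m), ignore_attr = TRUE)
  # metadata round trip
  meta <- default_gc_bundle()$meta
  mpath <- tempfile(fileext = ".tsv")
  write_sample_meta(meta, mpath, header = "fixture")
  expect_equal(read_sample_meta(mpath), meta)
  # edges
  edges <- data.frame(protein_a = "p1", protein_b = "p2", score = 0.9)
  epath <- tempfile(fileext = ".tsv")
  write_edge_tsv(edges, epath)
  expect_equal(read_edge_tsv(epath), edges)
})
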