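# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

default_gc_bundle <- function(seed = 1) {
  key <- paste0("gc", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_gc_multiomic(gc_sim_config(), seed = seed)
  .fixture_env[[key]]
}

default_regen_bundle <- function(seed = 42) {
  key <- paste0("regen", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_regen_lipidome(regen_sim_config(),
                                                   seed = seed)
  .fixture_env[[key]]
}

default_gc_results <- function(seed = 1) {
  key <- paste0("gcres", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_gc_pipeline(
      pipeline_config(simulate = list(config = NULL, seed = seed)))
  .fixture_env[[key]]
}

default_regen_results <- function(seed = 42) {
  key <- paste0("regres", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_regen_pipeline(
      pipeline_config(simulate = list(config = NULL, seed = seed)))
  .fixture_env[[key]]
}

# small labelled matrix in a chosen space
toy_matrix <- function(values, nrow, space = "raw",
                       features = NULL, samples = NULL) {
  m <- matrix(values, nrow = nrow)
  rownames(m) <- if (is.null(features)) paste0("f", seq_len(nrow(m))) else
    features
  colnames(m) <- if (is.null(samples)) paste0("s", seq_len(ncol(m))) else
    samples
  attr(m, "space") <- space
  m
}

# brute-force midrank AUC: count winning pairs, half credit for ties
brute_auc <- function(pos, neg) {
  wins <- 0
  for (x in pos) for (y in neg)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(pos) * length(neg))
}

# exhaustive hypergeometric upper tail: enumerate every size-n subset of the
# background and count overlaps >= k
brute_hyper_p <- function(N, K, n, k) {
  term <- seq_len(K)
  hits <- 0
  subsets <- utils::combn(N, n)
  for (j in seq_len(ncol(subsets)))
    hits <- hits + (sum(subsets[, j] %in% term) >= k)
  hits / ncol(subsets)
}
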