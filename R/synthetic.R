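#' @title Synthetic multi-omic data with planted, recoverable structure
#' @name synthetic-data
#' @description
#' Generators for two study designs: a growth-cone development experiment
#' (2 subcellular fractions x 5 developmental stages with ~6 biological
#' replicates per cell, proteome + lipidome) and an optic-nerve regeneration
#' lipidome (normal controls, crush+saline, and Wnt3a- or Zymosan-induced
#' regeneration across post-injury days, with acquisition-batch structure).
#' Measurement noise is multiplicative lognormal: normal in log2 space with
#' `sd = sqrt(log(1 + CV^2)) / log(2)`, so a target coefficient of variation
#' maps exactly onto the log-scale noise. All planted effects are additive in
#' log2 space and are recorded in a truth object for parameter-recovery
#' testing.
NULL

GC_STAGES <- c("E18", "P0", "P3", "P6", "P9")
GC_FRACTIONS <- c("GCM", "GCP")

# early/late switching shape over the 5 stage ordinals (zero mean):
# elevated at E18/P0, depressed at P3-P9. Against the stage ordinal this
# contrast has Pearson r = -0.866, i.e. it passes a |r| > 0.7 trend gate
# with the sign the class direction implies.
STEP_PROFILE <- c(1, 1, -2 / 3, -2 / 3, -2 / 3)

#' Convert a target CV into a log2-space noise SD
#'
#' For lognormal intensities, `CV = sqrt(exp(sigma_ln^2) - 1)`; inverting and
#' changing the base gives the log2 SD that realizes the requested CV.
#'
#' @param cv coefficient of variation (fraction, > 0).
#' @return standard deviation in log2 units.
#' @export
cv_to_log2_sd <- function(cv) {
  if (!is.numeric(cv) || cv <= 0) stop("noise_cv must be > 0")
  sqrt(log1p(cv^2)) / log(2)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

#' Generator settings for the growth-cone development experiment
#'
#' Defaults encode the emulated study design: 600 proteins and 200 lipid
#' species over 20 classes, 5 stages (E18..P9) x 2 fractions (GCM/GCP) with 6
#' replicates per cell except GCM/E18 and GCP/P9 (5 each), for 29 + 29 = 58
#' samples. Effect sizes are expressed in units of the log2 noise SD.
#'
#' @param n_proteins,n_lipid_species feature counts.
#' @param lipid_classes pool of class codes species are drawn from.
#' @param replicates biological replicates per stage x fraction cell.
#' @param reduced_cells list of `c(fraction, stage)` cells with one fewer
#'   replicate.
#' @param noise_cv target coefficient of variation of the lognormal noise.
#' @param baseline_log2_mean,baseline_log2_sd lognormal baseline abundance
#'   parameters (log2 space).
#' @param n_trend_pos,n_trend_neg numbers of proteins with planted linear
#'   stage trends (per direction).
#' @param trend_slope_sd per-stage slope of trend proteins, in noise-SD units.
#' @param n_fraction_features,fraction_shift_log2 proteins carrying a planted
#'   GCM-vs-GCP log2 shift, and its size.
#' @param early_classes,late_classes lipid classes planted high in early
#'   (E18/P0) or late (P3-P9) development; the switching contrast has
#'   amplitude `class_switch_sd` noise SDs.
#' @param class_switch_sd amplitude of the early/late class contrast.
#' @param coupled_classes,n_coupled_per_class protein-lipid co-trending:
#'   for each listed class, this many proteins share the class's stage
#'   profile (amplitude `coupling_sd` noise SDs).
#' @param coupling_sd amplitude of the coupled-protein profiles.
#' @param min_class_size guaranteed species count for classes that carry
#'   planted effects.
#' @return list of settings for [generate_gc_multiomic()].
#' @export
gc_sim_config <- function(n_proteins = 600,
                          n_lipid_species = 200,
                          lipid_classes = c("PC", "PE", "PS", "PI", "PG",
                                            "PA", "Cer", "SM", "CerG1",
                                            "TG", "DG", "MG", "ChE", "ZyE",
                                            "So", "CL", "LPC", "LPS", "LPG",
                                            "SQDG"),
                          replicates = 6,
                          reduced_cells = list(c("GCM", "E18"),
                                               c("GCP", "P9")),
                          noise_cv = 0.08,
                          baseline_log2_mean = 20,
                          baseline_log2_sd = 2,
                          n_trend_pos = 60,
                          n_trend_neg = 60,
                          trend_slope_sd = 1.5,
                          n_fraction_features = 150,
                          fraction_shift_log2 = 1.5,
                          early_classes = c("TG", "DG", "MG", "ChE", "ZyE",
                                            "So"),
                          late_classes = c("CerG1", "LPC", "LPS", "LPG"),
                          class_switch_sd = 4,
                          coupled_classes = c("TG", "ChE", "CerG1", "LPC"),
                          n_coupled_per_class = 4,
                          coupling_sd = 4,
                          min_class_size = 4) {
  cfg <- as.list(environment())
  counts <- c(n_proteins, n_lipid_species, replicates, n_trend_pos,
              n_trend_neg, n_fraction_features, n_coupled_per_class)
  if (any(counts <= 0)) stop("configuration error: counts must be positive")
  if (noise_cv <= 0) stop("configuration error: noise_cv must be > 0")
  if (length(intersect(early_classes, late_classes)))
    stop("configuration error: early and late class sets must be disjoint")
  if (!all(c(early_classes, late_classes, coupled_classes) %in% lipid_classes))
    stop("configuration error: effect classes must come from lipid_classes")
  needed <- n_trend_pos + n_trend_neg + n_fraction_features +
    length(coupled_classes) * n_coupled_per_class
  if (needed > n_proteins)
    stop("configuration error: planted protein sets exceed n_proteins")
  cfg
}

gc_sample_table <- function(config) {
  rows <- list()
  for (fr in GC_FRACTIONS) {
    for (st in GC_STAGES) {
      n <- config$replicates
      for (rc in config$reduced_cells)
        if (rc[1] == fr && rc[2] == st) n <- n - 1L
      rows[[paste(fr, st)]] <- data.frame(
        sample_id = sprintf("%s_%s_r%d", fr, st, seq_len(n)),
        fraction = fr, stage = st,
        stage_ordinal = match(st, GC_STAGES) - 1L,
        replicate = seq_len(n),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

chains_per_class <- c(PC = 2, PE = 2, PS = 2, PI = 2, PG = 2, PA = 2,
                      Cer = 2, SM = 2, CerG1 = 2, TG = 3, DG = 2, MG = 1,
                      ChE = 1, ZyE = 1, So = 1, CL = 4, LPC = 1, LPE = 1,
                      LPS = 1, LPG = 1, LPI = 1, SQDG = 2)
SPHINGOID_CLASSES <- c("Cer", "SM", "CerG1", "So")

random_species_name <- function(class) {
  n_chain <- chains_per_class[[class]]
  if (is.null(n_chain)) n_chain <- 2L
  carbons <- sample(12:26, n_chain, replace = TRUE)
  # double-bond counts span 0-6 so unsaturation-based ontology terms are
  # exercised
  dbs <- sample(0:6, n_chain, replace = TRUE,
                prob = c(4, 4, 3, 2, 2, 1, 1))
  pre <- rep("", n_chain)
  if (class %in% SPHINGOID_CLASSES) {
    pre[1] <- sample(c("d", "t"), 1, prob = c(0.8, 0.2))
    carbons[1] <- sample(seq(14L, 22L, by = 1L), 1)
    dbs[1] <- sample(0:2, 1)
  }
  body <- paste0(pre, carbons, ":", dbs, collapse = "/")
  paste0(class, "(", body, ")")
}

draw_species_names <- function(classes, existing = character(0)) {
  names <- character(length(classes))
  seen <- existing
  for (i in seq_along(classes)) {
    for (try in 1:500) {
      nm <- random_species_name(classes[i])
      if (!nm %in% seen) break
      if (try == 500) stop("could not draw a unique species name")
    }
    names[i] <- nm
    seen <- c(seen, nm)
  }
  names
}

# uniform class membership, then top up classes carrying planted effects so
# none of them is empty by chance
draw_lipid_classes <- function(n, pool, protected, min_size) {
  classes <- sample(pool, n, replace = TRUE)
  for (cl in protected) {
    deficit <- min_size - sum(classes == cl)
    if (deficit > 0) {
      donors <- which(!classes %in% protected)
      take <- sample(donors, deficit)
      classes[take] <- cl
    }
  }
  classes
}

#' Generate the growth-cone development multi-omic bundle
#'
#' Builds matched proteome and lipidome abundance matrices (raw intensity
#' space), sample metadata, and a truth record of every planted effect.
#' Baselines are lognormal; planted effects (linear protein stage trends, a
#' GCM/GCP fraction shift, early/late lipid-class switching, protein-lipid
#' co-trending) are applied additively in log2 space; measurement noise is
#' lognormal at the configured CV. Deterministic given `(config, seed)`.
#'
#' @param config settings from [gc_sim_config()].
#' @param seed integer RNG seed.
#' @return object of class `gc_bundle`: list with `proteins` and `lipids`
#'   (features x samples raw matrices), `meta` (sample table) and `truth`.
#' @export
generate_gc_multiomic <- function(config = gc_sim_config(), seed = 1) {
  with_seed(seed, {
    meta <- gc_sample_table(config)
    n_s <- nrow(meta)
    sigma <- cv_to_log2_sd(config$noise_cv)
    ord <- meta$stage_ordinal
    gcm <- as.numeric(meta$fraction == "GCM")

    ## ---- proteome -------------------------------------------------------
    prot_ids <- sprintf("prot%04d", seq_len(config$n_proteins))
    i <- 0
    take <- function(n) {
      out <- prot_ids[(i + 1):(i + n)]
      i <<- i + n
      out
    }
    trend_pos <- take(config$n_trend_pos)
    trend_neg <- take(config$n_trend_neg)
    frac_set <- take(config$n_fraction_features)
    coupled <- lapply(config$coupled_classes, function(cl)
      take(config$n_coupled_per_class))
    names(coupled) <- config$coupled_classes

    base_p <- stats::rnorm(config$n_proteins, config$baseline_log2_mean,
                           config$baseline_log2_sd)
    slope <- stats::setNames(numeric(config$n_proteins), prot_ids)
    slope[trend_pos] <- config$trend_slope_sd * sigma
    slope[trend_neg] <- -config$trend_slope_sd * sigma

    P <- matrix(base_p, config$n_proteins, n_s,
                dimnames = list(prot_ids, meta$sample_id))
    P <- P + outer(slope, ord - 2)
    P[frac_set, ] <- P[frac_set, , drop = FALSE] +
      config$fraction_shift_log2 * rep(gcm, each = length(frac_set))
    coupled_dir <- character(0)
    for (cl in config$coupled_classes) {
      shape <- if (cl %in% config$early_classes) STEP_PROFILE else
        -STEP_PROFILE
      prof <- config$coupling_sd * sigma * shape[ord + 1]
      P[coupled[[cl]], ] <- P[coupled[[cl]], , drop = FALSE] +
        rep(prof, each = length(coupled[[cl]]))
      coupled_dir[cl] <- if (cl %in% config$early_classes) "decreasing" else
        "increasing"
    }
    P <- P + matrix(stats::rnorm(length(P), 0, sigma), nrow(P))

    ## coupled proteins follow a stage contrast with |r| ~ 0.87, so they are
    ## genuinely trending features and belong to the planted trend sets
    trend_pos_all <- c(trend_pos,
                       unlist(coupled[coupled_dir == "increasing"],
                              use.names = FALSE))
    trend_neg_all <- c(trend_neg,
                       unlist(coupled[coupled_dir == "decreasing"],
                              use.names = FALSE))

    ## ---- lipidome -------------------------------------------------------
    protected <- unique(c(config$early_classes, config$late_classes,
                          config$coupled_classes))
    classes <- draw_lipid_classes(config$n_lipid_species,
                                  config$lipid_classes, protected,
                                  config$min_class_size)
    species <- draw_species_names(classes)
    base_l <- stats::rnorm(config$n_lipid_species, config$baseline_log2_mean,
                           config$baseline_log2_sd)
    L <- matrix(base_l, config$n_lipid_species, n_s,
                dimnames = list(species, meta$sample_id))
    step <- config$class_switch_sd * sigma * STEP_PROFILE[ord + 1]
    early_rows <- classes %in% config$early_classes
    late_rows <- classes %in% config$late_classes
    L[early_rows, ] <- L[early_rows, , drop = FALSE] +
      rep(step, each = sum(early_rows))
    L[late_rows, ] <- L[late_rows, , drop = FALSE] -
      rep(step, each = sum(late_rows))
    L <- L + matrix(stats::rnorm(length(L), 0, sigma), nrow(L))

    pl_pairs <- do.call(rbind, lapply(config$coupled_classes, function(cl)
      data.frame(protein_id = unname(coupled[[cl]]), lipid_class = cl,
                 direction = unname(coupled_dir[cl]),
                 stringsAsFactors = FALSE)))

    truth <- list(
      trend_proteins_pos = trend_pos_all,
      trend_proteins_neg = trend_neg_all,
      fraction_effect_features = frac_set,
      early_classes = config$early_classes,
      late_classes = config$late_classes,
      pl_coupled_pairs = pl_pairs,
      marker_species = NA_character_,
      crush_depleted_species = character(0),
      batch_shifts = NULL,
      noise_cv = config$noise_cv,
      noise_log2_sd = sigma,
      lipid_annotation = data.frame(species_id = species,
                                    class_code = classes,
                                    stringsAsFactors = FALSE),
      config = config)

    bundle <- list(
      proteins = new_abundance_matrix(2^P, prot_ids, meta$sample_id, "raw"),
      lipids = new_abundance_matrix(2^L, species, meta$sample_id, "raw"),
      meta = meta,
      truth = truth)
    class(bundle) <- "gc_bundle"
    bundle
  })
}

#' Generator settings for the optic-nerve regeneration lipidome
#'
#' Defaults mirror the regeneration study design: 21 uninjured controls, 16
#' crush+saline, 6 Wnt3a and 10 Zymosan samples collected 3/7/15 days post
#' injection in two acquisition batches. One marker species is planted with
#' an 8-noise-SD elevation in all regenerating samples; nine species (eight
#' PC, one PE) are depleted in the crush+saline arm; TG/MG/PG rise and CerG1
#' falls in regenerating samples at days 7 and 15.
#'
#' @param n_species number of lipid species.
#' @param lipid_classes class pool.
#' @param n_control,n_crush,n_wnt3a,n_zymosan group sizes.
#' @param wnt3a_days,zymosan_days,crush_days post-injection day per sample.
#' @param marker_species planted regeneration marker (shorthand name).
#' @param marker_sep_sd marker elevation in noise-SD units.
#' @param crush_depleted species depleted after crush (saline arm).
#' @param crush_depletion_log2 depletion size (log2).
#' @param class_effects named list `day -> named log2 shifts per class`
#'   applied to regenerating samples at that day.
#' @param batch_shifts named nominal additive log2 offsets per acquisition
#'   batch.
#' @param batch_shift_feature_sd SD of the per-feature offsets drawn around
#'   each batch's nominal shift.
#' @param noise_cv,baseline_log2_mean,baseline_log2_sd as in
#'   [gc_sim_config()].
#' @param min_class_size guaranteed size of effect-carrying classes.
#' @return list of settings for [generate_regen_lipidome()].
#' @export
regen_sim_config <- function(n_species = 200,
                             lipid_classes = c("PC", "PE", "PS", "PI", "PG",
                                               "PA", "Cer", "SM", "CerG1",
                                               "TG", "DG", "MG", "ChE",
                                               "ZyE", "So", "CL", "LPC",
                                               "LPS", "LPG", "SQDG"),
                             n_control = 21, n_crush = 16,
                             n_wnt3a = 6, n_zymosan = 10,
                             wnt3a_days = c(3, 7, 7, 15, 15, 15),
                             zymosan_days = rep(c(3, 7, 15), c(3, 3, 4)),
                             crush_days = rep(c(3, 7, 15), c(6, 5, 5)),
                             marker_species = "Cer(d18:1/24:0)",
                             marker_sep_sd = 8,
                             crush_depleted = c("PC(16:0/18:1)",
                                                "PC(16:0/16:0)",
                                                "PC(18:0/18:1)",
                                                "PC(16:0/20:4)",
                                                "PC(18:0/22:6)",
                                                "PC(16:0/18:2)",
                                                "PC(18:1/18:1)",
                                                "PC(16:0/22:6)",
                                                "PE(18:0/22:6)"),
                             crush_depletion_log2 = -2,
                             class_effects = list(
                               `7` = c(TG = 0.6, CerG1 = -0.6),
                               `15` = c(TG = 1.8, MG = 1.5, PG = 1.5,
                                        CerG1 = -1.8)),
                             batch_shifts = c(batchA = 0.8, batchB = 0),
                             batch_shift_feature_sd = 0.15,
                             noise_cv = 0.08,
                             baseline_log2_mean = 20,
                             baseline_log2_sd = 2,
                             min_class_size = 6) {
  cfg <- as.list(environment())
  if (any(c(n_control, n_crush, n_wnt3a, n_zymosan) < 2))
    stop("configuration error: every treatment group needs >= 2 samples")
  if (n_species <= 0 || noise_cv <= 0)
    stop("configuration error: counts and noise_cv must be positive")
  if (length(wnt3a_days) != n_wnt3a || length(zymosan_days) != n_zymosan ||
      length(crush_days) != n_crush)
    stop("configuration error: day vectors must match group sizes")
  cfg
}

regen_sample_table <- function(config) {
  batches <- names(config$batch_shifts)
  if (length(batches) < 1) batches <- "batchA"
  split2 <- function(n) {
    # controls and crush samples are split across the two acquisition
    # batches; induced-regeneration arms were each run as one experiment
    a <- ceiling(n / 2)
    rep(batches[c(1, min(2, length(batches)))], c(a, n - a))
  }
  meta <- rbind(
    data.frame(sample_id = sprintf("ctrl_%02d", seq_len(config$n_control)),
               treatment = "control", day = NA_real_,
               batch = split2(config$n_control), stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("crush_%02d", seq_len(config$n_crush)),
               treatment = "crush_saline", day = config$crush_days,
               batch = split2(config$n_crush), stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("wnt3a_%02d", seq_len(config$n_wnt3a)),
               treatment = "wnt3a", day = config$wnt3a_days,
               batch = batches[1], stringsAsFactors = FALSE),
    data.frame(sample_id = sprintf("zymo_%02d", seq_len(config$n_zymosan)),
               treatment = "zymosan", day = config$zymosan_days,
               batch = batches[min(2, length(batches))],
               stringsAsFactors = FALSE))
  rownames(meta) <- NULL
  meta
}

#' Generate the optic-nerve regeneration lipidome bundle
#'
#' @param config settings from [regen_sim_config()].
#' @param seed integer RNG seed.
#' @return object of class `regen_bundle`: list with `lipids` (species x
#'   samples raw matrix), `meta` and `truth`.
#' @export
generate_regen_lipidome <- function(config = regen_sim_config(), seed = 42) {
  with_seed(seed, {
    meta <- regen_sample_table(config)
    n_s <- nrow(meta)
    sigma <- cv_to_log2_sd(config$noise_cv)

    forced <- c(config$marker_species, config$crush_depleted)
    forced_classes <- sub("\\(.*$", "", forced)
    n_free <- config$n_species - length(forced)
    if (n_free < 0)
      stop("configuration error: n_species smaller than forced species list")
    protected <- unique(c(names(config$class_effects[["7"]]),
                          names(config$class_effects[["15"]]),
                          unlist(lapply(config$class_effects, names))))
    free_classes <- draw_lipid_classes(n_free, config$lipid_classes,
                                       protected, config$min_class_size)
    free_names <- draw_species_names(free_classes, existing = forced)
    species <- c(forced, free_names)
    classes <- c(forced_classes, free_classes)

    base <- stats::rnorm(config$n_species, config$baseline_log2_mean,
                         config$baseline_log2_sd)
    L <- matrix(base, config$n_species, n_s,
                dimnames = list(species, meta$sample_id))

    is_regen <- meta$treatment %in% c("wnt3a", "zymosan")
    ## batch effects are feature-specific offsets centered on the batch's
    ## nominal shift, as real acquisition-batch effects are; a uniform
    ## whole-sample shift would be absorbed by column normalization
    batch_offsets <- sapply(names(config$batch_shifts), function(b)
      stats::rnorm(config$n_species, config$batch_shifts[[b]],
                   config$batch_shift_feature_sd))
    if (!is.matrix(batch_offsets))
      batch_offsets <- matrix(batch_offsets, config$n_species)
    rownames(batch_offsets) <- species
    L <- L + batch_offsets[, match(meta$batch, names(config$batch_shifts)),
                           drop = FALSE]
    L[config$marker_species, is_regen] <-
      L[config$marker_species, is_regen] + config$marker_sep_sd * sigma
    is_crush <- meta$treatment == "crush_saline"
    L[config$crush_depleted, is_crush] <-
      L[config$crush_depleted, is_crush] + config$crush_depletion_log2
    for (day in names(config$class_effects)) {
      eff <- config$class_effects[[day]]
      sel <- is_regen & !is.na(meta$day) & meta$day == as.numeric(day)
      for (cl in names(eff)) {
        rows <- classes == cl
        L[rows, sel] <- L[rows, sel, drop = FALSE] + eff[[cl]]
      }
    }
    L <- L + matrix(stats::rnorm(length(L), 0, sigma), nrow(L))

    truth <- list(
      trend_proteins_pos = character(0),
      trend_proteins_neg = character(0),
      fraction_effect_features = character(0),
      early_classes = character(0),
      late_classes = character(0),
      pl_coupled_pairs = NULL,
      marker_species = config$marker_species,
      crush_depleted_species = config$crush_depleted,
      batch_shifts = config$batch_shifts,
      batch_offsets = batch_offsets,
      class_effects = config$class_effects,
      noise_cv = config$noise_cv,
      noise_log2_sd = sigma,
      lipid_annotation = data.frame(species_id = species,
                                    class_code = classes,
                                    stringsAsFactors = FALSE),
      config = config)

    bundle <- list(
      lipids = new_abundance_matrix(2^L, species, meta$sample_id, "raw"),
      meta = meta,
      truth = truth)
    class(bundle) <- "regen_bundle"
    bundle
  })
}

#' @export
print.gc_bundle <- function(x, ...) {
  cat("growth-cone multi-omic bundle:",
      nrow(x$proteins), "proteins,", nrow(x$lipids), "lipid species,",
      nrow(x$meta), "samples\n")
  invisible(x)
}

#' @export
print.regen_bundle <- function(x, ...) {
  cat("regeneration lipidome bundle:", nrow(x$lipids), "species,",
      nrow(x$meta), "samples (",
      paste(names(table(x$meta$treatment)),
            table(x$meta$treatment), collapse = ", "), ")\n")
  invisible(x)
}

#' Generate STRING/CORUM/ontology-style knowledge tables for a GC bundle
#'
#' Builds (1) a protein-protein edge list containing every within-class pair
#' of the bundle's coupled proteins plus `decoy_factor` times as many decoy
#' edges among proteins with no planted trend, (2) two planted protein
#' complexes (an 8-member complex from the positively co-trending proteins
#' and a 2-member complex from the negatively co-trending ones), and (3)
#' lipid ontology-style term sets from [build_class_term_sets()].
#'
#' @param bundle a `gc_bundle` from [generate_gc_multiomic()].
#' @param seed integer RNG seed (decoy sampling and edge scores).
#' @param decoy_factor decoy edges per planted edge.
#' @return list with `edges` (data.frame `protein_a`, `protein_b`, `score`,
#'   `planted`), `complexes` (GMT-style named list) and `terms` (GMT-style
#'   named list over lipid species).
#' @export
generate_knowledge_tables <- function(bundle, seed = 1, decoy_factor = 5) {
  truth <- bundle$truth
  pairs <- truth$pl_coupled_pairs
  if (is.null(pairs) || !nrow(pairs))
    stop("generation error: truth contains no protein-lipid coupled pairs")
  with_seed(seed + 7L, {
    planted <- do.call(rbind, lapply(split(pairs$protein_id,
                                           pairs$lipid_class), function(ids) {
      if (length(ids) < 2) return(NULL)
      cmb <- utils::combn(sort(ids), 2)
      data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                 stringsAsFactors = FALSE)
    }))
    rownames(planted) <- NULL
    planted$score <- round(stats::runif(nrow(planted), 0.7, 0.99), 3)
    planted$planted <- TRUE

    n_decoy <- decoy_factor * nrow(planted)
    edges <- planted
    if (n_decoy > 0) {
      eligible <- setdiff(rownames(bundle$proteins),
                          c(truth$trend_proteins_pos,
                            truth$trend_proteins_neg,
                            truth$fraction_effect_features))
      seen <- paste(planted$protein_a, planted$protein_b)
      dec <- matrix(character(0), 0, 2)
      while (nrow(dec) < n_decoy) {
        cand <- sort(sample(eligible, 2))
        key <- paste(cand[1], cand[2])
        if (!key %in% seen) {
          dec <- rbind(dec, cand)
          seen <- c(seen, key)
        }
      }
      decoys <- data.frame(protein_a = dec[, 1], protein_b = dec[, 2],
                           score = round(stats::runif(n_decoy, 0.4, 0.9), 3),
                           planted = FALSE, stringsAsFactors = FALSE)
      edges <- rbind(planted, decoys)
    }
    rownames(edges) <- NULL

    up <- pairs$protein_id[pairs$direction == "increasing"]
    down <- pairs$protein_id[pairs$direction == "decreasing"]
    complexes <- list()
    if (length(up) >= 2)
      complexes[["CPLX_LATE_8"]] <- list(
        description = "planted complex co-increasing with stage",
        members = utils::head(up, 8))
    if (length(down) >= 2)
      complexes[["CPLX_EARLY_2"]] <- list(
        description = "planted dimer co-decreasing with stage",
        members = utils::head(down, 2))

    terms <- build_class_term_sets(
      annotation = parse_lipid_name(rownames(bundle$lipids)))

    list(edges = edges, complexes = complexes, terms = terms)
  })
}
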