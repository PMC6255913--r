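#' Configuration for the two-cohort synthetic expression generator
#'
#' The defaults encode the study conditions the generator emulates: two
#' whole-blood microarray cohorts with the diagnostic group sizes of the
#' AddNeuroMed discovery data (143/77/104 and 102/65/78 for AD/MCI/CTL),
#' log2-scale expression with small differential-expression effects, age
#' and gender covariate effects on a subset of features, an additive
#' per-cohort batch offset, heteroskedastic per-feature noise drawn from a
#' scaled inverse-chi-square prior, and a small planted discriminative
#' panel of known standardized effect size.
#'
#' @param n_per_group list of two integer vectors named `A` and `B`, each
#'   with elements `AD`, `MCI`, `CTL`.
#' @param n_features number of features (probesets) G.
#' @param deg_fraction fraction of features that are true DEGs.
#' @param deg_effect_range range (log2 units) of absolute AD effect sizes.
#' @param mci_attenuation multiplier mapping AD effects to MCI effects;
#'   the default 1.2 makes MCI changes slightly larger, the direction the
#'   blood data show.
#' @param concordance_target fraction of DEGs whose MCI effect shares the
#'   AD direction.
#' @param panel_features number of planted panel features k.
#' @param panel_effect standardized mean difference (in units of the
#'   feature's own noise sd) separating AD from CTL on each panel feature.
#' @param age_mean,age_sd mean and sd of simulated ages (years).
#' @param age_slope_fraction fraction of features with an age effect (and,
#'   independently, with a gender effect).
#' @param age_slope_range range of absolute age slopes (log2 units/year).
#' @param gender_offset_range range of absolute gender offsets (log2 units).
#' @param batch_offset_sd sd of the per-dataset per-feature additive batch
#'   offset.
#' @param var_prior_df prior degrees of freedom d0 of the noise-variance
#'   distribution.
#' @param var_prior_scale prior scale s0^2 of the noise-variance
#'   distribution.
#' @param seed integer seed; all sub-streams are derived from it by fixed
#'   offsets.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = list(A = c(AD = 143, MCI = 77, CTL = 104),
                                          B = c(AD = 102, MCI = 65, CTL = 78)),
                       n_features = 2000,
                       deg_fraction = 0.2,
                       deg_effect_range = c(0.1, 0.5),
                       mci_attenuation = 1.2,
                       concordance_target = 1.0,
                       panel_features = 4,
                       panel_effect = 1.0,
                       age_mean = 75, age_sd = 6.5,
                       age_slope_fraction = 0.3,
                       age_slope_range = c(0.01, 0.05),
                       gender_offset_range = c(0.05, 0.2),
                       batch_offset_sd = 0.5,
                       var_prior_df = 4,
                       var_prior_scale = 0.05,
                       seed = 1) {
  cfg <- list(n_per_group = n_per_group, n_features = as.integer(n_features),
              deg_fraction = deg_fraction, deg_effect_range = deg_effect_range,
              mci_attenuation = mci_attenuation,
              concordance_target = concordance_target,
              panel_features = as.integer(panel_features),
              panel_effect = panel_effect,
              age_mean = age_mean, age_sd = age_sd,
              age_slope_fraction = age_slope_fraction,
              age_slope_range = age_slope_range,
              gender_offset_range = gender_offset_range,
              batch_offset_sd = batch_offset_sd,
              var_prior_df = var_prior_df, var_prior_scale = var_prior_scale,
              seed = as.integer(seed))
  stopifnot(is.list(n_per_group), all(c("A", "B") %in% names(n_per_group)))
  for (d in c("A", "B"))
    stopifnot(all(c("AD", "MCI", "CTL") %in% names(n_per_group[[d]])),
              all(n_per_group[[d]] >= 0))
  frac <- c(cfg$deg_fraction, cfg$concordance_target, cfg$age_slope_fraction)
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$n_features < cfg$panel_features)
    stop("n_features must be at least panel_features")
  if (cfg$mci_attenuation <= 0 || cfg$mci_attenuation > 2)
    stop("mci_attenuation must be in (0, 2]")
  sds <- c(cfg$age_sd, cfg$batch_offset_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (cfg$var_prior_df <= 0 || cfg$var_prior_scale <= 0)
    stop("variance prior parameters must be positive")
  if (cfg$panel_effect < 0) stop("panel_effect must be >= 0")
  structure(cfg, class = "sim_config")
}

# Signed uniform draws on +/-[lo, hi]
.signed_runif <- function(n, range) {
  sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, range[1], range[2])
}

.simulate_samples <- function(counts, prefix, cfg) {
  groups <- rep(c("AD", "MCI", "CTL"), counts[c("AD", "MCI", "CTL")])
  n <- length(groups)
  data.frame(
    sample_id = sprintf("%s_s%04d", prefix, seq_len(n)),
    group = groups,
    age = pmax(45, stats::rnorm(n, cfg$age_mean, cfg$age_sd)),
    gender = sample(c("M", "F"), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

#' Generate two synthetic cohorts with known ground truth
#'
#' Expression for feature g, sample i is
#' `baseline_g + batch_{d,g} + group effect + slope_g (age_i - age_mean) +
#'  gamma_g 1[female] + N(0, sigma_g)`, with `sigma_g^2` drawn from a
#' scaled inverse-chi-square prior `s0^2 d0 / chisq(d0)`. DEG features get
#' an AD effect `delta_g` and an MCI effect `mci_attenuation * delta_g`
#' (direction flipped for a `1 - concordance_target` fraction). Panel
#' features additionally separate AD from CTL by `panel_effect * sigma_g`
#' (MCI receives `mci_attenuation` times that separation). The same seed
#' always reproduces the same draws.
#'
#' @param config a [sim_config()].
#' @return A list with elements `datasets` (two [expression_dataset()]s
#'   named A and B), `sample_info` (two data.frames), and `truth` (all
#'   planted quantities; see Details).
#' @export
generate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  G <- config$n_features
  n_deg <- round(config$deg_fraction * G)
  if (n_deg < 1)
    stop("deg_fraction * n_features < 1: no DEG can be planted")

  # stream 1: feature-level parameters
  set.seed(config$seed)
  feature_ids <- sprintf("f%05d", seq_len(G))
  baseline <- stats::rnorm(G, 8, 1.5)
  sigma2 <- config$var_prior_scale * config$var_prior_df /
    stats::rchisq(G, df = config$var_prior_df)
  deg_idx <- sort(sample.int(G, n_deg))
  delta_ad <- .signed_runif(n_deg, config$deg_effect_range)
  n_flip <- round((1 - config$concordance_target) * n_deg)
  flip <- rep(FALSE, n_deg)
  if (n_flip > 0) flip[sample.int(n_deg, n_flip)] <- TRUE
  delta_mci <- config$mci_attenuation * delta_ad * ifelse(flip, -1, 1)
  panel_idx <- sort(sample.int(G, config$panel_features))
  slope <- numeric(G)
  n_slope <- round(config$age_slope_fraction * G)
  if (n_slope > 0) {
    slope_idx <- sample.int(G, n_slope)
    slope[slope_idx] <- .signed_runif(n_slope, config$age_slope_range)
  }
  gender_off <- numeric(G)
  if (n_slope > 0) {
    gender_idx <- sample.int(G, n_slope)
    gender_off[gender_idx] <- .signed_runif(n_slope, config$gender_offset_range)
  }
  batch <- cbind(A = stats::rnorm(G, 0, config$batch_offset_sd),
                 B = stats::rnorm(G, 0, config$batch_offset_sd))

  eff_ad <- numeric(G); eff_ad[deg_idx] <- delta_ad
  eff_mci <- numeric(G); eff_mci[deg_idx] <- delta_mci
  sigma <- sqrt(sigma2)

  build <- function(label, stream_offset) {
    # stream 2/3: per-dataset samples and noise
    set.seed(config$seed + stream_offset)
    info <- .simulate_samples(config$n_per_group[[label]], label, config)
    n <- nrow(info)
    is_ad <- info$group == "AD"
    is_mci <- info$group == "MCI"
    is_f <- info$gender == "F"
    m <- matrix(baseline + batch[, label], nrow = G, ncol = n)
    m <- m + outer(eff_ad, as.numeric(is_ad)) +
      outer(eff_mci, as.numeric(is_mci)) +
      outer(slope, info$age - config$age_mean) +
      outer(gender_off, as.numeric(is_f))
    sep <- config$panel_effect * sigma[panel_idx]
    m[panel_idx, is_ad] <- m[panel_idx, is_ad] + sep
    m[panel_idx, is_mci] <- m[panel_idx, is_mci] +
      config$mci_attenuation * sep
    m <- m + matrix(stats::rnorm(G * n, 0, sigma), nrow = G, ncol = n)
    dimnames(m) <- list(feature_ids, info$sample_id)
    list(ds = expression_dataset(m, label), info = info)
  }
  A <- build("A", 1L)
  B <- build("B", 2L)

  truth <- list(
    deg = data.frame(feature_id = feature_ids[deg_idx],
                     delta_ad = delta_ad, delta_mci = delta_mci,
                     stringsAsFactors = FALSE),
    panel = data.frame(feature_id = feature_ids[panel_idx],
                       delta = rep(config$panel_effect,
                                   config$panel_features),
                       overlaps_deg = feature_ids[panel_idx] %in%
                         feature_ids[deg_idx],
                       stringsAsFactors = FALSE),
    covariate_slopes = stats::setNames(slope, feature_ids),
    gender_offsets = stats::setNames(gender_off, feature_ids),
    batch_offsets = list(A = stats::setNames(batch[, "A"], feature_ids),
                         B = stats::setNames(batch[, "B"], feature_ids)),
    noise_variances = stats::setNames(sigma2, feature_ids),
    baseline = stats::setNames(baseline, feature_ids),
    config = unclass(config))

  list(datasets = list(A = A$ds, B = B$ds),
       sample_info = list(A = A$info, B = B$info),
       truth = truth)
}

#' Write the ground-truth object of a simulation as JSON
#'
#' @param truth the `truth` element of [generate_cohorts()] output.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  # named numeric vectors become JSON objects so the names survive
  for (nm in c("covariate_slopes", "gender_offsets", "noise_variances",
               "baseline"))
    if (!is.null(truth[[nm]])) truth[[nm]] <- as.list(truth[[nm]])
  if (!is.null(truth$batch_offsets))
    truth$batch_offsets <- lapply(truth$batch_offsets, as.list)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a simulation ground-truth JSON back
#'
#' @param path path written by [write_truth()].
#' @return A list mirroring the original truth object.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("covariate_slopes", "gender_offsets", "noise_variances",
               "baseline"))
    if (!is.null(tr[[nm]])) tr[[nm]] <- unlist(tr[[nm]])
  if (!is.null(tr$batch_offsets))
    tr$batch_offsets <- lapply(tr$batch_offsets, unlist)
  tr
}

#' Generate two feature lists with a prescribed overlap odds ratio
#'
#' Solves, for the expected overlap count `a`, the cross-product equation
#' `a d / (b c) = target_or` under the fixed margins (`b = n_listA - a`,
#' `c = n_listB - a`, `d = n_universe - n_listA - n_listB + a`), rounds
#' `a`, then samples memberships consistent with those counts. A
#' `concordance` fraction of the overlapping features share regulation
#' direction between the two lists.
#'
#' @param n_universe,n_listA,n_listB universe and list sizes.
#' @param target_or desired odds ratio (> 0).
#' @param concordance fraction of overlap with the same direction.
#' @param seed integer seed.
#' @return list with data.frames `listA`, `listB` (columns `feature_id`,
#'   `direction`) and `truth` (the 2x2 counts and targets).
#' @export
generate_overlap_lists <- function(n_universe, n_listA, n_listB, target_or,
                                   concordance, seed) {
  if (n_listA > n_universe || n_listB > n_universe)
    stop("list sizes cannot exceed the universe size")
  if (target_or <= 0) stop("target_or must be positive")
  if (concordance < 0 || concordance > 1)
    stop("concordance must lie in [0, 1]")
  N <- n_universe; nA <- n_listA; nB <- n_listB; or <- target_or
  if (abs(or - 1) < 1e-12) {
    a_exp <- nA * nB / N
  } else {
    # (1-or) a^2 + (N - nA - nB + or (nA + nB)) a - or nA nB = 0
    qa <- 1 - or
    qb <- N - nA - nB + or * (nA + nB)
    qc <- -or * nA * nB
    disc <- qb^2 - 4 * qa * qc
    roots <- (-qb + c(1, -1) * sqrt(disc)) / (2 * qa)
    lo <- max(0, nA + nB - N); hi <- min(nA, nB)
    feasible <- roots[roots >= lo - 1e-9 & roots <= hi + 1e-9]
    if (!length(feasible))
      stop("no feasible overlap count for these margins and target_or")
    a_exp <- feasible[1L]
  }
  a <- as.integer(round(a_exp))
  a <- max(max(0L, nA + nB - N), min(a, min(nA, nB)))
  set.seed(seed)
  ids <- sprintf("g%06d", seq_len(N))
  overlap <- sample(ids, a)
  rest <- setdiff(ids, overlap)
  onlyA <- sample(rest, nA - a)
  onlyB <- sample(setdiff(rest, onlyA), nB - a)
  dirA <- stats::setNames(sample(c("up", "down"), nA, replace = TRUE),
                          c(overlap, onlyA))
  n_conc <- round(concordance * a)
  dirB_overlap <- dirA[overlap]
  if (a > n_conc) {
    disc_idx <- sample.int(a, a - n_conc)
    dirB_overlap[disc_idx] <- ifelse(dirB_overlap[disc_idx] == "up",
                                     "down", "up")
  }
  dirB <- c(dirB_overlap,
            stats::setNames(sample(c("up", "down"), nB - a, replace = TRUE),
                            onlyB))
  listA <- data.frame(feature_id = names(dirA), direction = unname(dirA),
                      stringsAsFactors = FALSE)
  listB <- data.frame(feature_id = names(dirB), direction = unname(dirB),
                      stringsAsFactors = FALSE)
  list(listA = listA, listB = listB,
       truth = list(a = a, b = nA - a, c = nB - a, d = N - nA - nB + a,
                    n_universe = N, target_or = target_or,
                    concordance_target = concordance,
                    n_concordant = sum(dirB_overlap == dirA[overlap])),
       universe = ids)
}

#' Generate a gene-set collection with planted enrichment
#'
#' Non-planted sets draw members uniformly from the universe; a planted
#' set with fold enrichment `f` draws members with sampling weight `f`
#' for genes in `deg_list` and 1 otherwise, so DEG genes are
#' overrepresented roughly `f`-fold relative to background.
#'
#' @param n_genes universe size (gene ids `g000001`...).
#' @param n_sets number of sets.
#' @param set_size_range integer pair, inclusive range of set sizes.
#' @param planted data.frame with columns `set_index`, `fold_enrichment`
#'   (may have zero rows).
#' @param deg_list character vector of DEG gene ids (subset of universe).
#' @param seed integer seed.
#' @return list with `sets` (a `gene_set_collection`), `universe`, and
#'   `truth` (planted indices, folds, realized hit counts).
#' @export
generate_genesets <- function(n_genes, n_sets, set_size_range, planted,
                              deg_list, seed) {
  stopifnot(set_size_range[1] >= 1, set_size_range[2] <= n_genes)
  if (nrow(planted) && any(planted$set_index > n_sets))
    stop("planted set_index exceeds n_sets")
  if (nrow(planted) && any(planted$fold_enrichment <= 0))
    stop("fold_enrichment must be positive")
  set.seed(seed)
  ids <- sprintf("g%06d", seq_len(n_genes))
  if (length(setdiff(deg_list, ids)))
    stop("deg_list contains ids outside the universe")
  is_deg <- ids %in% deg_list
  if (nrow(planted) && any(planted$fold_enrichment > 1) && !any(is_deg))
    stop("cannot plant enrichment: deg_list is empty in the universe")
  folds <- rep(1, n_sets)
  if (nrow(planted)) folds[planted$set_index] <- planted$fold_enrichment
  sizes <- set_size_range[1] +
    sample.int(set_size_range[2] - set_size_range[1] + 1L, n_sets,
               replace = TRUE) - 1L
  sets <- vector("list", n_sets)
  for (j in seq_len(n_sets)) {
    w <- ifelse(is_deg, folds[j], 1)
    sets[[j]] <- sample(ids, sizes[j], prob = w)
  }
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  hits <- vapply(sets, function(s) sum(s %in% deg_list), integer(1))
  list(sets = structure(sets, class = "gene_set_collection"),
       universe = ids,
       truth = list(planted = planted, set_sizes = sizes,
                    realized_hits = hits))
}

#' Optimal AUC of a single Gaussian feature with standardized shift delta
#'
#' For one feature with equal-variance Gaussian class conditionals
#' separated by `delta` standard deviations, the Bayes-optimal classifier
#' attains AUC `Phi(delta / sqrt(2))`. Used as a closed-form calibration
#' oracle for the classifier stack.
#'
#' @param delta nonnegative standardized mean difference.
#' @return AUC in `[0.5, 1)`.
#' @export
planted_bayes_auc <- function(delta) {
  if (any(delta < 0)) stop("delta must be nonnegative")
  stats::pnorm(delta / sqrt(2))
}
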