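#' Default parameters of the skewed trait generator
#'
#' The trait (alpha-amylase activity in U/g of flour) is drawn from a
#' two-component log-normal mixture: a bulk component concentrated below
#' 0.2 U/g and a heavy right-tail component reaching roughly 8 U/g. The
#' defaults are calibrated so that the expected fraction of values below
#' 0.2 U/g is 0.88 and draws lie within [0.01, 10] (truncation bounds).
#'
#' @return a list with components \code{weights}, \code{meanlog},
#'   \code{sdlog} (each length 2: bulk, tail), and truncation bounds
#'   \code{lower}, \code{upper}.
#' @export
trait_mixture_defaults <- function() {
  list(weights = c(0.88, 0.12),
       meanlog = c(log(0.105), log(0.9)),
       sdlog   = c(0.25, 0.8),
       lower = 0.01, upper = 10)
}

#' Generate trait values from a skewed two-component mixture
#'
#' @param n number of values to draw (>= 1).
#' @param mixture_params mixture configuration, see
#'   [trait_mixture_defaults()]. A component with \code{sdlog = 0} is a point
#'   mass at \code{exp(meanlog)}.
#' @param seed integer seed; the draw is fully reproducible.
#' @return numeric vector of \code{n} activities in U/g, all within the
#'   truncation bounds.
#' @export
generate_trait <- function(n, mixture_params = trait_mixture_defaults(),
                           seed = NULL) {
  stopifnot(n >= 1)
  p <- mixture_params
  w <- p$weights
  if (any(w < 0) || any(w > 1) || abs(sum(w) - 1) > 1e-8)
    stop("mixture weights must lie in [0,1] and sum to 1")
  with_seed(seed, {
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    x <- exp(p$meanlog[comp] + p$sdlog[comp] * stats::rnorm(n))
    pmin(pmax(x, p$lower), p$upper)
  })
}

#' Default configuration of the synthetic cohort generator
#'
#' The defaults emulate, at desk scale (300 wheat samples x 2,000 peptide
#' clusters), the structure of the study cohort: a skewed trait, QC injections
#' every 48 samples, an internal-standard cluster, injection-order intensity
#' drift resetting at each mass-calibration event, categorical technical
#' factors with 4 (LC column) / 6 (mass calibration) / 2 (capillary) levels,
#' planted trait-correlated peptides, low-abundance-biased intensity
#' missingness, and a 5.4% trait-missing fraction.
#'
#' @param n_samples number of wheat (non-QC) samples.
#' @param n_features number of peptide clusters (one of which is the internal
#'   standard).
#' @param n_biomarkers number of planted trait-associated features.
#' @param qc_interval QC injection spacing (one QC every \code{qc_interval}
#'   injections).
#' @param noise_sd SD of the log-scale measurement noise for wheat samples.
#' @param qc_noise_sd SD of the log-scale noise for pooled QC injections.
#' @param factor_sd SD of the per-level technical-factor offsets (log scale).
#' @param drift_range per-injection fractional decay range of the sensitivity
#'   drift within each mass-calibration interval.
#' @param effect_range magnitude range of the planted biomarker slopes on the
#'   standardized-inverse trait scale (log-intensity units per SD).
#' @param weight_jitter half-width (mg) of the flour-weight tolerance around
#'   the 20 mg nominal aliquot.
#' @param trait_missing_fraction fraction of wheat samples with unmeasured
#'   trait.
#' @param mixture_params trait mixture, see [trait_mixture_defaults()].
#' @param intensity_meanlog,intensity_sdlog log-normal distribution of the
#'   per-feature baseline abundances.
#' @param sensitivity_range range of the per-feature sensitivity multiplier
#'   applied to technical offsets and drift.
#' @param miss_max,miss_center_offset,miss_width logistic intensity-missingness
#'   model: a cell at log-intensity L is censored with probability
#'   \code{miss_max * plogis((center - L) / miss_width)} where \code{center =
#'   intensity_meanlog - miss_center_offset}.
#' @param factor_breaks list of run-fraction breakpoints for the
#'   \code{lc_column}, \code{mass_cal} and \code{capillary} level blocks
#'   (non-aligned so the additive design stays full rank).
#' @return a configuration list.
#' @export
cohort_config <- function(n_samples = 300, n_features = 2000,
                          n_biomarkers = 60, qc_interval = 48,
                          noise_sd = 0.40, qc_noise_sd = 0.20,
                          factor_sd = 0.30, drift_range = c(0.001, 0.004),
                          effect_range = c(0.5, 1.0), weight_jitter = 0.2,
                          trait_missing_fraction = 0.054,
                          mixture_params = trait_mixture_defaults(),
                          intensity_meanlog = log(1e5),
                          intensity_sdlog = 1.2,
                          sensitivity_range = c(0.25, 1.75),
                          miss_max = 0.6, miss_center_offset = 2.4,
                          miss_width = 0.8,
                          factor_breaks = list(
                            lc_column = c(0.27, 0.52, 0.74),
                            mass_cal = c(0.15, 0.33, 0.50, 0.68, 0.85),
                            capillary = 0.45)) {
  cfg <- as.list(environment())
  if (cfg$n_biomarkers >= cfg$n_features)
    stop("n_biomarkers must be smaller than n_features")
  if (cfg$qc_interval <= 0) stop("qc_interval must be positive")
  cfg
}

# Number of injections needed so that n_samples wheat samples remain after
# inserting one QC every qc_interval injections.
.n_injections <- function(n_samples, qc_interval) {
  n_inj <- n_samples
  repeat {
    nxt <- n_samples + (n_inj %/% qc_interval)
    if (nxt == n_inj) return(n_inj)
    n_inj <- nxt
  }
}

.cut_levels <- function(order, n_inj, breaks) {
  findInterval(order / n_inj, breaks) + 1L
}

#' Generate a seeded synthetic cohort with ground truth
#'
#' Builds a raw-stage [lcms_matrix()] carrying log-normal baseline feature
#' abundances, a flour-weight loading multiplier, a spiked internal-standard
#' cluster, QC injections at regular intervals, planted biomarkers whose
#' log-intensities shift proportionally to the standardized-inverse trait,
#' injected technical-factor offsets and injection-order drift (via
#' [inject_technical_effects()]), low-abundance-biased intensity missingness,
#' and a trait-missing mask. The returned truth object records everything
#' needed for parameter-recovery tests.
#'
#' Planted slopes are expressed on the standardized-inverse trait scale, on
#' which high trait activity maps to low values; a biomarker with positive
#' slope on this scale therefore accumulates in low-trait samples and its
#' expected two-bin direction (high-trait bin minus low-trait bin) is "down".
#'
#' @param config a [cohort_config()] list.
#' @param seed integer seed; identical (config, seed) pairs produce
#'   bit-identical cohorts.
#' @return list with elements \code{matrix} (raw-stage \code{lcms_matrix}) and
#'   \code{truth} (see Details).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  cfg <- config
  with_seed(seed, {
    n_inj <- .n_injections(cfg$n_samples, cfg$qc_interval)
    qc_orders <- seq(cfg$qc_interval, n_inj, by = cfg$qc_interval)
    wheat_orders <- setdiff(seq_len(n_inj), qc_orders)

    ## ---- sample metadata -------------------------------------------------
    n_qc <- length(qc_orders)
    trait <- generate_trait(cfg$n_samples, cfg$mixture_params, seed = NULL)
    n_tmiss <- floor(cfg$trait_missing_fraction * cfg$n_samples)
    tmiss <- sample.int(cfg$n_samples, n_tmiss)
    trait_obs <- trait
    trait_obs[tmiss] <- NA_real_
    weights <- 20 + stats::runif(cfg$n_samples, -cfg$weight_jitter,
                                 cfg$weight_jitter)
    smp <- data.frame(
      sample_id = c(sprintf("S%04d", seq_len(cfg$n_samples)),
                    sprintf("QC%02d", seq_len(n_qc))),
      injection_order = c(wheat_orders, qc_orders),
      flour_weight_mg = c(weights, rep(NA_real_, n_qc)),
      is_qc = rep(c(FALSE, TRUE), c(cfg$n_samples, n_qc)),
      stringsAsFactors = FALSE)
    ord <- smp$injection_order
    smp$lc_column <- .cut_levels(ord, n_inj, cfg$factor_breaks$lc_column)
    smp$mass_cal <- .cut_levels(ord, n_inj, cfg$factor_breaks$mass_cal)
    smp$capillary <- .cut_levels(ord, n_inj, cfg$factor_breaks$capillary)
    smp$trait_u_per_g <- c(trait_obs, rep(NA_real_, n_qc))
    smp$trait_imputed <- FALSE

    ## ---- feature metadata ------------------------------------------------
    nf <- cfg$n_features
    mz <- stats::runif(nf, 300.13, 1921.55)
    charge <- sample(2:7, nf, replace = TRUE)
    feat <- data.frame(
      cluster_id = sprintf("Cluster_%05d", seq_len(nf)),
      rt_min = stats::runif(nf, 2, 38),
      mz = mz,
      mass_da = (mz - 1.00728) * charge,
      charge = charge,
      is_internal_standard = FALSE,
      is_trait_row = FALSE,
      stringsAsFactors = FALSE)
    is_idx <- 1L
    feat$cluster_id[is_idx] <- "Cluster_IS"
    feat$is_internal_standard[is_idx] <- TRUE

    ## ---- ground truth ----------------------------------------------------
    bm_idx <- if (cfg$n_biomarkers > 0)
      sample(setdiff(seq_len(nf), is_idx), cfg$n_biomarkers) else integer(0)
    bm_sign <- rep_len(c(1, -1), cfg$n_biomarkers)
    bm_effect <- bm_sign * stats::runif(cfg$n_biomarkers,
                                        cfg$effect_range[1],
                                        cfg$effect_range[2])
    n_levels <- c(lc_column = max(smp$lc_column),
                  mass_cal = max(smp$mass_cal),
                  capillary = max(smp$capillary))
    factor_effects <- lapply(n_levels, function(k) {
      e <- stats::rnorm(k, 0, cfg$factor_sd)
      e - mean(e)   # identifiable: offsets sum to zero per factor
    })
    drift_params <- stats::runif(max(smp$mass_cal), cfg$drift_range[1],
                                 cfg$drift_range[2])
    sensitivity <- stats::runif(nf, cfg$sensitivity_range[1],
                                cfg$sensitivity_range[2])
    sensitivity[is_idx] <- 0.6

    ## ---- log-intensity assembly -------------------------------------------
    mu <- cfg$intensity_meanlog + cfg$intensity_sdlog * stats::rnorm(nf)
    mu[is_idx] <- cfg$intensity_meanlog + log(5)
    ns <- nrow(smp)
    noise <- matrix(stats::rnorm(nf * ns), nf, ns)
    noise[, smp$is_qc] <- cfg$qc_noise_sd * noise[, smp$is_qc]
    noise[, !smp$is_qc] <- cfg$noise_sd * noise[, !smp$is_qc]
    noise[is_idx, ] <- 0.125 * noise[is_idx, ]  # IS measured precisely
    L <- mu + noise
    loading <- log(weights / 20)
    L[, !smp$is_qc] <- sweep(L[, !smp$is_qc, drop = FALSE], 2, loading, "+")
    if (cfg$n_biomarkers > 0) {
      inv <- 1 / trait   # underlying biology uses the full trait, masked or not
      z_inv <- (inv - mean(inv)) / stats::sd(inv)
      L[bm_idx, !smp$is_qc] <- L[bm_idx, !smp$is_qc, drop = FALSE] +
        bm_effect %o% z_inv
    }

    mat <- lcms_matrix(exp(L), feat, smp, stage = "raw")
    truth <- list(
      biomarker_ids = feat$cluster_id[bm_idx],
      biomarker_effect = stats::setNames(bm_effect, feat$cluster_id[bm_idx]),
      expected_direction = stats::setNames(
        ifelse(bm_effect > 0, "down", "up"), feat$cluster_id[bm_idx]),
      drift_params = drift_params,
      factor_effects = factor_effects,
      feature_sensitivity = stats::setNames(sensitivity, feat$cluster_id),
      seed = seed,
      config = cfg)
    mat <- inject_technical_effects(mat, truth)

    ## ---- intensity missingness (never the IS row) -------------------------
    Lx <- log(mat$values)
    center <- cfg$intensity_meanlog - cfg$miss_center_offset
    p_miss <- cfg$miss_max * stats::plogis((center - Lx) / cfg$miss_width)
    drop <- matrix(stats::runif(nf * ns), nf, ns) < p_miss
    drop[is_idx, ] <- FALSE
    mat$values[drop] <- NA_real_

    list(matrix = mat, truth = truth)
  })
}

#' Inject technical-factor offsets and injection-order drift
#'
#' Technical effects are multiplicative on intensity (additive on the log
#' scale): each sample receives its factor-level offsets and a geometric
#' sensitivity decay per injection within its mass-calibration interval
#' (reset at each maintenance event), both modulated by a per-feature
#' sensitivity multiplier.
#'
#' @param matrix a raw-stage [lcms_matrix()].
#' @param truth a truth list carrying \code{factor_effects} (per-factor
#'   per-level log offsets), \code{drift_params} (per-mass-calibration-interval
#'   per-injection fractional decay), and \code{feature_sensitivity}.
#' @return the matrix with effects applied (stage unchanged).
#' @export
inject_technical_effects <- function(matrix, truth) {
  smp <- matrix$samples
  for (f in names(truth$factor_effects)) {
    lev <- smp[[f]]
    if (anyNA(lev)) stop("sample with undefined level of factor ", f)
    if (max(lev) > length(truth$factor_effects[[f]]))
      stop("sample with undefined level of factor ", f)
  }
  sens <- truth$feature_sensitivity[matrix$features$cluster_id]
  if (anyNA(sens)) sens <- rep(1, nrow(matrix$features))
  sample_offset <- rep(0, nrow(smp))
  for (f in names(truth$factor_effects))
    sample_offset <- sample_offset + truth$factor_effects[[f]][smp[[f]]]
  # geometric drift: (1 - d_m)^(t - t0(m)) within each mass-cal interval
  ord <- smp$injection_order
  interval_start <- tapply(ord, smp$mass_cal, min)[as.character(smp$mass_cal)]
  d <- truth$drift_params[smp$mass_cal]
  sample_offset <- sample_offset + (ord - interval_start) * log(1 - d)
  matrix$values <- matrix$values * exp(sens %o% sample_offset)
  matrix
}

#' Generate an MS2 identification catalog from MS1 features
#'
#' Draws a subset of the MS1 features, jitters their coordinates (normal ppm
#' error on m/z and mass, normal error in minutes on retention time), and
#' attaches 1..k accession identifiers to the identified fraction. The truth
#' mapping (MS2 row to source MS1 cluster) is returned for matching tests.
#'
#' @param features a feature metadata data.frame (\code{cluster_id},
#'   \code{rt_min}, \code{mz}, \code{mass_da}).
#' @param jitter list: \code{ppm_sd} (ppm error SD for m/z and mass),
#'   \code{rt_sd} (minutes), \code{fraction_present} (share of MS1 features
#'   with an MS2 counterpart), \code{fraction_identified} (share of MS2 rows
#'   with accessions), \code{multiplicity} (vector of possible accession
#'   counts per identified row, sampled uniformly).
#' @param seed integer seed.
#' @return list with \code{catalog} (data.frame \code{ms2_id}, \code{rt_min},
#'   \code{mz}, \code{mass_da}, \code{accessions} semicolon-separated,
#'   \code{peptide_sequence}) and \code{truth} (data.frame \code{ms2_id},
#'   \code{source_cluster_id}, \code{n_accessions}).
#' @export
generate_ms2_catalog <- function(features,
                                 jitter = list(ppm_sd = 5, rt_sd = 0.1,
                                               fraction_present = 0.6,
                                               fraction_identified = 0.4,
                                               multiplicity = 1:6),
                                 seed = 1) {
  if (jitter$ppm_sd < 0 || jitter$rt_sd < 0)
    stop("jitter SDs must be non-negative")
  with_seed(seed, {
    n <- nrow(features)
    n_pick <- round(jitter$fraction_present * n)
    pick <- sort(sample.int(n, n_pick))
    src <- features[pick, ]
    mz <- src$mz * (1 + jitter$ppm_sd * 1e-6 * stats::rnorm(n_pick))
    mass <- src$mass_da * (1 + jitter$ppm_sd * 1e-6 * stats::rnorm(n_pick))
    rt <- src$rt_min + jitter$rt_sd * stats::rnorm(n_pick)
    ided <- stats::runif(n_pick) < jitter$fraction_identified
    mult <- integer(n_pick)
    mv <- jitter$multiplicity
    mult[ided] <- mv[sample.int(length(mv), sum(ided), replace = TRUE)]
    acc <- vapply(seq_len(n_pick), function(i) {
      if (!ided[i]) return("")
      paste(sprintf("ACC%05d", sample.int(9000, mult[i])), collapse = ";")
    }, character(1))
    pep <- ifelse(ided, vapply(seq_len(n_pick), function(i)
      paste(sample(c("A", "G", "L", "S", "V", "E", "K", "R"), 10,
                   replace = TRUE), collapse = ""), character(1)), "")
    list(
      catalog = data.frame(ms2_id = sprintf("MS2_%05d", seq_len(n_pick)),
                           rt_min = rt, mz = mz, mass_da = mass,
                           accessions = acc, peptide_sequence = pep,
                           stringsAsFactors = FALSE),
      truth = data.frame(ms2_id = sprintf("MS2_%05d", seq_len(n_pick)),
                         source_cluster_id = src$cluster_id,
                         n_accessions = mult, stringsAsFactors = FALSE))
  })
}

#' Write cohort ground truth as JSON
#'
#' @param truth a truth list from [generate_cohort()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$config <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
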