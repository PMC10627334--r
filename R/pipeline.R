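#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end workflow with defaults
#' matching the study settings: 3-step normalization, ASCA with 100
#' permutations, PLS with 3 latent factors and 10% valid values, PLSR
#' imputation with 20 latent factors and 20% valid values, 6x8 SOM, k = 20
#' k-means, divisive HCA, correlation threshold 0.15, q threshold 0.05,
#' trait threshold 0.17 U/g, 8-bin and 2-bin profiling, and 20 ppm / 1 min
#' identity matching. Every stochastic stage derives its seed from the master
#' seed, and the full configuration is recorded in the run manifest.
#'
#' @param seed master integer seed.
#' @param cohort a [cohort_config()] (used when the simulate stage runs).
#' @param threshold trait split in U/g.
#' @param trait_floor lower clamp applied to (imputed) trait values before
#'   the inverse transform, which is undefined at zero; NULL (default) uses
#'   the smallest measured activity of the cohort, keeping the inverse of
#'   clipped imputations inside the observed inverse range.
#' @param pls_components,pls_valid PLS screen settings.
#' @param impute_components,impute_valid,n_holdout,impute_vip_cut trait
#'   imputation settings (features above \code{impute_vip_cut} VIP are used).
#' @param som_rows,som_cols,kmeans_k,clust_valid,hca_min_size,vip_cut
#'   clustering settings (\code{vip_cut} selects the feature subset).
#' @param corr_threshold,q_threshold union-selection thresholds.
#' @param n_perm ASCA permutations.
#' @param n_boot,two_group_valid two-group test settings.
#' @param ppm_tol,rt_tol_min,ms2_jitter identity-linking settings.
#' @param run_link run the MS2 linking stage.
#' @return a configuration list.
#' @export
pipeline_config <- function(seed = 1, cohort = cohort_config(),
                            threshold = 0.17, trait_floor = NULL,
                            pls_components = 3, pls_valid = 0.10,
                            impute_components = 20, impute_valid = 0.20,
                            n_holdout = 179, impute_vip_cut = 1.5,
                            som_rows = 6, som_cols = 8, kmeans_k = 20,
                            clust_valid = 0.10, hca_min_size = 20,
                            vip_cut = 1.0, corr_threshold = 0.15,
                            q_threshold = 0.05, n_perm = 100,
                            n_boot = 10, two_group_valid = 0.90,
                            ppm_tol = 20, rt_tol_min = 1.0,
                            ms2_jitter = list(ppm_sd = 5, rt_sd = 0.1,
                                              fraction_present = 0.6,
                                              fraction_identified = 0.4,
                                              multiplicity = 1:6),
                            run_link = TRUE) {
  as.list(environment())
}

#' Run the full discovery pipeline on a synthetic cohort
#'
#' Executes simulate -> normalize (weight, IS, drift) -> correct (ASCA before
#' and after, fixed-effect residuals, z-transform, K-S diagnostics) -> trait
#' (missingness, unbiased subset, PLSR imputation, trait-row incorporation)
#' -> discover (PLS-VIP, SOM / k-means / divisive HCA neighbourhoods,
#' correlation and regression screens, union selection) -> profile (8-bin and
#' 2-bin means, two-group test, volcano, heatmap sample order) -> link
#' (synthetic MS2 catalog, ppm/RT matching, wide-to-long identity table).
#' Stage products and a JSON manifest are written under \code{out_dir} when
#' given; identical (config, seed) runs produce byte-identical outputs.
#'
#' @param config a [pipeline_config()] list.
#' @param out_dir output directory for stage CSVs and the manifest; NULL
#'   keeps everything in memory.
#' @return invisible list with all stage results, the ground truth, and
#'   recovery metrics against it.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  emit <- function(obj, name) {
    if (!is.null(out_dir))
      utils::write.csv(obj, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE, na = "")
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  ## ---- simulate ---------------------------------------------------------
  sim <- generate_cohort(cfg$cohort, seed = seed)
  raw <- sim$matrix
  if (!is.null(out_dir)) {
    write_lcms_csv(raw, file.path(out_dir, "matrix_raw.csv"),
                   file.path(out_dir, "sample_meta.csv"))
    write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  }

  ## ---- normalize --------------------------------------------------------
  nw <- normalize_by_weight(raw)
  ni <- normalize_by_internal_standard(nw$matrix)
  nd <- correct_injection_drift(ni$matrix)
  normalized <- drop_qc_samples(nd$matrix)

  ## ---- correct ----------------------------------------------------------
  asca_pre <- asca_effects(normalized, n_perm = cfg$n_perm, seed = seed + 1)
  fitres <- fit_technical_model_residuals(normalized)
  corrected <- fitres$matrix
  asca_post <- asca_effects(corrected, n_perm = cfg$n_perm, seed = seed + 2)
  ks_corrected <- ks_normality(corrected)
  zmat <- z_transform_rows(corrected)
  ks_z <- ks_normality(zmat)

  ## ---- trait ------------------------------------------------------------
  miss <- missingness_report(zmat$samples)
  unbiased <- select_unbiased_subset(zmat$samples, cfg$threshold,
                                     seed = seed + 3)
  z_unb <- subset_lcms(zmat, samples = unbiased)
  pls0 <- fit_pls(z_unb, n_components = cfg$pls_components,
                  valid_fraction = cfg$pls_valid)
  vip_feats <- names(pls0$vip)[pls0$vip > cfg$impute_vip_cut]
  missing_ids <- zmat$samples$sample_id[!zmat$samples$is_qc &
                                          is.na(zmat$samples$trait_u_per_g)]
  imp <- impute_trait_plsr(
    subset_lcms(zmat, features = vip_feats,
                samples = c(unbiased, missing_ids)),
    n_components = cfg$impute_components,
    valid_fraction = cfg$impute_valid, seed = seed + 4,
    n_holdout = cfg$n_holdout, threshold = cfg$threshold)
  trait_full <- zmat$samples$trait_u_per_g
  names(trait_full) <- zmat$samples$sample_id
  got <- imp$trait$trait_imputed
  trait_full[imp$trait$sample_id[got]] <- imp$trait$trait_u_per_g[got]
  zmat$samples$trait_u_per_g <- unname(trait_full)
  zmat$samples$trait_imputed <- zmat$samples$sample_id %in%
    imp$trait$sample_id[got]
  floor_ <- if (is.null(cfg$trait_floor)) {
    min(zmat$samples$trait_u_per_g[!zmat$samples$trait_imputed &
                                     !is.na(zmat$samples$trait_u_per_g)])
  } else cfg$trait_floor
  trait_floored <- pmax(trait_full, floor_)
  ztr <- incorporate_trait_row(zmat, trait_floored)

  ## ---- discover ---------------------------------------------------------
  z_unb2 <- subset_lcms(ztr, samples = unbiased)
  pls <- fit_pls(z_unb2, n_components = cfg$pls_components,
                 valid_fraction = cfg$pls_valid)
  vip_summary <- vip_threshold_summary(pls$vip)
  clust_feats <- union(names(pls$vip_all)[pls$vip_all > cfg$vip_cut],
                       "Cluster_AAA")
  z_clust <- subset_lcms(z_unb2,
                         features = intersect(ztr$features$cluster_id,
                                              clust_feats))
  som <- som_cluster(z_clust, rows = cfg$som_rows, cols = cfg$som_cols,
                     valid_fraction = cfg$clust_valid, seed = seed + 5)
  km <- kmeans_cluster(z_clust, k = cfg$kmeans_k,
                       valid_fraction = cfg$clust_valid, seed = seed + 6)
  hca <- divisive_hca(z_clust, valid_fraction = cfg$clust_valid,
                      min_size = cfg$hca_min_size)
  nb <- list(som = trait_neighbourhood(som),
             kmeans = trait_neighbourhood(km),
             hca = trait_neighbourhood(hca))
  corr <- correlate_with_trait(ztr, corr_threshold = cfg$corr_threshold)
  regr <- regress_on_trait(ztr)
  biomarkers <- select_biomarkers(nb, corr, regr, vip = pls$vip_all,
                                  corr_threshold = cfg$corr_threshold,
                                  q_threshold = cfg$q_threshold)
  emit(biomarkers, "biomarkers")

  ## ---- profile ----------------------------------------------------------
  wheat_trait <- stats::setNames(ztr$samples$trait_u_per_g,
                                 ztr$samples$sample_id)
  bins8 <- bin_means(ztr, assign_bins(wheat_trait, "equal_size_rank",
                                      n_bins = 8))
  unb_trait <- wheat_trait[unbiased]
  bins2 <- assign_bins(unb_trait, "threshold", threshold = cfg$threshold)
  z_bm <- subset_lcms(z_unb2, features = intersect(ztr$features$cluster_id,
                                                   biomarkers$cluster_id))
  tg <- two_group_test(z_bm, bins2, valid_fraction = cfg$two_group_valid,
                       n_boot = cfg$n_boot, seed = seed + 7)
  volcano <- volcano_table(tg, biomarkers)
  emit(volcano, "volcano")
  sample_order <- order_samples_hca(z_bm)

  ## ---- link -------------------------------------------------------------
  link <- NULL
  if (isTRUE(cfg$run_link)) {
    feat1 <- raw$features[!raw$features$is_trait_row &
                            !raw$features$is_internal_standard, ]
    ms2 <- generate_ms2_catalog(feat1, jitter = cfg$ms2_jitter,
                                seed = seed + 8)
    mres <- match_clusters(feat1, ms2$catalog, ppm_tol = cfg$ppm_tol,
                           rt_tol_min = cfg$rt_tol_min)
    idx <- match(mres$pairs$ms2_id, ms2$catalog$ms2_id)
    identified <- data.frame(cluster_id = mres$pairs$ms1_cluster_id,
                             accessions = ms2$catalog$accessions[idx],
                             peptide_sequence =
                               ms2$catalog$peptide_sequence[idx],
                             stringsAsFactors = FALSE)
    long <- expand_wide_to_long(identified)
    emit(mres$pairs, "ms1_ms2_pairs")
    emit(long, "identity_long")
    link <- list(catalog = ms2, matches = mres, long = long)
  }

  recovery <- evaluate_recovery(biomarkers, volcano, sim$truth)

  manifest <- list(
    config = cfg[setdiff(names(cfg), "cohort")],
    cohort = cfg$cohort[!vapply(cfg$cohort, is.list, logical(1))],
    stage_dims = list(raw = dim(raw), normalized = dim(normalized),
                      z = dim(ztr)),
    derived_seeds = seed + 0:8,
    asca_pre_p = asca_pre$p, asca_post_p = asca_post$p,
    ks_D = c(corrected = ks_corrected$ks_D, z = ks_z$ks_D),
    missingness = miss,
    n_unbiased = length(unbiased),
    imputation = imp$report[c("n_imputed", "r2_overall", "r2_high",
                              "r2_low", "clipped_to_zero")],
    vip_summary = vip_summary,
    n_biomarkers_selected = nrow(biomarkers),
    volcano_counts = as.list(attr(volcano, "counts")),
    recovery = recovery,
    match_rate_percent = if (!is.null(link))
      link$matches$match_rate_percent else NULL)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)

  invisible(list(truth = sim$truth, raw = raw, normalized = normalized,
                 asca_pre = asca_pre, asca_post = asca_post,
                 corrected = corrected, z = ztr,
                 ks = list(corrected = ks_corrected, z = ks_z),
                 missingness = miss, unbiased = unbiased,
                 imputation = imp$report, pls = pls,
                 vip_summary = vip_summary,
                 assignments = list(som = som, kmeans = km, hca = hca),
                 neighbourhoods = nb, correlation = corr, regression = regr,
                 biomarkers = biomarkers, bins8 = bins8, bins2 = bins2,
                 two_group = tg, volcano = volcano,
                 sample_order = sample_order, link = link,
                 recovery = recovery, manifest = manifest))
}

#' Recovery of planted biomarkers
#'
#' Compares a selection table and its volcano directions with the generator
#' ground truth: precision and recall of the selected set against the planted
#' ids, and the fraction of recovered biomarkers whose two-bin direction
#' matches the planted slope's expected direction (a positive slope on the
#' standardized-inverse scale accumulates in low-trait samples, hence
#' direction "down").
#'
#' @param biomarkers a [select_biomarkers()] table.
#' @param volcano a [volcano_table()] data.frame (may be NULL to skip the
#'   direction check).
#' @param truth the generator truth list.
#' @return list \code{n_selected}, \code{n_true}, \code{precision},
#'   \code{recall}, \code{direction_agreement}.
#' @export
evaluate_recovery <- function(biomarkers, volcano, truth) {
  sel <- biomarkers$cluster_id
  tru <- truth$biomarker_ids
  tp <- length(intersect(sel, tru))
  agree <- NA_real_
  if (!is.null(volcano) && nrow(volcano)) {
    hit <- volcano$cluster_id[volcano$cluster_id %in% tru]
    if (length(hit)) {
      expect <- truth$expected_direction[hit]
      got <- volcano$direction[match(hit, volcano$cluster_id)]
      agree <- mean(got == expect)
    }
  }
  list(n_selected = length(sel), n_true = length(tru),
       precision = if (length(sel)) tp / length(sel) else NA_real_,
       recall = if (length(tru)) tp / length(tru) else NA_real_,
       direction_agreement = agree)
}
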