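#' Transform trait values
#'
#' The raw trait (activity in U/g) is heavily right-skewed; the inverse
#' function brings it close to normality, and its standardized form
#' (\code{std_inverse}: \code{(1/x - mean)/SD} over non-missing entries) is
#' the scale on which the trait joins the peptide matrix as a pseudo-feature.
#' Note that the inverse family reverses order: high activity maps to low
#' transformed values.
#'
#' @param values numeric trait vector (may be named by sample id); missing
#'   propagates.
#' @param method one of \code{"ln"}, \code{"log2"}, \code{"inverse"},
#'   \code{"std_inverse"}.
#' @return the transformed vector.
#' @export
transform_trait <- function(values, method = c("std_inverse", "inverse",
                                               "ln", "log2")) {
  method <- match.arg(method)
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    ids <- if (!is.null(names(values))) names(values)[bad] else which(bad)
    stop("non-positive trait value under ", method, " transform for: ",
         paste(ids, collapse = ", "))
  }
  switch(method,
         ln = log(values),
         log2 = log2(values),
         inverse = 1 / values,
         std_inverse = {
           inv <- 1 / values
           (inv - mean(inv, na.rm = TRUE)) / stats::sd(inv, na.rm = TRUE)
         })
}

#' Select a balanced ("unbiased") sample subset
#'
#' The trait distribution is skewed towards low activities; to restore
#' balance, all samples at or above the threshold are kept and an equal-sized
#' simple random sample (without replacement, seeded) of below-threshold
#' samples joins them.
#'
#' @param meta sample-metadata data.frame (\code{sample_id},
#'   \code{trait_u_per_g}, \code{is_qc}); QC and trait-missing samples are
#'   ignored.
#' @param threshold activity threshold in U/g.
#' @param seed integer seed for the low-trait draw.
#' @return character vector of sample ids, high-trait samples first; its
#'   length is twice the high-trait count.
#' @export
select_unbiased_subset <- function(meta, threshold = 0.17, seed = 1) {
  usable <- !meta$is_qc & !is.na(meta$trait_u_per_g)
  ids <- meta$sample_id[usable]
  trait <- meta$trait_u_per_g[usable]
  high <- ids[trait >= threshold]
  low <- ids[trait < threshold]
  if (length(high) > length(low))
    stop("more samples at/above the threshold than below it; ",
         "balanced subsetting is undefined")
  if (length(high) == 0) return(character(0))
  picked <- with_seed(seed, sample(low, length(high)))
  c(high, picked)
}

#' Impute missing trait values by univariate PLS regression
#'
#' Fits a NIPALS PLS1 model of the trait on the peptide matrix (samples with a
#' measured trait as training observations; features filtered to at least
#' \code{valid_fraction} non-missing values over the training samples and
#' row-mean imputed), validates it on a seeded hold-out spanning the trait
#' range (stratified over 10 equal-width trait strata), then predicts the
#' trait for trait-missing samples. Negative predictions are clipped to zero
#' and counted.
#'
#' @param matrix an [lcms_matrix()] (z stage recommended); columns are the
#'   samples to train on / impute.
#' @param n_components number of latent factors.
#' @param valid_fraction minimum fraction of non-missing values per feature.
#' @param seed integer seed for the hold-out draw.
#' @param n_holdout requested hold-out size; capped at a quarter of the
#'   training samples (capping is flagged in the report).
#' @param threshold activity split for the high/low validation accuracies.
#' @return list with \code{trait} (data.frame \code{sample_id},
#'   \code{trait_u_per_g}, \code{trait_imputed}) and \code{report}
#'   (\code{n_imputed}, \code{r2_overall}, \code{r2_high}, \code{r2_low},
#'   \code{clipped_to_zero}, \code{holdout_ids}, \code{holdout_capped},
#'   \code{n_features_used}).
#' @export
impute_trait_plsr <- function(matrix, n_components = 20,
                              valid_fraction = 0.20, seed = 1,
                              n_holdout = 179, threshold = 0.17) {
  smp <- matrix$samples
  train <- which(!smp$is_qc & !is.na(smp$trait_u_per_g))
  target <- which(!smp$is_qc & is.na(smp$trait_u_per_g))
  if (length(train) < 10) stop("too few trait-measured samples to train on")
  keep_feat <- !matrix$features$is_trait_row
  fi <- .filter_impute_rows(matrix$values[keep_feat, train, drop = FALSE],
                            valid_fraction)
  Xtr <- t(fi$values)
  ytr <- smp$trait_u_per_g[train]

  ## hold-out validation stratified over 10 equal-width trait strata
  cap <- max(5L, floor(length(train) / 4))
  hold_n <- min(n_holdout, cap)
  hold_idx <- with_seed(seed, {
    strata <- cut(ytr, breaks = seq(min(ytr), max(ytr), length.out = 11),
                  include.lowest = TRUE)
    per <- ceiling(hold_n / nlevels(strata))
    picked <- unlist(lapply(split(seq_along(ytr), strata), function(i)
      if (length(i)) sample(i, min(per, length(i))) else integer(0)))
    if (length(picked) > hold_n) picked <- sort(sample(picked, hold_n))
    sort(picked)
  })
  # guard against overfit on small cohorts: at most one latent factor per
  # ten training observations (the full-scale default of 20 is unaffected)
  ncomp_eff <- function(n_obs) max(2L, min(n_components, ncol(Xtr),
                                           n_obs %/% 10, n_obs - 1L))
  clamp <- function(p) pmin(p, max(ytr))   # never extrapolate above training
  fit_v <- pls1_nipals(Xtr[-hold_idx, , drop = FALSE], ytr[-hold_idx],
                       ncomp_eff(length(train) - length(hold_idx)))
  pred_v <- clamp(predict_pls1(fit_v, Xtr[hold_idx, , drop = FALSE]))
  obs_v <- ytr[hold_idx]
  r2 <- function(o, p) if (length(o) > 2 && stats::sd(o) > 0 &&
                           stats::sd(p) > 0) stats::cor(o, p)^2 else NA_real_
  hi <- obs_v > threshold

  ## final model on all training samples, applied to trait-missing samples
  fit <- pls1_nipals(Xtr, ytr, ncomp_eff(length(train)))
  clipped <- 0L
  trait_out <- data.frame(sample_id = smp$sample_id,
                          trait_u_per_g = smp$trait_u_per_g,
                          trait_imputed = smp$trait_imputed,
                          stringsAsFactors = FALSE)
  if (length(target)) {
    Vt <- matrix$values[keep_feat, target, drop = FALSE][fi$keep, ,
                                                         drop = FALSE]
    if (anyNA(Vt)) {
      rm_ <- rowMeans(fi$values)
      idx <- which(is.na(Vt), arr.ind = TRUE)
      Vt[idx] <- rm_[idx[, 1]]
    }
    pred <- clamp(predict_pls1(fit, t(Vt)))
    clipped <- sum(pred < 0)
    pred[pred < 0] <- 0
    trait_out$trait_u_per_g[target] <- pred
    trait_out$trait_imputed[target] <- TRUE
  }
  report <- list(n_imputed = length(target),
                 r2_overall = r2(obs_v, pred_v),
                 r2_high = r2(obs_v[hi], pred_v[hi]),
                 r2_low = r2(obs_v[!hi], pred_v[!hi]),
                 clipped_to_zero = clipped,
                 holdout_ids = smp$sample_id[train][hold_idx],
                 holdout_capped = hold_n < n_holdout,
                 n_features_used = length(fi$keep))
  list(trait = trait_out, report = report)
}

#' Incorporate the trait as pseudo-feature "Cluster_AAA"
#'
#' Appends one extra row holding the standardized-inverse trait of every
#' sample, so that clustering and screening methods can group peptides that
#' behave like (or conversely to) the trait. The matrix must be at the
#' z-transformed stage and every sample must carry a trait value (imputed
#' values allowed). Removing the row restores the input exactly.
#'
#' @param matrix a z-stage [lcms_matrix()].
#' @param trait numeric vector of raw trait values named by sample id, or a
#'   data.frame with \code{sample_id} and \code{trait_u_per_g}.
#' @return the matrix with the added trait row (\code{cluster_id}
#'   \code{"Cluster_AAA"}, \code{is_trait_row = TRUE}).
#' @export
incorporate_trait_row <- function(matrix, trait) {
  require_stage(matrix, "z", "incorporate_trait_row")
  if (any(matrix$features$is_trait_row))
    stop("matrix already carries a trait row")
  if (is.data.frame(trait))
    trait <- stats::setNames(trait$trait_u_per_g, trait$sample_id)
  vals <- trait[matrix$samples$sample_id]
  if (anyNA(vals))
    stop("trait missing for sample(s): ",
         paste(matrix$samples$sample_id[is.na(vals)], collapse = ", "))
  z <- transform_trait(unname(vals), "std_inverse")
  matrix$values <- rbind(matrix$values,
                         matrix(z, 1, ncol(matrix$values),
                                dimnames = list("Cluster_AAA", NULL)))
  matrix$features <- rbind(matrix$features,
                           .complete_feature_meta(
                             data.frame(cluster_id = "Cluster_AAA",
                                        is_trait_row = TRUE)))
  validate_lcms_matrix(matrix)
  matrix
}

#' Trait missingness report
#'
#' @param meta sample-metadata data.frame with \code{is_qc} and
#'   \code{trait_u_per_g}.
#' @return list \code{n_total} (non-QC samples), \code{n_missing}, and
#'   \code{percent_missing} (one decimal).
#' @export
missingness_report <- function(meta) {
  wheat <- !meta$is_qc
  n_total <- sum(wheat)
  n_missing <- sum(wheat & is.na(meta$trait_u_per_g))
  list(n_total = n_total, n_missing = n_missing,
       percent_missing = round(100 * n_missing / n_total, 1))
}
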