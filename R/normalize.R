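#' Three-step normalization cascade
#'
#' Label-free intensities are normalized in a fixed order matching the
#' acquisition design: (1) flour-weight scaling to cancel sample-preparation
#' loading differences, (2) internal-standard scaling to cancel post-digestion
#' technical variation, (3) QC-anchored correction of injection-order
#' sensitivity drift. Each step returns the transformed matrix together with a
#' \code{normalization_report} (per-sample scaling factors and per-feature QC
#' coefficients of variation before/after). Missing values are never imputed.
#'
#' @name normalize
NULL

.qc_cv <- function(m) {
  qc <- m$values[, m$samples$is_qc, drop = FALSE]
  if (ncol(qc) < 2) return(rep(NA_real_, nrow(qc)))
  mu <- rowMeans(qc, na.rm = TRUE)
  sd_ <- apply(qc, 1, stats::sd, na.rm = TRUE)
  sd_ / mu
}

.norm_report <- function(step, factors, cv_before, cv_after, flagged = character(0)) {
  structure(list(step = step, per_sample_factor = factors,
                 qc_cv_before = cv_before, qc_cv_after = cv_after,
                 flagged_features = flagged),
            class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("normalization_report (step: ", x$step, ")\n", sep = "")
  cat("  samples scaled: ", length(x$per_sample_factor),
      "; median factor: ", signif(stats::median(x$per_sample_factor), 4),
      "\n", sep = "")
  if (length(x$flagged_features))
    cat("  features on global drift curve: ", length(x$flagged_features),
        "\n", sep = "")
  invisible(x)
}

#' Flour-weight normalization
#'
#' Each wheat sample's intensities are multiplied by
#' \code{nominal_weight / flour_weight_mg}, cancelling the loading variation of
#' the 20 mg (nominal) flour aliquot. QC injections of the pooled sample carry
#' no flour weight and are left unscaled (factor 1).
#'
#' @param matrix a raw-stage [lcms_matrix()].
#' @param nominal_weight nominal aliquot mass in mg.
#' @return list \code{matrix} (stage \code{"weight"}) and \code{report}.
#' @export
normalize_by_weight <- function(matrix, nominal_weight = 20) {
  require_stage(matrix, "raw", "normalize_by_weight")
  w <- matrix$samples$flour_weight_mg
  qc <- matrix$samples$is_qc
  bad <- !qc & (is.na(w) | w <= 0)
  if (any(bad))
    stop("missing or non-positive flour weight for sample(s): ",
         paste(matrix$samples$sample_id[bad], collapse = ", "))
  fac <- ifelse(qc, 1, nominal_weight / w)
  cv0 <- .qc_cv(matrix)
  matrix$values <- sweep(matrix$values, 2, fac, "*")
  matrix <- set_stage(matrix, "weight")
  rep_ <- .norm_report("weight",
                       stats::setNames(fac, matrix$samples$sample_id),
                       cv0, .qc_cv(matrix))
  list(matrix = matrix, report = rep_)
}

#' Internal-standard normalization
#'
#' Each sample is divided by the ratio of its internal-standard (IS) intensity
#' to the median IS intensity across all samples; the IS feature becomes
#' constant afterwards. The IS is spiked post-digestion, so this step absorbs
#' post-digestion sample-to-sample technical variation.
#'
#' @param matrix an [lcms_matrix()] at stage \code{"weight"}.
#' @return list \code{matrix} (stage \code{"is"}) and \code{report}.
#' @export
normalize_by_internal_standard <- function(matrix) {
  require_stage(matrix, "weight", "normalize_by_internal_standard")
  is_idx <- which(matrix$features$is_internal_standard)
  if (length(is_idx) != 1) stop("matrix must carry exactly one IS feature")
  is_row <- matrix$values[is_idx, ]
  bad <- is.na(is_row)
  if (any(bad))
    stop("IS intensity missing in sample(s): ",
         paste(matrix$samples$sample_id[bad], collapse = ", "))
  if (any(is_row <= 0))
    stop("IS intensity must be positive in every sample")
  fac <- is_row / stats::median(is_row)
  cv0 <- .qc_cv(matrix)
  matrix$values <- sweep(matrix$values, 2, fac, "/")
  matrix <- set_stage(matrix, "is")
  rep_ <- .norm_report("internal_standard",
                       stats::setNames(fac, matrix$samples$sample_id),
                       cv0, .qc_cv(matrix))
  list(matrix = matrix, report = rep_)
}

#' QC-anchored injection-order drift correction
#'
#' Instrument sensitivity drifts over a long acquisition run; pooled QC
#' injections at fixed intervals anchor its estimation. Per feature, the drift
#' curve is the piecewise-linear interpolation of the feature's QC intensities
#' across injection order (constant extrapolation beyond the first/last QC),
#' rescaled to its median QC level, and divided out at every sample's
#' injection position — so the median QC level is preserved. Features observed
#' in fewer than half of the QCs fall back to a global drift curve (per-QC
#' median of feature-wise ratios to the feature's QC median) and are flagged
#' in the report.
#'
#' @param matrix an [lcms_matrix()] at stage \code{"is"}.
#' @return list \code{matrix} (stage \code{"drift"}) and \code{report}.
#' @export
correct_injection_drift <- function(matrix) {
  require_stage(matrix, "is", "correct_injection_drift")
  qc <- matrix$samples$is_qc
  if (sum(qc) < 2) stop("drift correction needs at least 2 QC samples")
  ord <- matrix$samples$injection_order
  if (anyNA(ord)) stop("all samples need a known injection order")
  qc_ord <- ord[qc]
  qv <- matrix$values[, qc, drop = FALSE]
  n_qc <- ncol(qv)
  qc_med <- apply(qv, 1, stats::median, na.rm = TRUE)

  # global curve: per-QC median of feature ratios to their QC median
  ratio <- qv / qc_med
  global_anchor <- apply(ratio, 2, stats::median, na.rm = TRUE)

  n_obs <- rowSums(!is.na(qv))
  use_global <- n_obs < pmax(2, ceiling(n_qc / 2))
  cv0 <- .qc_cv(matrix)
  out <- matrix$values
  o <- order(qc_ord)
  for (f in seq_len(nrow(out))) {
    if (use_global[f]) {
      anchors <- global_anchor
    } else {
      anchors <- qv[f, ] / qc_med[f]
    }
    ok <- !is.na(anchors)
    if (sum(ok) < 2) { anchors <- global_anchor; ok <- !is.na(anchors) }
    curve <- stats::approx(qc_ord[ok], anchors[ok], xout = ord,
                           rule = 2)$y
    out[f, ] <- out[f, ] / curve
  }
  matrix$values <- out
  matrix <- set_stage(matrix, "drift")
  rep_ <- .norm_report("drift",
                       stats::setNames(rep(1, ncol(out)),
                                       matrix$samples$sample_id),
                       cv0, .qc_cv(matrix),
                       flagged = matrix$features$cluster_id[use_global])
  list(matrix = matrix, report = rep_)
}
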