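#' ASCA quantification of technical-factor effects
#'
#' ANOVA simultaneous component analysis partitions the variance of a
#' multivariate dataset by designed fixed factors. Per factor, the effect
#' matrix assigns each sample the mean profile of its level (after grand-mean
#' centring per feature); its sum of squares over the total sum of squares is
#' the factor's variance fraction. Significance is assessed by permuting that
#' factor's sample labels and recomputing the effect sum of squares:
#' \code{p = (1 + #(SS_perm >= SS_obs)) / (n_perm + 1)}, so the smallest
#' attainable p with 100 permutations is 1/101. Samples with incomplete factor
#' metadata are dropped; missing intensities are imputed to zero first
#' (matching the preprocessing used for the full-cohort decompositions).
#'
#' @param matrix an [lcms_matrix()].
#' @param factors character vector of sample-metadata factor columns.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutations.
#' @return an \code{asca_result}: data.frame with one row per factor
#'   (\code{factor}, \code{variance_fraction}, \code{p}) plus attributes
#'   \code{residual_fraction} and \code{n_permutations}.
#' @export
asca_effects <- function(matrix, factors = c("lc_column", "mass_cal",
                                             "capillary"),
                         n_perm = 100, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  meta <- matrix$samples[factors]
  complete <- stats::complete.cases(meta)
  if (!any(complete)) stop("no samples with complete factor metadata")
  X <- t(matrix$values[, complete, drop = FALSE])  # samples x features
  X[is.na(X)] <- 0
  X <- sweep(X, 2, colMeans(X))
  ss_total <- sum(X^2)
  meta <- meta[complete, , drop = FALSE]

  ss_between <- function(g) {
    # sum over levels of n_l * ||mean_l||^2, computed via level sums
    sums <- rowsum(X, g)
    n_l <- as.vector(table(g)[rownames(sums)])
    sum(sums^2 / n_l)
  }

  res <- with_seed(seed, {
    lapply(factors, function(f) {
      g <- meta[[f]]
      if (length(unique(g)) < 2)
        stop("factor ", f, " has a single level; no variance attributable")
      ss_obs <- ss_between(g)
      exceed <- sum(vapply(seq_len(n_perm), function(i)
        ss_between(sample(g)) >= ss_obs, logical(1)))
      c(vf = ss_obs / ss_total, p = (1 + exceed) / (n_perm + 1))
    })
  })
  out <- data.frame(factor = factors,
                    variance_fraction = vapply(res, `[`, 0, "vf"),
                    p = vapply(res, `[`, 0, "p"),
                    stringsAsFactors = FALSE)
  attr(out, "residual_fraction") <- 1 - sum(out$variance_fraction)
  attr(out, "n_permutations") <- n_perm
  class(out) <- c("asca_result", "data.frame")
  out
}

#' Per-feature fixed-effect correction: fit and keep residuals
#'
#' Fits, independently for every feature, the additive fixed-effect model
#' \deqn{Y = u + Column(i) + MassCal(j) + Cap(k) + e}
#' by ordinary least squares with sum-to-zero level constraints, and returns
#' the matrix of residuals as the corrected data. Missing cells are dropped
#' from each feature's fit (never imputed to zero here, which would bias the
#' level effects) and stay missing in the output. Samples with incomplete
#' factor metadata are not corrected: they are passed through centred on the
#' feature mean and flagged. Residuals of complete observations are orthogonal
#' to every factor-level indicator (within-level sums are zero) and
#' \code{fitted + residual} reconstructs the input exactly.
#'
#' @param matrix an [lcms_matrix()] at stage \code{"drift"}.
#' @param factors sample-metadata columns entering the model.
#' @return list with \code{matrix} (residuals, stage \code{"corrected"}),
#'   \code{model} (per-feature coefficient data.frame: grand mean and
#'   sum-to-zero level effects), \code{uncorrected_samples} (ids passed
#'   through centred-only), and \code{rank_deficient} (flagged feature ids).
#' @export
fit_technical_model_residuals <- function(matrix,
                                          factors = c("lc_column", "mass_cal",
                                                      "capillary")) {
  require_stage(matrix, "drift", "fit_technical_model_residuals")
  meta <- matrix$samples[factors]
  complete <- stats::complete.cases(meta)
  fl <- lapply(factors, function(f) factor(meta[[f]][complete]))
  names(fl) <- factors
  use <- vapply(fl, function(f) nlevels(f) > 1, logical(1))
  design <- if (any(use)) {
    stats::model.matrix(~ ., data = as.data.frame(fl[use]),
                        contrasts.arg = lapply(fl[use],
                                               function(x) "contr.sum"))
  } else {
    matrix(1, sum(complete), 1, dimnames = list(NULL, "(Intercept)"))
  }
  V <- matrix$values[, complete, drop = FALSE]
  nf <- nrow(V)
  res <- V
  coefs <- matrix(NA_real_, nf, ncol(design),
                  dimnames = list(matrix$features$cluster_id,
                                  colnames(design)))
  rank_def <- logical(nf)
  for (f in seq_len(nf)) {
    y <- V[f, ]
    ok <- !is.na(y)
    if (sum(ok) <= ncol(design)) { rank_def[f] <- TRUE; next }
    fit <- stats::lm.fit(design[ok, , drop = FALSE], y[ok])
    if (fit$rank < ncol(design)) rank_def[f] <- TRUE
    res[f, ok] <- fit$residuals
    coefs[f, ] <- fit$coefficients
  }
  out <- matrix$values
  out[, complete] <- res
  # incomplete-metadata samples: centred on the feature mean, flagged
  if (any(!complete)) {
    mu <- rowMeans(V, na.rm = TRUE)
    out[, !complete] <- matrix$values[, !complete, drop = FALSE] - mu
  }
  matrix$values <- out
  matrix <- set_stage(matrix, "corrected")
  list(matrix = matrix,
       model = as.data.frame(coefs),
       uncorrected_samples = matrix$samples$sample_id[!complete],
       rank_deficient = matrix$features$cluster_id[rank_def])
}

#' Row-wise z-transform
#'
#' Centres and scales each feature row to mean 0 and SD 1 (denominator n-1)
#' over its finite values; missing stays missing. Constant rows (zero spread)
#' are emitted as all zeros and flagged in the \code{"constant_rows"}
#' attribute. Applying the transform twice equals applying it once, and
#' between-row Pearson correlations are preserved.
#'
#' @param matrix an [lcms_matrix()] at stage \code{"corrected"} or \code{"z"}.
#' @return the transformed matrix (stage \code{"z"}).
#' @export
z_transform_rows <- function(matrix) {
  if (!matrix$stage %in% c("corrected", "z"))
    stop("z_transform_rows expects a matrix at stage 'corrected' (or 'z'), ",
         "got '", matrix$stage, "'")
  v <- matrix$values
  mu <- rowMeans(v, na.rm = TRUE)
  sd_ <- apply(v, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(sd_) & sd_ == 0
  sd_[const | is.na(sd_)] <- 1
  matrix$values <- (v - mu) / sd_
  matrix$values[const, ] <- ifelse(is.na(v[const, , drop = FALSE]), NA_real_, 0)
  matrix <- set_stage(matrix, "z")
  attr(matrix, "constant_rows") <- matrix$features$cluster_id[const]
  matrix
}

# Asymptotic Kolmogorov distribution tail: P(sqrt(n) D > lambda).
.kolmogorov_p <- function(d, n) {
  lambda <- (sqrt(n) + 0.12 + 0.11 / sqrt(n)) * d
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Pools all finite values of the matrix, standardizes them, and computes
#' \code{D = sup |F_n - Phi|} over the empirical-CDF jump points against the
#' standard normal CDF, with an asymptotic p-value. Used as a distribution
#' diagnostic of the corrected and z-transformed stages (the z-transform
#' reduces but does not abolish the departure from normality).
#'
#' @param matrix an [lcms_matrix()] (any stage).
#' @param n_bins number of histogram bins retained in the report.
#' @return a \code{normality_report} list: \code{ks_D}, \code{ks_p},
#'   \code{histogram_bins} (counts), \code{breaks}, \code{n}, \code{stage_tag}.
#' @export
ks_normality <- function(matrix, n_bins = 30) {
  x <- matrix$values[is.finite(matrix$values)]
  if (length(x) < 10) stop("need at least 10 finite values")
  z <- sort((x - mean(x)) / stats::sd(x))
  n <- length(z)
  phi <- stats::pnorm(z)
  d <- max(seq_len(n) / n - phi, phi - (seq_len(n) - 1) / n)
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  structure(list(ks_D = d, ks_p = .kolmogorov_p(d, n),
                 histogram_bins = h$counts, breaks = h$breaks, n = n,
                 stage_tag = matrix$stage),
            class = "normality_report")
}

#' PCA overview of samples
#'
#' Centred principal component analysis with samples as observations (scores)
#' and features as variables (loadings); missing values are imputed to zero
#' for the decomposition, consistent with [asca_effects()]. Used to visualise
#' how each normalization/correction stage reshapes the sample cloud (e.g. the
#' injection-order gradient visible before correction and absent after).
#'
#' @param matrix an [lcms_matrix()].
#' @param n_components number of components (<= min(dim)).
#' @return list: \code{scores} (samples x components), \code{loadings}
#'   (features x components), \code{variance_explained} (per component,
#'   decreasing), \code{stage_tag}.
#' @export
pca_overview <- function(matrix, n_components = 2) {
  X <- t(matrix$values)
  X[is.na(X)] <- 0
  if (n_components > min(dim(X)))
    stop("n_components exceeds the matrix rank bound")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x,
       loadings = pc$rotation,
       variance_explained = ve[seq_len(n_components)],
       stage_tag = matrix$stage)
}
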