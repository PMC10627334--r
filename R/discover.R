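#' Fit a PLS model of the trait on the peptide matrix and score VIP
#'
#' Features are the variables (filtered to at least \code{valid_fraction}
#' non-missing values over the used samples, then row-mean imputed), samples
#' the observations, and the response is the standardized-inverse trait.
#' The model is a NIPALS PLS1 fit; per-feature Variable Importance in
#' Projection scores are
#' \deqn{VIP_j = \sqrt{p \sum_a SS_a w_{ja}^2 / \sum_a SS_a}}
#' with \eqn{SS_a} the response variance captured by component \eqn{a} and
#' unit-norm weight vectors, so mean(VIP^2) = 1 by construction. If the trait
#' pseudo-row is present it takes part in the fit but is excluded from the
#' returned VIP ranking.
#'
#' @param matrix an [lcms_matrix()] (z stage recommended).
#' @param response numeric response per sample (defaults to the
#'   standardized-inverse of the sample-metadata trait).
#' @param n_components number of latent factors.
#' @param valid_fraction minimum non-missing fraction per feature.
#' @return a \code{pls_vip} list: the fitted \code{model}, \code{vip} (named,
#'   trait row excluded), \code{vip_all} (named, including the trait row),
#'   \code{features_used}, \code{explained_y_variance}.
#' @export
fit_pls <- function(matrix, response = NULL, n_components = 3,
                    valid_fraction = 0.10) {
  if (is.null(response)) {
    response <- transform_trait(matrix$samples$trait_u_per_g, "std_inverse")
  }
  if (anyNA(response)) stop("response must be complete on the used samples")
  fi <- .filter_impute_rows(matrix$values, valid_fraction)
  ids <- matrix$features$cluster_id[fi$keep]
  model <- pls1_nipals(t(fi$values), response,
                       min(n_components, length(fi$keep),
                           ncol(matrix$values) - 1))
  vip <- stats::setNames(pls1_vip(model), ids)
  trait_ids <- matrix$features$cluster_id[matrix$features$is_trait_row]
  structure(list(model = model,
                 vip = vip[setdiff(ids, trait_ids)],
                 vip_all = vip,
                 features_used = ids,
                 explained_y_variance = model$explained_y_variance),
            class = "pls_vip")
}

#' Summarise VIP counts above thresholds
#'
#' @param vip numeric VIP scores.
#' @param thresholds ascending thresholds; counts are strictly greater-than.
#' @param n_total denominator of the percentages (defaults to
#'   \code{length(vip)}).
#' @return data.frame with \code{threshold}, \code{count}, \code{percent}
#'   (nearest integer).
#' @export
vip_threshold_summary <- function(vip, thresholds = c(0.5, 1.0, 1.5),
                                  n_total = length(vip)) {
  if (n_total == 0) stop("n_total must be positive")
  if (is.unsorted(thresholds)) stop("thresholds must be sorted ascending")
  counts <- vapply(thresholds, function(t) sum(vip > t), integer(1))
  data.frame(threshold = thresholds, count = counts,
             percent = vapply(counts, .percent, integer(1), total = n_total))
}

## ---- correlation-distance clustering engines --------------------------------

# Shared preparation: filter features by valid fraction, row-mean impute,
# row-standardize (centre, unit norm). Positive correlation distance between
# two profiles is 1 - r; on unit-norm rows r is a plain dot product.
.cluster_prep <- function(matrix, valid_fraction) {
  fi <- .filter_impute_rows(matrix$values, valid_fraction)
  ru <- .row_unit(fi$values)
  list(z = ru$z, ids = matrix$features$cluster_id[fi$keep],
       trait_id = matrix$features$cluster_id[matrix$features$is_trait_row])
}

# Correlation of unit rows with (arbitrary-scale) centroids.
.cor_to_centroids <- function(z, centroids) {
  cs <- .row_unit(centroids)$z
  tcrossprod(z, cs)
}

# k-means under positive correlation distance with mean centroids.
# init: row indices of the starting centroids. Ties break to the lowest group.
.corr_kmeans <- function(z, k, max_iter = 50, init) {
  centroids <- z[init, , drop = FALSE]
  assign_prev <- rep(0L, nrow(z))
  for (iter in seq_len(max_iter)) {
    r <- .cor_to_centroids(z, centroids)
    assign_ <- max.col(r, ties.method = "first")
    for (g in seq_len(k)) {               # revive empty groups
      if (!any(assign_ == g)) {
        worst <- which.min(r[cbind(seq_len(nrow(z)), assign_)])
        assign_[worst] <- g
      }
    }
    if (identical(assign_, assign_prev)) break
    assign_prev <- assign_
    centroids <- rowsum(z, assign_) /
      as.vector(table(factor(assign_, levels = seq_len(k))))
  }
  r <- .cor_to_centroids(z, centroids)
  list(assignment = assign_,
       distance = 1 - r[cbind(seq_len(nrow(z)), assign_)],
       centroids = centroids)
}

# Deterministic 2-means split: initialise with the farthest pair (ties to the
# lowest indices). Returns NULL when the members are indistinguishable.
.split_two <- function(z) {
  m <- nrow(z)
  r <- tcrossprod(z)
  d <- 1 - r
  far <- arrayInd(which.max(d), dim(d))
  if (d[far[1], far[2]] < 1e-12) return(NULL)
  km <- .corr_kmeans(z, 2, max_iter = 50,
                     init = sort(c(far[1], far[2])))
  if (length(unique(km$assignment)) < 2) return(NULL)
  km$assignment
}

#' Batch self-organising map of feature profiles
#'
#' Features are mapped onto a rectangular grid by a batch SOM under positive
#' correlation distance: profiles are row-standardized, codebooks are
#' initialised from a seeded sample of features, and at each iteration every
#' feature is assigned to its best-matching unit (highest correlation, ties to
#' the lowest unit index) and codebooks are updated as Gaussian-neighbourhood
#' weighted means, with the neighbourhood radius shrinking linearly from
#' \code{max(rows, cols)/2} to 1.
#'
#' @param matrix an [lcms_matrix()] (features in rows).
#' @param rows,cols grid dimensions.
#' @param max_iter number of batch iterations.
#' @param valid_fraction minimum non-missing fraction per feature.
#' @param seed integer seed (codebook initialisation).
#' @return a \code{cluster_assignment}: data.frame \code{cluster_id},
#'   \code{label} ("row,col"), \code{som_row}, \code{som_col},
#'   \code{distance} (1 - correlation to the unit codebook), with attributes
#'   \code{method} and \code{trait_id}.
#' @export
som_cluster <- function(matrix, rows = 6, cols = 8, max_iter = 50,
                        valid_fraction = 0.10, seed = 1) {
  prep <- .cluster_prep(matrix, valid_fraction)
  z <- prep$z
  n_units <- rows * cols
  if (n_units > nrow(z)) stop("SOM grid larger than the feature count")
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  gd2 <- as.matrix(stats::dist(grid))^2
  code <- with_seed(seed, z[sample.int(nrow(z), n_units), , drop = FALSE])
  r0 <- max(rows, cols) / 2
  for (it in seq_len(max_iter)) {
    r_t <- r0 + (1 - r0) * (it - 1) / max(1, max_iter - 1)
    cor_ <- .cor_to_centroids(z, code)
    bmu <- max.col(cor_, ties.method = "first")
    h <- exp(-gd2 / (2 * r_t^2))          # units x units neighbourhood
    wsum <- matrix(0, n_units, ncol(z))
    present <- rowsum(z, bmu)
    wsum[as.integer(rownames(present)), ] <- present
    wcnt <- as.vector(table(factor(bmu, levels = seq_len(n_units))))
    num <- h %*% wsum
    den <- as.vector(h %*% wcnt)
    nz <- den > 0
    code[nz, ] <- num[nz, , drop = FALSE] / den[nz]
  }
  cor_ <- .cor_to_centroids(z, code)
  bmu <- max.col(cor_, ties.method = "first")
  out <- data.frame(cluster_id = prep$ids,
                    label = paste(grid$row[bmu], grid$col[bmu], sep = ","),
                    som_row = grid$row[bmu], som_col = grid$col[bmu],
                    distance = 1 - cor_[cbind(seq_len(nrow(z)), bmu)],
                    stringsAsFactors = FALSE)
  structure(out, method = "som", trait_id = prep$trait_id,
            class = c("cluster_assignment", "data.frame"))
}

#' k-means clustering of feature profiles under correlation distance
#'
#' @param matrix an [lcms_matrix()].
#' @param k number of groups.
#' @param max_iter iteration cap.
#' @param valid_fraction minimum non-missing fraction per feature.
#' @param seed integer seed (initial centroids are seeded feature samples).
#' @param nstart number of seeded restarts; the run with the smallest total
#'   within-group correlation distance is kept (k-means local optima are a
#'   known hazard and restarts are the standard remedy).
#' @return a \code{cluster_assignment}: data.frame \code{cluster_id},
#'   \code{label} (group index), \code{distance} to the group centroid, with
#'   attributes \code{method}, \code{trait_id},
#'   \code{overall_variance_explained} and \code{group_variance_explained}.
#' @export
kmeans_cluster <- function(matrix, k = 20, max_iter = 50,
                           valid_fraction = 0.10, seed = 1, nstart = 10) {
  prep <- .cluster_prep(matrix, valid_fraction)
  z <- prep$z
  if (k > nrow(z)) stop("k exceeds the feature count")
  inits <- with_seed(seed, lapply(seq_len(nstart), function(i)
    sort(sample.int(nrow(z), k))))
  runs <- lapply(inits, function(init) .corr_kmeans(z, k, max_iter, init))
  km <- runs[[which.min(vapply(runs, function(r) sum(r$distance),
                               numeric(1)))]]
  # variance explained in the Euclidean embedding of the correlation distance
  gmean <- colMeans(z)
  tot <- sum(sweep(z, 2, gmean)^2)
  wthn <- vapply(seq_len(k), function(g) {
    zi <- z[km$assignment == g, , drop = FALSE]
    if (!nrow(zi)) return(0)
    sum(sweep(zi, 2, colMeans(zi))^2)
  }, numeric(1))
  totg <- vapply(seq_len(k), function(g) {
    zi <- z[km$assignment == g, , drop = FALSE]
    if (!nrow(zi)) return(0)
    sum(sweep(zi, 2, gmean)^2)
  }, numeric(1))
  out <- data.frame(cluster_id = prep$ids,
                    label = km$assignment,
                    distance = km$distance,
                    stringsAsFactors = FALSE)
  structure(out, method = "kmeans", trait_id = prep$trait_id,
            overall_variance_explained = 1 - sum(wthn) / tot,
            group_variance_explained = ifelse(totg > 0, 1 - wthn / totg, NA),
            class = c("cluster_assignment", "data.frame"))
}

#' Divisive hierarchical clustering by recursive 2-means bisection
#'
#' Top-down clustering under positive correlation distance: starting from one
#' cluster holding all features, the recursion splits every cluster larger
#' than \code{min_size} with a deterministic 2-means (initialised at the
#' farthest pair of members), laying the two children out depth-first with the
#' child containing the lowest original feature index first. Leaves give each
#' feature an order index (tree leaf order) and a terminal-cluster id.
#' Clusters whose members are indistinguishable become leaves regardless of
#' size.
#'
#' @param matrix an [lcms_matrix()].
#' @param valid_fraction minimum non-missing fraction per feature.
#' @param min_size clusters at or below this size are not split further.
#' @return a \code{cluster_assignment}: data.frame \code{cluster_id},
#'   \code{label} (terminal cluster id), \code{order} (leaf order index),
#'   with attributes \code{method} and \code{trait_id}.
#' @export
divisive_hca <- function(matrix, valid_fraction = 0.10, min_size = 20) {
  prep <- .cluster_prep(matrix, valid_fraction)
  z <- prep$z
  n <- nrow(z)
  leaves <- list()
  recurse <- function(idx) {
    if (length(idx) <= min_size) { leaves[[length(leaves) + 1]] <<- idx; return() }
    split_ <- .split_two(z[idx, , drop = FALSE])
    if (is.null(split_)) { leaves[[length(leaves) + 1]] <<- idx; return() }
    a <- idx[split_ == 1]; b <- idx[split_ == 2]
    if (min(a) > min(b)) { tmp <- a; a <- b; b <- tmp }
    recurse(a); recurse(b)
  }
  recurse(seq_len(n))
  order_idx <- integer(n)
  leaf_id <- integer(n)
  pos <- 0L
  for (li in seq_along(leaves)) {
    idx <- leaves[[li]]
    order_idx[idx] <- pos + seq_along(idx)
    leaf_id[idx] <- li
    pos <- pos + length(idx)
  }
  out <- data.frame(cluster_id = prep$ids, label = leaf_id,
                    order = order_idx, stringsAsFactors = FALSE)
  structure(out, method = "hca_divisive", trait_id = prep$trait_id,
            class = c("cluster_assignment", "data.frame"))
}

#' Features sharing the trait pseudo-row's cluster
#'
#' The trait row ("Cluster_AAA") is planted into the matrix precisely so that
#' unsupervised groupings reveal peptides behaving like the trait: its SOM
#' cell, k-means group or divisive-HCA terminal cluster is the trait
#' neighbourhood.
#'
#' @param assignment a \code{cluster_assignment} containing the trait row.
#' @return character vector of feature ids sharing the trait row's group,
#'   excluding the trait row itself.
#' @export
trait_neighbourhood <- function(assignment) {
  trait_id <- attr(assignment, "trait_id")
  if (length(trait_id) != 1 || !trait_id %in% assignment$cluster_id)
    stop("trait row absent from the cluster assignment")
  lab <- assignment$label[assignment$cluster_id == trait_id]
  setdiff(assignment$cluster_id[assignment$label == lab], trait_id)
}

## ---- bivariate screens ------------------------------------------------------

# Pairwise-complete per-feature statistics against a complete covariate x.
.rowwise_linfit <- function(V, x) {
  keep_x <- !is.na(x)
  V <- V[, keep_x, drop = FALSE]
  x <- x[keep_x]
  M <- !is.na(V)
  V0 <- V; V0[!M] <- 0
  n <- rowSums(M)
  Sx <- as.vector(M %*% x)
  Sxx <- as.vector(M %*% x^2)
  Sy <- rowSums(V0)
  Syy <- rowSums(V0^2)
  Sxy <- as.vector(V0 %*% x)
  vx <- n * Sxx - Sx^2
  vy <- n * Syy - Sy^2
  num <- n * Sxy - Sx * Sy
  r <- num / sqrt(pmax(vx * vy, 0))
  r[vx <= 0 | vy <= 0] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  slope <- ifelse(vx > 0, num / vx, NA_real_)
  list(n = n, r = r, slope = slope)
}

#' Per-feature Pearson correlation with the trait row
#'
#' Correlates every feature with the trait pseudo-row over pairwise-complete
#' observations (minimum overlap \code{min_overlap}); features whose signed
#' correlation reaches \code{corr_threshold} are flagged.
#'
#' @param matrix an [lcms_matrix()] containing the trait row.
#' @param corr_threshold flagging threshold on the signed correlation (the
#'   negative tail is deliberately excluded).
#' @param min_overlap minimum pairwise-complete sample count.
#' @return data.frame \code{cluster_id}, \code{n}, \code{r}, \code{r2},
#'   \code{corr_flag}; the trait row is included (r = 1) and marked by the
#'   \code{trait_id} attribute.
#' @export
correlate_with_trait <- function(matrix, corr_threshold = 0.15,
                                 min_overlap = 10) {
  ti <- which(matrix$features$is_trait_row)
  if (length(ti) != 1) stop("matrix must contain exactly one trait row")
  x <- matrix$values[ti, ]
  fit <- .rowwise_linfit(matrix$values, x)
  r <- fit$r
  r[fit$n < min_overlap] <- NA_real_
  out <- data.frame(cluster_id = matrix$features$cluster_id,
                    n = fit$n, r = r, r2 = r^2,
                    corr_flag = !is.na(r) & r >= corr_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "trait_id") <- matrix$features$cluster_id[ti]
  out
}

#' Per-feature linear regression on the transformed trait
#'
#' Regresses each feature on the (inverse-family-transformed) trait by
#' ordinary least squares over pairwise-complete observations, reports the
#' slope and the two-sided t-test p-value, and adjusts p across all tested
#' features by the Benjamini-Hochberg procedure (q-values). Features with
#' fewer than \code{min_complete} complete cases or no variance are excluded
#' from the BH family (p and q missing). The trait row regressed on itself
#' yields q = 0.
#'
#' @param matrix an [lcms_matrix()] containing the trait row.
#' @param trait transformed trait values per sample; defaults to the trait
#'   row itself (standardized inverse).
#' @param min_complete minimum complete cases per feature.
#' @return data.frame \code{cluster_id}, \code{n}, \code{slope}, \code{p},
#'   \code{q}.
#' @export
regress_on_trait <- function(matrix, trait = NULL, min_complete = 10) {
  ti <- which(matrix$features$is_trait_row)
  if (is.null(trait)) {
    if (length(ti) != 1) stop("matrix must contain a trait row or an ",
                              "explicit trait vector")
    trait <- matrix$values[ti, ]
  }
  fit <- .rowwise_linfit(matrix$values, trait)
  n <- fit$n
  r <- fit$r
  ok <- n >= min_complete & !is.na(r)
  t_ <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, 0))
  p <- ifelse(ok, 2 * stats::pt(-abs(t_), n - 2), NA_real_)
  p[ok & !is.finite(t_)] <- 0       # exact linear relation (the trait row)
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  data.frame(cluster_id = matrix$features$cluster_id, n = n,
             slope = fit$slope, p = p, q = q, stringsAsFactors = FALSE)
}

#' Union biomarker selection
#'
#' A feature is selected if it satisfies at least one criterion: membership in
#' the trait row's SOM cell, k-means group or divisive-HCA terminal cluster,
#' signed correlation at or above \code{corr_threshold} (optionally the
#' squared-correlation reading via \code{use_r2}), or a regression q-value
#' below \code{q_threshold}. All five flags and the underlying statistics are
#' recorded; the trait row itself is excluded from the output.
#'
#' @param neighbourhoods named list of feature-id vectors
#'   (\code{som}, \code{kmeans}, \code{hca}) from [trait_neighbourhood()].
#' @param correlation output of [correlate_with_trait()].
#' @param regression output of [regress_on_trait()] on the same features.
#' @param vip optional named VIP vector to carry into the records.
#' @param corr_threshold,q_threshold selection thresholds.
#' @param use_r2 if \code{TRUE}, the correlation criterion is
#'   \code{r^2 > corr_threshold} irrespective of sign.
#' @return data.frame of selected features: \code{cluster_id}, \code{vip},
#'   \code{r}, \code{r2}, \code{q}, the five criterion flags and
#'   \code{selected} (always \code{TRUE}; the full universe with flags is in
#'   the \code{"universe"} attribute).
#' @export
select_biomarkers <- function(neighbourhoods, correlation, regression,
                              vip = NULL, corr_threshold = 0.15,
                              q_threshold = 0.05, use_r2 = FALSE) {
  trait_id <- attr(correlation, "trait_id")
  ids_c <- setdiff(correlation$cluster_id, trait_id)
  ids_r <- setdiff(regression$cluster_id, trait_id)
  if (!setequal(ids_c, ids_r))
    stop("correlation and regression were computed on different feature sets")
  tab <- data.frame(cluster_id = ids_c, stringsAsFactors = FALSE)
  ci <- match(tab$cluster_id, correlation$cluster_id)
  ri <- match(tab$cluster_id, regression$cluster_id)
  tab$vip <- if (!is.null(vip)) unname(vip[tab$cluster_id]) else NA_real_
  tab$r <- correlation$r[ci]
  tab$r2 <- correlation$r2[ci]
  tab$q <- regression$q[ri]
  tab$som_flag <- tab$cluster_id %in% neighbourhoods$som
  tab$kmeans_flag <- tab$cluster_id %in% neighbourhoods$kmeans
  tab$hca_flag <- tab$cluster_id %in% neighbourhoods$hca
  tab$corr_flag <- if (use_r2) {
    !is.na(tab$r2) & tab$r2 > corr_threshold
  } else {
    !is.na(tab$r) & tab$r >= corr_threshold
  }
  tab$regression_flag <- !is.na(tab$q) & tab$q < q_threshold
  tab$selected <- tab$som_flag | tab$kmeans_flag | tab$hca_flag |
    tab$corr_flag | tab$regression_flag
  out <- tab[tab$selected, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "universe") <- tab
  out
}
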