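#' Bin samples by trait value
#'
#' Two data-reduction schemes over trait-sorted samples:
#' \code{equal_size_rank} stably sorts the samples by increasing trait and
#' cuts contiguous blocks of near-equal size (sizes differ by at most one,
#' remainder going to the earliest bins: 3,990 samples in 8 bins gives six
#' bins of 499 then two of 498); \code{threshold} makes two bins split at an
#' activity value, every sample at or above the threshold landing in bin 2.
#'
#' @param trait numeric trait values named by sample id (or a data.frame with
#'   \code{sample_id} and \code{trait_u_per_g}).
#' @param scheme \code{"equal_size_rank"} or \code{"threshold"}.
#' @param n_bins number of bins (equal-size scheme); must not exceed the
#'   sample count.
#' @param threshold split value in U/g (threshold scheme).
#' @return a \code{bin_profile} list: \code{scheme}, \code{n_bins},
#'   \code{bin_of_sample} (named integer), \code{bin_sizes},
#'   \code{mean_bin_size}.
#' @export
assign_bins <- function(trait, scheme = c("equal_size_rank", "threshold"),
                        n_bins = 8, threshold = 0.17) {
  scheme <- match.arg(scheme)
  if (is.data.frame(trait))
    trait <- stats::setNames(trait$trait_u_per_g, trait$sample_id)
  if (anyNA(trait)) stop("binning needs a complete trait")
  n <- length(trait)
  if (scheme == "equal_size_rank") {
    if (n_bins > n) stop("more bins than samples")
    base <- n %/% n_bins
    rem <- n %% n_bins
    sizes <- c(rep(base + 1L, rem), rep(base, n_bins - rem))
    ord <- order(trait)                     # stable sort by increasing trait
    bin <- integer(n)
    bin[ord] <- rep(seq_len(n_bins), sizes)
  } else {
    n_bins <- 2L
    bin <- ifelse(trait >= threshold, 2L, 1L)
    sizes <- tabulate(bin, 2L)
  }
  structure(list(scheme = scheme, n_bins = as.integer(n_bins),
                 bin_of_sample = stats::setNames(bin, names(trait)),
                 bin_sizes = sizes, mean_bin_size = n / n_bins,
                 threshold = if (scheme == "threshold") threshold else NULL),
            class = "bin_profile")
}

#' Per-feature bin means
#'
#' Averages each feature within every trait bin over non-missing values (a bin
#' with no observation for a feature yields a missing mean); standard errors
#' are retained for the two-bin charts.
#'
#' @param matrix an [lcms_matrix()].
#' @param bins a [assign_bins()] profile covering the matrix samples.
#' @return the \code{bin_profile} augmented with
#'   \code{per_feature_bin_means} and \code{per_feature_bin_se}
#'   (features x bins matrices).
#' @export
bin_means <- function(matrix, bins) {
  b <- bins$bin_of_sample[matrix$samples$sample_id]
  if (anyNA(b)) stop("bins do not cover every sample of the matrix")
  V <- matrix$values
  g <- factor(b, levels = seq_len(bins$n_bins))
  M <- !is.na(V)
  V0 <- V; V0[!M] <- 0
  cnt <- t(rowsum(t(M) + 0, g))
  sums <- t(rowsum(t(V0), g))
  means <- sums / cnt
  means[cnt == 0] <- NA_real_
  sq <- t(rowsum(t(V0^2), g))
  var_ <- (sq - cnt * means^2) / pmax(cnt - 1, 1)
  se <- sqrt(pmax(var_, 0) / cnt)
  se[cnt < 2] <- NA_real_
  dimnames(means) <- dimnames(se) <-
    list(matrix$features$cluster_id, paste0("bin", seq_len(bins$n_bins)))
  bins$per_feature_bin_means <- means
  bins$per_feature_bin_se <- se
  bins
}

#' Two-group test across a threshold binning
#'
#' Per feature, a two-sided Student t test (pooled variance by default, Welch
#' optional) between the two trait bins, with the directed effect size
#' \code{mean(bin2) - mean(bin1)} (on z-scored data this approximates a
#' standardized effect). Features below \code{valid_fraction} non-missing
#' values across the binned samples are dropped. An optional
#' bootstrap-stabilized p (mean analytic p over \code{n_boot} seeded balanced
#' subsamples of equal group size) is reported alongside the analytic p,
#' which is the primary output.
#'
#' @param matrix an [lcms_matrix()].
#' @param bins a two-bin [assign_bins()] profile.
#' @param valid_fraction minimum non-missing fraction per feature.
#' @param n_boot number of balanced resamples (0 disables).
#' @param seed integer seed for the resamples.
#' @param var_equal pooled-variance t test if \code{TRUE}, Welch otherwise.
#' @return data.frame \code{cluster_id}, \code{n1}, \code{n2},
#'   \code{effect_size}, \code{p}, \code{boot_p}, \code{direction}
#'   ("up" iff effect_size > 0, bin2 - bin1 convention).
#' @export
two_group_test <- function(matrix, bins, valid_fraction = 0.90, n_boot = 10,
                           seed = 1, var_equal = TRUE) {
  if (bins$n_bins != 2) stop("two_group_test needs a two-bin profile")
  b <- bins$bin_of_sample[matrix$samples$sample_id]
  if (anyNA(b)) stop("bins do not cover every sample of the matrix")
  V <- matrix$values
  keep <- rowMeans(!is.na(V)) >= valid_fraction
  V <- V[keep, , drop = FALSE]

  tstat <- function(V, b) {
    g1 <- which(b == 1); g2 <- which(b == 2)
    stats_for <- function(idx) {
      Vi <- V[, idx, drop = FALSE]
      M <- !is.na(Vi)
      n <- rowSums(M)
      V0 <- Vi; V0[!M] <- 0
      mu <- rowSums(V0) / n
      ss <- rowSums(V0^2) - n * mu^2
      list(n = n, mu = mu, var = ss / pmax(n - 1, 1))
    }
    s1 <- stats_for(g1); s2 <- stats_for(g2)
    eff <- s2$mu - s1$mu
    if (var_equal) {
      df <- s1$n + s2$n - 2
      sp2 <- ((s1$n - 1) * s1$var + (s2$n - 1) * s2$var) / df
      se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    } else {
      a1 <- s1$var / s1$n; a2 <- s2$var / s2$n
      se <- sqrt(a1 + a2)
      df <- (a1 + a2)^2 / (a1^2 / (s1$n - 1) + a2^2 / (s2$n - 1))
    }
    bad <- s1$n < 2 | s2$n < 2
    if (any(bad)) stop("a group has fewer than 2 values for feature(s): ",
                       paste(rownames(V)[bad], collapse = ", "))
    t_ <- eff / se
    p <- 2 * stats::pt(-abs(t_), df)
    p[se == 0 & eff == 0] <- 1
    list(effect = eff, p = p, n1 = s1$n, n2 = s2$n)
  }
  base <- tstat(V, b)
  boot_p <- rep(NA_real_, nrow(V))
  if (n_boot > 0) {
    g1 <- which(b == 1); g2 <- which(b == 2)
    m <- min(length(g1), length(g2))
    boot <- with_seed(seed, {
      acc <- matrix(0, nrow(V), n_boot)
      for (i in seq_len(n_boot)) {
        idx <- c(sample(g1, m), sample(g2, m))
        acc[, i] <- tstat(V[, idx, drop = FALSE], b[idx])$p
      }
      acc
    })
    boot_p <- rowMeans(boot)
  }
  data.frame(cluster_id = rownames(V),
             n1 = base$n1, n2 = base$n2,
             effect_size = base$effect, p = base$p, boot_p = boot_p,
             direction = ifelse(base$effect > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Volcano table of the selected biomarkers
#'
#' Joins two-group test results with the biomarker records: one row per
#' biomarker with the directed effect size, -log10 p, direction and the five
#' selection flags. The trait pseudo-row is excluded by default (its p-value
#' is an extreme outlier by construction).
#'
#' @param results a [two_group_test()] data.frame.
#' @param biomarkers a [select_biomarkers()] table.
#' @param include_trait_row keep the trait row if present in \code{results}.
#' @return data.frame with attribute \code{counts} (\code{up}, \code{down}).
#' @export
volcano_table <- function(results, biomarkers, include_trait_row = FALSE) {
  ids <- biomarkers$cluster_id
  if (!include_trait_row) ids <- setdiff(ids, "Cluster_AAA")
  ri <- match(ids, results$cluster_id)
  keep <- !is.na(ri)
  out <- cbind(results[ri[keep], c("cluster_id", "effect_size", "p",
                                   "direction")],
               biomarkers[match(ids[keep], biomarkers$cluster_id),
                          c("som_flag", "kmeans_flag", "hca_flag",
                            "corr_flag", "regression_flag")])
  out$neg_log10_p <- -log10(pmax(out$p, .Machine$double.xmin))
  rownames(out) <- NULL
  attr(out, "counts") <- c(up = sum(out$direction == "up"),
                           down = sum(out$direction == "down"))
  out
}

#' Order samples by agglomerative Ward clustering for the heatmap
#'
#' Agglomerative hierarchical clustering of the sample profiles (restricted
#' to the biomarker features) under positive correlation distance with Ward
#' linkage; the returned leaf order arranges the heatmap columns by molecular
#' similarity.
#'
#' @param matrix an [lcms_matrix()] restricted to the biomarker features.
#' @param valid_fraction minimum non-missing fraction per feature before the
#'   sample-by-sample correlation is computed (row-mean imputation after).
#' @return character vector: sample ids in leaf order.
#' @export
order_samples_hca <- function(matrix, valid_fraction = 0.50) {
  if (ncol(matrix$values) < 2) stop("need at least 2 samples")
  fi <- .filter_impute_rows(matrix$values, valid_fraction)
  v <- fi$values
  sds <- apply(v, 2, stats::sd)
  if (all(sds == 0)) return(matrix$samples$sample_id)  # degenerate: stable order
  d <- 1 - stats::cor(v)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  matrix$samples$sample_id[hc$order]
}
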