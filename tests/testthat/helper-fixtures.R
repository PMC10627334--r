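# Shared fixtures. The default-cohort pipeline run is the workhorse of several
# tests; it is computed once per session and cached.

.fixture_env <- new.env(parent = emptyenv())

default_run <- function() {
  if (is.null(.fixture_env$run))
    .fixture_env$run <- run_pipeline(pipeline_config(seed = 42))
  .fixture_env$run
}

# A small lcms_matrix built from explicit values; samples are non-QC unless
# flagged, with sequential injection orders and nominal weights.
make_matrix <- function(values, is_qc = rep(FALSE, ncol(values)),
                        stage = "raw", is_col = NA, trait = NULL) {
  values <- as.matrix(values)
  nf <- nrow(values); ns <- ncol(values)
  feat <- data.frame(cluster_id = sprintf("F%03d", seq_len(nf)))
  feat$is_internal_standard <- seq_len(nf) == is_col
  smp <- data.frame(sample_id = sprintf("s%03d", seq_len(ns)),
                    injection_order = seq_len(ns),
                    flour_weight_mg = ifelse(is_qc, NA_real_, 20),
                    is_qc = is_qc)
  if (!is.null(trait)) smp$trait_u_per_g <- ifelse(is_qc, NA_real_, trait)
  lcms_matrix(values, feat, smp, stage = stage)
}

# Noise-free cohort configuration: every stochastic nuisance switched off;
# overrides win.
noise_free_config <- function(...) {
  base <- list(noise_sd = 0, qc_noise_sd = 0, factor_sd = 0,
               drift_range = c(0, 0), weight_jitter = 0,
               trait_missing_fraction = 0, miss_max = 0)
  do.call(cohort_config, utils::modifyList(base, list(...)))
}

# Brute-force Benjamini-Hochberg: q_i = min_{j: p_j >= p_i} m * p_(j) / rank_j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force agglomerative Ward (ward.D2 Lance-Williams recurrence) on a
# dissimilarity matrix; returns the list of member sets merged at each step.
ward_oracle_merges <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1, n)
  dd <- d^2                      # ward.D2 operates on squared dissimilarities
  active <- seq_len(n)
  merges <- list()
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[a]; j <- active[b]
      if (dd[i, j] < bestv) { bestv <- dd[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    ni <- sizes[i]; nj <- sizes[j]
    new_members <- sort(c(clusters[[i]], clusters[[j]]))
    merges[[length(merges) + 1]] <- new_members
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      dd_new <- ((ni + nk) * dd[i, k] + (nj + nk) * dd[j, k] -
                   nk * dd[i, j]) / (ni + nj + nk)
      dd[i, k] <- dd[k, i] <- dd_new
    }
    clusters[[i]] <- new_members
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  merges
}
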