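test_that("trait generator reproduces the low-activity share and bounds", {
  frac <- vapply(1:5, function(s)
    mean(generate_trait(3773, seed = s) < 0.2), numeric(1))
  expect_true(all(abs(100 * frac - 88) < 2))

  x <- generate_trait(10000, seed = 2)
  expect_true(all(x >= 0.01 & x <= 10))

  # degenerate mixture: point mass at 0.1
  pm <- trait_mixture_defaults()
  pm$weights <- c(1, 0); pm$meanlog <- c(log(0.1), 0); pm$sdlog <- c(0, 0)
  expect_equal(generate_trait(1, pm, seed = 1), 0.1)

  bad <- trait_mixture_defaults(); bad$weights <- c(0.7, 0.7)
  expect_error(generate_trait(10, bad, seed = 1), "weights")
})

test_that("cohort generation is deterministic with QCs on the interval grid", {
  cfg <- cohort_config(n_samples = 150, n_features = 300, n_biomarkers = 10)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$biomarker_effect, b$truth$biomarker_effect)

  smp <- a$matrix$samples
  qc_ord <- smp$injection_order[smp$is_qc]
  n_inj <- max(smp$injection_order)
  expect_equal(sort(qc_ord), seq(48, n_inj, by = 48))
  expect_equal(length(qc_ord), n_inj %/% 48)
  expect_setequal(smp$injection_order, seq_len(n_inj))
  expect_equal(max(smp$lc_column), 4)
  expect_equal(max(smp$mass_cal), 6)
  expect_equal(max(smp$capillary), 2)
  expect_true(all(is.na(smp$trait_u_per_g[smp$is_qc])))
  w <- smp$flour_weight_mg[!smp$is_qc]
  expect_true(all(abs(w - 20) <= 0.2))
  expect_equal(sum(!smp$is_qc & is.na(smp$trait_u_per_g)),
               floor(0.054 * 150))
})

test_that("planted biomarkers are exact on the log scale when noise-free", {
  cfg <- noise_free_config(n_samples = 100, n_features = 60, n_biomarkers = 4)
  sim <- generate_cohort(cfg, seed = 3)
  smp <- sim$matrix$samples
  w <- !smp$is_qc
  tr <- smp$trait_u_per_g[w]
  z_inv <- (1 / tr - mean(1 / tr)) / sd(1 / tr)
  for (id in sim$truth$biomarker_ids) {
    r <- cor(log(sim$matrix$values[id, w]), z_inv)
    expect_equal(abs(r), 1, tolerance = 1e-10)
    expect_equal(sign(r), sign(sim$truth$biomarker_effect[[id]]))
  }
})

test_that("null cohorts carry no trait-correlated structure", {
  cfg <- cohort_config(n_samples = 200, n_features = 300, n_biomarkers = 0,
                       trait_missing_fraction = 0)
  sim <- generate_cohort(cfg, seed = 11)
  smp <- sim$matrix$samples
  w <- !smp$is_qc
  tr <- smp$trait_u_per_g[w]
  z_inv <- (1 / tr - mean(1 / tr)) / sd(1 / tr)
  r <- apply(log(sim$matrix$values[, w]), 1, function(v)
    cor(v, z_inv, use = "pairwise.complete.obs"))
  n_eff <- sum(w)
  expect_lt(abs(mean(r, na.rm = TRUE)), 3 / sqrt(n_eff * length(r)) * 5)
  # 95th percentile of |r| consistent with the null sampling bound
  expect_lt(quantile(abs(r), 0.95, na.rm = TRUE),
            qnorm(0.999) / sqrt(n_eff - 3))
})

test_that("technical-effect injection matches its closed forms", {
  cfg <- noise_free_config(n_samples = 100, n_features = 30, n_biomarkers = 0,
                           trait_missing_fraction = 0)
  sim <- generate_cohort(cfg, seed = 5)
  m <- sim$matrix

  # all offsets and drift zero: identity
  truth0 <- sim$truth
  truth0$factor_effects <- lapply(truth0$factor_effects, function(e) e * 0)
  truth0$drift_params <- truth0$drift_params * 0
  expect_equal(inject_technical_effects(m, truth0)$values, m$values)

  # single-factor +0.5 log-unit offset at level 2, unit sensitivity
  m2 <- m
  m2$samples$capillary <- rep(1:2, length.out = nrow(m2$samples))
  truth1 <- truth0
  truth1$factor_effects <- list(capillary = c(0, 0.5))
  truth1$feature_sensitivity[] <- 1
  out <- inject_technical_effects(m2, truth1)
  lv <- m2$samples$capillary
  gap <- rowMeans(log(out$values[, lv == 2])) -
    rowMeans(log(out$values[, lv == 1])) -
    (rowMeans(log(m2$values[, lv == 2])) -
       rowMeans(log(m2$values[, lv == 1])))
  expect_equal(unname(gap), rep(0.5, nrow(out$values)), tolerance = 1e-12)

  # geometric decay: 1%/injection over one interval
  m3 <- m
  m3$samples$mass_cal <- 1L
  truth2 <- truth0
  truth2$factor_effects <- list()
  truth2$drift_params <- c(0.01)
  truth2$feature_sensitivity[] <- 1
  out3 <- inject_technical_effects(m3, truth2)
  s1 <- which(m3$samples$injection_order == 1)
  s48 <- which(m3$samples$injection_order == 48)
  expect_equal(out3$values[2, s48] / out3$values[2, s1],
               0.99^47 * m3$values[2, s48] / m3$values[2, s1],
               tolerance = 1e-12)

  # undefined factor level is rejected
  m4 <- m
  m4$samples$lc_column[3] <- NA_integer_
  expect_error(inject_technical_effects(m4, sim$truth), "undefined")
})

test_that("MS2 catalog generation honours its jitter configuration", {
  feat <- generate_cohort(cohort_config(n_samples = 60, n_features = 200,
                                        n_biomarkers = 0), seed = 2)
  feat <- feat$matrix$features

  # zero jitter, everything present: coordinates equal the source
  cat0 <- generate_ms2_catalog(feat, jitter = list(
    ppm_sd = 0, rt_sd = 0, fraction_present = 1, fraction_identified = 0.5,
    multiplicity = 1:3), seed = 4)
  src <- match(cat0$truth$source_cluster_id, feat$cluster_id)
  expect_equal(cat0$catalog$mz, feat$mz[src])
  expect_equal(cat0$catalog$mass_da, feat$mass_da[src])
  expect_equal(cat0$catalog$rt_min, feat$rt_min[src])

  # degenerate multiplicity: exactly 3 accessions per identified row
  cat3 <- generate_ms2_catalog(feat, jitter = list(
    ppm_sd = 0, rt_sd = 0, fraction_present = 1, fraction_identified = 1,
    multiplicity = 3), seed = 4)
  n_acc <- lengths(strsplit(cat3$catalog$accessions, ";"))
  expect_true(all(n_acc == 3))

  # stated SDs keep >95% of offsets inside the matching tolerances
  catj <- generate_ms2_catalog(feat, jitter = list(
    ppm_sd = 5, rt_sd = 0.1, fraction_present = 1, fraction_identified = 0,
    multiplicity = 1), seed = 9)
  srcj <- match(catj$truth$source_cluster_id, feat$cluster_id)
  dppm <- 1e6 * (catj$catalog$mz - feat$mz[srcj]) / feat$mz[srcj]
  drt <- catj$catalog$rt_min - feat$rt_min[srcj]
  expect_gt(mean(abs(dppm) <= 20 & abs(drt) <= 1), 0.95)

  expect_error(generate_ms2_catalog(feat, jitter = list(
    ppm_sd = -1, rt_sd = 0, fraction_present = 1, fraction_identified = 0,
    multiplicity = 1), seed = 1), "non-negative")
})
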