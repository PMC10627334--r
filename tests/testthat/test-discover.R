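test_that("VIP matches the single-relevant-variable closed form", {
  set.seed(10)
  n <- 60; p <- 20
  X <- matrix(0, p, n)
  X[1, ] <- rnorm(n)
  m <- make_matrix(X, stage = "z")
  fit <- fit_pls(m, response = X[1, ], n_components = 1, valid_fraction = 0)
  # the single informative feature carries all the weight: VIP = sqrt(p)
  expect_equal(unname(fit$vip["F001"]), sqrt(p), tolerance = 1e-8)
  expect_lt(max(fit$vip[-1]), 1e-6)
  expect_equal(mean(fit$vip^2), 1, tolerance = 1e-6)

  # mean(VIP^2) = 1 for an arbitrary fitted model
  X2 <- matrix(rnorm(p * n), p, n)
  fit2 <- fit_pls(make_matrix(X2, stage = "z"), response = rnorm(n),
                  n_components = 3, valid_fraction = 0)
  expect_equal(mean(fit2$vip^2), 1, tolerance = 1e-6)
})

test_that("PLS predictions agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(11)
  n <- 40; p <- 15
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p) + rnorm(n)
  ours <- wheatlma:::pls1_nipals(X, as.vector(y), 3)
  theirs <- mixOmics::pls(X, as.vector(y), ncomp = 3, mode = "regression",
                          scale = FALSE)
  # latent scores agree up to sign
  for (a in 1:3) {
    expect_equal(abs(cor(ours$scores[, a], theirs$variates$X[, a])), 1,
                 tolerance = 1e-6)
  }
})

test_that("VIP threshold summaries round the way reports print them", {
  vip <- c(rep(1.6, 2996), rep(1.2, 7252 - 2996), rep(0.7, 14440 - 7252),
           rep(0.3, 32336 - 14440))
  s <- vip_threshold_summary(vip, c(0.5, 1.0, 1.5))
  expect_equal(s$count, c(14440, 7252, 2996))
  expect_equal(s$percent, c(45, 22, 9))
  expect_equal(vip_threshold_summary(numeric(10), 1)$percent, 0)
  expect_equal(vip_threshold_summary(c(rep(2, 16168), rep(0, 16168)),
                                     1)$percent, 50)
  expect_error(vip_threshold_summary(vip, c(1, 0.5)), "ascending")
})

# two anti-correlated blocks of profiles with small within-block noise
block_matrix <- function(n_feat = 40, n_smp = 30, sd = 0.05, seed = 12) {
  set.seed(seed)
  base <- rnorm(n_smp)
  up <- rep(1, n_feat / 2) %o% base
  down <- rep(1, n_feat / 2) %o% (-base)
  v <- rbind(up, down) + matrix(rnorm(n_feat * n_smp, 0, sd), n_feat, n_smp)
  make_matrix(v, stage = "z")
}

test_that("SOM separates anti-correlated blocks and is deterministic", {
  m <- block_matrix()
  a <- som_cluster(m, rows = 2, cols = 3, seed = 5)
  b <- som_cluster(m, rows = 2, cols = 3, seed = 5)
  expect_identical(a$label, b$label)
  cells_up <- unique(a$label[1:20])
  cells_down <- unique(a$label[21:40])
  expect_length(intersect(cells_up, cells_down), 0)

  # exact duplicates land in the same cell at the same distance
  v <- rbind(matrix(rnorm(5 * 12), 5, 12))
  v <- rbind(v, v[3, ])
  a2 <- som_cluster(make_matrix(v, stage = "z"), rows = 2, cols = 2,
                    seed = 1)
  expect_equal(a2$label[6], a2$label[3])
  expect_equal(a2$distance[6], a2$distance[3], tolerance = 1e-12)

  expect_error(som_cluster(make_matrix(v, stage = "z"), rows = 10, cols = 10,
                           seed = 1), "grid")
})

test_that("k-means recovers separated blocks with high explained variance", {
  m <- block_matrix()
  km <- kmeans_cluster(m, k = 2, seed = 3)
  expect_length(unique(km$label[1:20]), 1)
  expect_length(unique(km$label[21:40]), 1)
  expect_true(km$label[1] != km$label[21])
  expect_gt(attr(km, "overall_variance_explained"), 0.9)

  # identical rows have zero within-group distance
  v <- matrix(rnorm(24), 2, 12)
  v <- v[rep(1:2, each = 4), ]
  km2 <- kmeans_cluster(make_matrix(v, stage = "z"), k = 2, seed = 2)
  expect_equal(max(km2$distance), 0, tolerance = 1e-12)

  expect_identical(kmeans_cluster(m, k = 5, seed = 7)$label,
                   kmeans_cluster(m, k = 5, seed = 7)$label)
  expect_error(kmeans_cluster(m, k = 999, seed = 1), "feature count")
})

test_that("divisive bisection keeps duplicates adjacent, splits blocks first", {
  m <- block_matrix()
  h <- divisive_hca(m, min_size = 5)
  # first split separates the anti-correlated blocks: leaf ids of the two
  # blocks are disjoint
  expect_length(intersect(unique(h$label[1:20]), unique(h$label[21:40])), 0)

  # duplicated features sit at adjacent order indices
  set.seed(13)
  v <- matrix(rnorm(8 * 15), 8, 15)
  v <- rbind(v, v[2, ] + 1e-9)
  h2 <- divisive_hca(make_matrix(v, stage = "z"), min_size = 2)
  expect_equal(abs(h2$order[9] - h2$order[2]), 1)

  # permuting feature order permutes labels but not memberships
  perm <- c(7, 3, 1, 9, 5, 2, 8, 6, 4)
  h3 <- divisive_hca(subset_lcms(make_matrix(v, stage = "z"),
                                 features = perm), min_size = 2)
  part2 <- split(h2$cluster_id, h2$label)
  part3 <- split(h3$cluster_id, h3$label)
  key <- function(p) unname(sort(vapply(p, function(x)
    paste(sort(x), collapse = "|"), character(1))))
  expect_identical(key(part2), key(part3))
})

test_that("the trait neighbourhood is its cluster minus the trait row", {
  asg <- structure(data.frame(cluster_id = c("A", "B", "C", "Cluster_AAA"),
                              label = c(1, 2, 1, 1)),
                   trait_id = "Cluster_AAA",
                   class = c("cluster_assignment", "data.frame"))
  expect_setequal(trait_neighbourhood(asg), c("A", "C"))
  asg$label <- c(2, 2, 2, 1)
  expect_length(trait_neighbourhood(asg), 0)
  attr(asg, "trait_id") <- character(0)
  expect_error(trait_neighbourhood(asg), "trait row")
})

test_that("correlation screen matches the direct Pearson formula", {
  set.seed(14)
  v <- matrix(rnorm(5 * 30), 5, 30)
  v[2, c(3, 9)] <- NA
  tr <- runif(30, 0.05, 3)
  m <- make_matrix(v, stage = "corrected", trait = tr)
  z <- incorporate_trait_row(z_transform_rows(m),
                             stats::setNames(tr, m$samples$sample_id))
  out <- correlate_with_trait(z)
  expect_equal(out$r[out$cluster_id == "Cluster_AAA"], 1, tolerance = 1e-12)
  for (f in 1:5) {
    oracle <- cor(z$values[f, ], z$values["Cluster_AAA", ],
                  use = "pairwise.complete.obs")
    expect_equal(out$r[f], oracle, tolerance = 1e-12)
  }
  # insufficient overlap: r missing
  v2 <- v; v2[1, 1:25] <- NA
  m2 <- make_matrix(v2, stage = "corrected", trait = tr)
  z2 <- incorporate_trait_row(z_transform_rows(m2),
                              stats::setNames(tr, m2$samples$sample_id))
  expect_true(is.na(correlate_with_trait(z2)$r[1]))
})

test_that("regression q-values match a brute-force BH oracle", {
  # worked family: p = (0.01, 0.02, 0.04) -> q = (0.03, 0.03, 0.04)
  expect_equal(bh_oracle(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))

  set.seed(15)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }

  # full screen: the trait row yields q = 0 and slopes match lm()
  set.seed(16)
  v <- matrix(rnorm(6 * 40), 6, 40)
  tr <- runif(40, 0.05, 3)
  m <- make_matrix(v, stage = "corrected", trait = tr)
  z <- incorporate_trait_row(z_transform_rows(m),
                             stats::setNames(tr, m$samples$sample_id))
  out <- regress_on_trait(z)
  expect_equal(out$q[out$cluster_id == "Cluster_AAA"], 0)
  x <- z$values["Cluster_AAA", ]
  for (f in 1:6) {
    lmfit <- summary(lm(z$values[f, ] ~ x))
    expect_equal(out$slope[f], lmfit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(out$p[f], lmfit$coefficients[2, 4], tolerance = 1e-10)
  }

  # type-I calibration on null features
  set.seed(17)
  vn <- matrix(rnorm(800 * 50), 800, 50)
  trn <- runif(50, 0.05, 3)
  mn <- make_matrix(vn, stage = "corrected", trait = trn)
  zn <- incorporate_trait_row(z_transform_rows(mn),
                              stats::setNames(trn, mn$samples$sample_id))
  outn <- regress_on_trait(zn)
  frac <- mean(outn$p[outn$cluster_id != "Cluster_AAA"] < 0.05)
  expect_gt(frac, 0.02); expect_lt(frac, 0.09)
})

test_that("union selection has OR semantics and threshold monotonicity", {
  corr <- data.frame(cluster_id = c("A", "B", "C", "D", "Cluster_AAA"),
                     n = 50, r = c(0.3, 0.05, -0.4, 0.1, 1),
                     r2 = c(0.09, 0.0025, 0.16, 0.01, 1),
                     corr_flag = NA)
  attr(corr, "trait_id") <- "Cluster_AAA"
  regr <- data.frame(cluster_id = c("A", "B", "C", "D", "Cluster_AAA"),
                     n = 50, slope = 1, p = c(0.2, 0.001, 0.5, 0.9, 0),
                     q = c(0.4, 0.01, 0.6, 0.9, 0))
  nb <- list(som = character(0), kmeans = "D", hca = character(0))
  sel <- select_biomarkers(nb, corr, regr)
  expect_setequal(sel$cluster_id, c("A", "B", "D"))
  expect_true(sel$corr_flag[sel$cluster_id == "A"])
  expect_false(any(sel$cluster_id == "C"))        # negative r never passes
  expect_false("Cluster_AAA" %in% sel$cluster_id)
  expect_equal(sel$selected, rep(TRUE, 3))

  # relaxing a threshold never shrinks the selection
  sel2 <- select_biomarkers(nb, corr, regr, corr_threshold = 0.05)
  expect_true(all(sel$cluster_id %in% sel2$cluster_id))
  sel3 <- select_biomarkers(nb, corr, regr, q_threshold = 0.5)
  expect_true(all(sel$cluster_id %in% sel3$cluster_id))

  # the r^2 reading flags strong negative correlations too
  sel4 <- select_biomarkers(nb, corr, regr, use_r2 = TRUE,
                            corr_threshold = 0.15)
  expect_true("C" %in% sel4$cluster_id)

  regr_bad <- regr[-2, ]
  expect_error(select_biomarkers(nb, corr, regr_bad), "different feature")
})
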