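test_that("equal-size binning distributes the remainder to early bins", {
  set.seed(18)
  tr <- stats::setNames(runif(3990, 0.04, 8), paste0("s", 1:3990))
  b <- assign_bins(tr, "equal_size_rank", n_bins = 8)
  expect_equal(b$bin_sizes, c(rep(499L, 6), rep(498L, 2)))
  expect_equal(round(b$mean_bin_size), 499)
  expect_lte(max(b$bin_sizes) - min(b$bin_sizes), 1)
  # bins respect trait order
  expect_true(all(diff(b$bin_of_sample[order(tr)]) >= 0))

  b1 <- assign_bins(stats::setNames(runif(8), paste0("x", 1:8)),
                    "equal_size_rank", n_bins = 8)
  expect_equal(b1$bin_sizes, rep(1L, 8))
  expect_error(assign_bins(tr[1:3], "equal_size_rank", n_bins = 8), "bins")

  # threshold scheme reproduces the balanced two-bin split
  tr2 <- stats::setNames(c(runif(467, 0.17, 8), runif(467, 0.01, 0.169)),
                         paste0("u", 1:934))
  b2 <- assign_bins(tr2, "threshold", threshold = 0.17)
  expect_equal(b2$bin_sizes, c(467L, 467L))
  expect_true(all(b2$bin_of_sample[tr2 >= 0.17] == 2))
})

test_that("bin means agree with direct averaging", {
  # hand-worked 4-sample, 2-bin case
  v <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40), 2, 4, byrow = TRUE)
  tr <- c(0.1, 0.1, 0.5, 0.5)
  m <- make_matrix(v, stage = "z", trait = tr)
  b <- assign_bins(stats::setNames(tr, m$samples$sample_id), "threshold",
                   threshold = 0.17)
  bm <- bin_means(m, b)
  expect_equal(unname(bm$per_feature_bin_means),
               matrix(c(1.5, 3.5, 15, 35), 2, 2, byrow = TRUE))

  # constant feature: all bin means equal the constant
  v2 <- matrix(7, 1, 12)
  tr2 <- seq(0.01, 3, length.out = 12)
  m2 <- make_matrix(v2, stage = "z", trait = tr2)
  b8 <- assign_bins(stats::setNames(tr2, m2$samples$sample_id),
                    "equal_size_rank", n_bins = 4)
  expect_true(all(bin_means(m2, b8)$per_feature_bin_means == 7))

  # a feature equal to the trait has strictly increasing bin means
  m3 <- make_matrix(matrix(tr2, 1, 12), stage = "z", trait = tr2)
  bm3 <- bin_means(m3, b8)
  expect_true(all(diff(bm3$per_feature_bin_means[1, ]) > 0))

  # a bin with no observation yields a missing mean
  v4 <- matrix(c(1, 1, NA, NA), 1, 4)
  m4 <- make_matrix(v4, stage = "z", trait = tr)
  expect_true(is.na(bin_means(m4, b)$per_feature_bin_means[1, 2]))
})

test_that("two-group test matches direct t-distribution evaluation", {
  set.seed(19)
  g <- c(rep(0.05, 100), rep(0.5, 100))
  v <- rbind(c(rnorm(100, 0, 1), rnorm(100, 1, 1)),
             rnorm(200))
  m <- make_matrix(v, stage = "z", trait = g)
  b <- assign_bins(stats::setNames(g, m$samples$sample_id), "threshold",
                   threshold = 0.17)
  out <- two_group_test(m, b, n_boot = 0)

  # oracle: classical pooled-variance t statistic evaluated directly
  x1 <- v[1, 1:100]; x2 <- v[1, 101:200]
  sp <- sqrt((99 * var(x1) + 99 * var(x2)) / 198)
  t_ <- (mean(x2) - mean(x1)) / (sp * sqrt(2 / 100))
  expect_equal(out$p[1], 2 * pt(-abs(t_), 198), tolerance = 1e-10)
  expect_equal(out$effect_size[1], mean(x2) - mean(x1), tolerance = 1e-12)
  expect_equal(out$p[1], t.test(x2, x1, var.equal = TRUE)$p.value,
               tolerance = 1e-10)
  expect_equal(out$direction[1], "up")

  # identical groups: zero effect, p = 1
  v2 <- matrix(rep(c(1, 2, 3, 4), 2), 1, 8)
  tr2 <- rep(c(0.05, 0.5), each = 4)
  m2 <- make_matrix(v2[, c(1:4, 1:4), drop = FALSE], stage = "z",
                    trait = tr2)
  b2 <- assign_bins(stats::setNames(tr2, m2$samples$sample_id), "threshold")
  out2 <- two_group_test(m2, b2, n_boot = 0)
  expect_equal(out2$effect_size, 0)
  expect_equal(out2$p, 1)

  # swapping the bins negates the effect and preserves p
  bswap <- b
  bswap$bin_of_sample <- 3L - bswap$bin_of_sample
  outs <- two_group_test(m, bswap, n_boot = 0)
  expect_equal(outs$effect_size, -out$effect_size, tolerance = 1e-12)
  expect_equal(outs$p, out$p, tolerance = 1e-12)

  # bootstrap-stabilized p is reproducible and in range
  outb <- two_group_test(m, b, n_boot = 5, seed = 4)
  outb2 <- two_group_test(m, b, n_boot = 5, seed = 4)
  expect_identical(outb$boot_p, outb2$boot_p)
  expect_true(all(outb$boot_p >= 0 & outb$boot_p <= 1))
})

test_that("volcano tables count directions and exclude the trait row", {
  res <- data.frame(cluster_id = c("A", "B", "Cluster_AAA"),
                    effect_size = c(0.5, 0.2, -1.2),
                    p = c(1e-4, 1e-3, 1e-23),
                    direction = c("up", "up", "down"))
  bm <- data.frame(cluster_id = c("A", "B", "Cluster_AAA"),
                   som_flag = TRUE, kmeans_flag = FALSE, hca_flag = FALSE,
                   corr_flag = TRUE, regression_flag = FALSE)
  v <- volcano_table(res, bm)
  expect_equal(attr(v, "counts"), c(up = 2L, down = 0L))
  expect_false("Cluster_AAA" %in% v$cluster_id)
  v2 <- volcano_table(res, bm, include_trait_row = TRUE)
  expect_true("Cluster_AAA" %in% v2$cluster_id)
})

test_that("effect directions agree with the planted biomarker signs", {
  run <- default_run()
  expect_gte(run$recovery$direction_agreement, 0.95)
})

test_that("sample ordering by Ward HCA matches a brute-force oracle", {
  set.seed(20)
  # two planted sample groups become contiguous blocks in leaf order
  v <- cbind(matrix(rnorm(40 * 6, 0, 0.2) + 1, 40, 6),
             matrix(rnorm(40 * 6, 0, 0.2) - 1, 40, 6))
  v <- v * rep(rnorm(40, 1, 0.3), 12)
  m <- make_matrix(v, stage = "z")
  ord <- order_samples_hca(m)
  blocks <- m$samples$sample_id[1:6]
  pos <- match(blocks, ord)
  expect_equal(max(pos) - min(pos), 5)

  # duplicated samples are adjacent
  v2 <- matrix(rnorm(10 * 5), 10, 5)
  v2 <- cbind(v2, v2[, 3])
  m2 <- make_matrix(v2, stage = "z")
  ord2 <- order_samples_hca(m2)
  expect_equal(abs(match("s003", ord2) - match("s006", ord2)), 1)

  # merge structure agrees with the Lance-Williams ward.D2 recurrence (n = 6)
  set.seed(21)
  v3 <- matrix(rnorm(12 * 6), 12, 6)
  m3 <- make_matrix(v3, stage = "z")
  d <- 1 - cor(v3)
  hc <- hclust(as.dist(d), method = "ward.D2")
  oracle <- ward_oracle_merges(d)
  for (k in 5:2) {
    ct <- cutree(hc, k)
    parts <- sort(vapply(split(seq_len(6), ct),
                         function(i) paste(i, collapse = ","), character(1)))
    # rebuild the oracle partition after 6 - k merges
    groups <- as.list(seq_len(6))
    for (mg in oracle[seq_len(6 - k)]) {
      groups <- Filter(function(g) !any(g %in% mg), groups)
      groups <- c(groups, list(sort(mg)))
    }
    oparts <- sort(vapply(groups, function(i) paste(i, collapse = ","),
                          character(1)))
    expect_identical(unname(parts), unname(oparts))
  }
})
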