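test_that("Grubbs statistic matches hand computations", {
  g <- grubbs_statistic(c(1, 2, 3))
  expect_equal(g$G, 1)                       # mean 2, sd 1, max dev 1
  expect_true(g$candidate %in% c(1L, 3L))

  g2 <- grubbs_statistic(c(0, 0, 0, 0, 0, 9))
  expect_equal(g2$G, 7.5 / sqrt(13.5), tolerance = 1e-10)  # ~2.0412
  expect_equal(g2$candidate, 6L)

  expect_error(grubbs_statistic(c(5, 5, 5, 5)), "degenerate")
  expect_error(grubbs_statistic(c(1, 2)), "at least 3")
})

test_that("Grubbs statistic is affine invariant", {
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1))
    a <- runif(1, -5, 5)
    b <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(grubbs_statistic(x)$G, grubbs_statistic(a + b * x)$G,
                 tolerance = 1e-12)
  }
})

test_that("critical values agree with published Grubbs tables", {
  expect_equal(grubbs_critical(6, 0.05), 1.887, tolerance = 1e-3)
  expect_equal(grubbs_critical(3, 0.05), 1.1543, tolerance = 1e-4)
  for (n in 3:8) {
    expect_equal(grubbs_critical(n, 0.05), unname(GRUBBS_TABLE_05[as.character(n)]),
                 tolerance = 5e-4)
  }
  # the alpha -> 0 limit approaches the attainable upper bound (n-1)/sqrt(n)
  for (n in c(3, 6, 10)) {
    expect_lte(grubbs_critical(n, 1e-12), (n - 1) / sqrt(n))
    expect_gt(grubbs_critical(n, 0.01), grubbs_critical(n, 0.05))
    expect_equal(grubbs_critical(n, 1e-12), (n - 1) / sqrt(n),
                 tolerance = 1e-3)
  }
  expect_error(grubbs_critical(2, 0.05), "n")
  expect_error(grubbs_critical(6, 0), "alpha")
  expect_error(grubbs_critical(6, 1), "alpha")
})

test_that("outlier flagging matches the closed-form decision", {
  expect_identical(flag_outliers(c(1, 2, 3), min_n = 2), integer(0))
  expect_identical(flag_outliers(c(0, 0, 0, 0, 0, 9)), 6L)
  expect_identical(flag_outliers(setNames(c(0, 0, 0, 0, 0, 9),
                                          letters[1:6])), "f")
  # vanishing alpha flags nothing
  expect_length(flag_outliers(rnorm(8), alpha = 1e-12, min_n = 2), 0)
  # the min_n floor stops removals
  expect_length(flag_outliers(c(0, 0, 9), min_n = 4), 0)
})

test_that("single-pass flagging agrees with a brute-force oracle (n <= 8)", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- if (i %% 2 == 0) rnorm(n) else rlnorm(n, sdlog = 0.8)
    if (sd(x) == 0) next
    # oracle: direct max standardized deviation vs published table value
    # (skip knife-edge draws within the table's 4-decimal precision)
    dev <- abs(x - mean(x)) / sd(x)
    crit <- GRUBBS_TABLE_05[as.character(n)]
    if (abs(max(dev) - crit) < 1e-3) next
    oracle <- which.max(dev)[dev[which.max(dev)] > crit]
    got <- flag_outliers(x, alpha = 0.05, policy = "single_pass", min_n = 2)
    expect_identical(as.integer(got), as.integer(oracle))
  }
})

test_that("null flag rate is calibrated at alpha", {
  set.seed(2024)
  n_groups <- 10000
  flagged <- vapply(seq_len(n_groups), function(i) {
    length(flag_outliers(rnorm(6), alpha = 0.05, policy = "single_pass",
                         min_n = 2)) > 0
  }, logical(1))
  rate <- mean(flagged)
  se <- sqrt(0.05 * 0.95 / n_groups)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("iterative flagging removes values in order and respects the floor", {
  # G = 41/20.1 = 2.04 > 1.887 flags the 60; the rerun on the remaining five
  # gives G = 1.744 > 1.715 and flags the 14; the floor of 4 then stops
  x <- c(10, 10.1, 9.9, 10.05, 14, 60)
  out <- flag_outliers(x, policy = "iterative", min_n = 4)
  expect_identical(out, c(6L, 5L))
  # single pass stops after the first removal
  expect_identical(flag_outliers(x, policy = "single_pass", min_n = 4), 6L)
  # with a floor of 6 nothing can be removed from 6 values
  expect_length(flag_outliers(x, min_n = 6), 0)
})

test_that("group summaries report means, sds and flags", {
  m <- build_strain_manifest(2, 0)
  tbl <- simulate_screen(m, list(), sim_config(cv_total = 0, seed = 1))
  s <- summarize_groups(tbl)
  expect_equal(nrow(s), 3 * 2)
  expect_equal(s$n_raw, rep(6L, 6))
  expect_equal(s$n_used, rep(6L, 6))
  ff <- s[s$reporter == "FF", ]
  expect_true(all(ff$mean == 1e4))
  expect_true(all(ff$sd == 0))
  # an implanted aberrant readout is flagged and excluded from the mean
  tbl2 <- tbl
  i <- which(tbl2$group_id == "G1" & tbl2$reporter == "FF")
  tbl2$counts[i] <- c(1e4, 1.02e4, 0.98e4, 1.01e4, 0.99e4, 9e4)
  s2 <- summarize_groups(tbl2)
  row <- s2[s2$group_id == "G1" & s2$reporter == "FF", ]
  expect_equal(row$n_used, 5L)
  expect_identical(row$outliers[[1]], "2.3")  # bio 2, tech 3
  expect_equal(row$mean, mean(c(1e4, 1.02e4, 0.98e4, 1.01e4, 0.99e4)))
})

test_that("viability filter drops exactly the non-viable strains", {
  m <- build_strain_manifest(19, 59, nonviable_rp_genes())
  groups <- c(manifest_wildtype(m), m$gene_id)   # all 137 strains + WT
  ff <- setNames(rep(1e4, length(groups)), groups)
  ren <- setNames(rep(8e7, length(groups)), groups)
  tbl <- const_readouts(ff, ren, n_bio = 1, n_tech = 2)
  expect_message(out <- filter_viable(tbl, m), "9 non-viable")
  expect_equal(length(unique(out$group_id)), 129)
  expect_false(any(nonviable_rp_genes() %in% out$group_id))

  # all viable: identity
  m2 <- build_strain_manifest(2, 0)
  tbl2 <- simulate_screen(m2, list(), sim_config(seed = 3))
  expect_message(out2 <- filter_viable(tbl2, m2), "0 non-viable")
  expect_equal(as.data.frame(out2), as.data.frame(tbl2))

  # all strains non-viable: only the wild type remains
  m3 <- build_strain_manifest(2, 0, nonviable_ids = c("G1", "G2"))
  tbl3 <- const_readouts(c(WT = 1e4, G1 = 1e4, G2 = 1e4),
                         c(WT = 8e7, G1 = 8e7, G2 = 8e7))
  expect_message(out3 <- filter_viable(tbl3, m3), "1 usable")
  expect_identical(unique(out3$group_id), "WT")

  # unknown group
  tbl4 <- const_readouts(c(WT = 1e4, BOGUS = 1e4), c(WT = 8e7, BOGUS = 8e7))
  expect_error(filter_viable(tbl4, m2), "BOGUS")
})
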