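test_that("normalization reproduces crafted fold changes exactly", {
  tbl <- const_readouts(ff = c(WT = 1.0e4, S1 = 2.7e4, S2 = 1.6e4),
                        ren = c(WT = 8.0e7, S1 = 8.0e7, S2 = 1.8 * 8.0e7))
  pts <- normalize_screen(tbl)
  s1 <- pts[pts$strain_id == "S1", ]
  expect_equal(s1$ff_fold, 2.7)
  expect_equal(s1$ren_fold, 1)
  expect_equal(s1$p_ff, 0)    # zero-noise limit: means differ
  expect_equal(s1$p_ren, 1)   # means identical
  # distance: (1.6, 1.8) -> sqrt(0.36 + 0.64) = 1
  s2 <- pts[pts$strain_id == "S2", ]
  expect_equal(s2$distance, 1)
  # the wild type sits exactly at (1, 1)
  wt <- pts[pts$is_wildtype, ]
  expect_equal(c(wt$ff_fold, wt$ren_fold, wt$distance), c(1, 1, 0))
})

test_that("normalization validates the wild type and short strains", {
  tbl <- const_readouts(ff = c(S1 = 2e4, S2 = 1e4),
                        ren = c(S1 = 8e7, S2 = 8e7))
  expect_error(normalize_screen(tbl), "wild-type")
  # a strain with too few readouts is excluded with a warning
  short <- dplyr::bind_rows(
    const_readouts(ff = c(WT = 1e4, S1 = 2e4), ren = c(WT = 8e7, S1 = 8e7)),
    const_readouts(ff = c(S2 = 3e4), ren = c(S2 = 8e7), n_bio = 1, n_tech = 2)
  )
  expect_warning(pts <- normalize_screen(lux_readouts(short)), "S2")
  expect_false("S2" %in% pts$strain_id)
  expect_identical(attr(pts, "excluded"), "S2")
})

test_that("reporter concordance matches direct computation", {
  pts <- make_points(ff = c(1, 2, 3), ren = c(1, 2, 4))
  expect_equal(pearson_across_strains(pts), 0.981981, tolerance = 1e-5)
  expect_equal(pearson_across_strains(make_points(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(pearson_across_strains(make_points(c(1, 2, 3), c(5, 4, 3))), -1)
  expect_warning(
    r <- pearson_across_strains(make_points(c(1, 2, 3), c(2, 2, 2))),
    "zero variance")
  expect_true(is.na(r))
  expect_error(pearson_across_strains(make_points(c(1, 2), c(1, 2))),
               "at least 3")
  # the wild-type point does not enter the correlation
  with_wt <- dplyr::bind_rows(make_points(c(1, 2, 3), c(1, 2, 4)),
                              make_points(10, 10, wildtype = TRUE))
  expect_equal(pearson_across_strains(with_wt), 0.981981, tolerance = 1e-5)
})

test_that("inert radius is twice the normalized spread and scale-free", {
  x <- 1 + 0.24 * c(-1, 0, 1)   # sample mean 1, sample sd 0.24
  expect_equal(inert_radius(x), 0.48)
  expect_equal(inert_radius(2 * x), 0.48)       # scale invariance
  expect_equal(inert_radius(1e4 * x), 0.48)
  expect_equal(inert_radius(c(5, 5, 5)), 0)     # constant measurements
  expect_error(inert_radius(c(1, 2)), "at least 3")
  expect_error(inert_radius(c(1, -1, 2)), "degenerate")
})

test_that("strain classification follows the circle, band and quadrants", {
  pts <- make_points(ff = c(2.7, 1.0, 0.4, 2.7, 0.8, 1.8),
                     ren = c(1.0, 1.0, 0.45, 2.7, 1.9, 0.3),
                     q_ff = c(0.001, 1, 0.5, 0.001, 0.9, 0.01),
                     q_ren = c(0.9, 1, 0.5, 0.001, 0.01, 0.8))
  cls <- classify_strains(pts, radius = 0.48, wt_ren_band = 0.48,
                          alpha = 0.05)$class
  expect_identical(cls, c("selective_hit", "inert", "q4_both_down",
                          "q2_both_up", "q1_ren_up", "q3_ff_up"))
})

test_that("classification is total and mutually exclusive (property)", {
  set.seed(8)
  for (i in 1:25) {
    n <- 40
    pts <- make_points(ff = rlnorm(n, 0, 0.5), ren = rlnorm(n, 0, 0.5),
                       q_ff = runif(n), q_ren = runif(n))
    out <- classify_strains(pts, radius = 0.48, wt_ren_band = 0.48)
    expect_false(any(is.na(out$class)))
    expect_true(all(out$class %in% c("inert", "q1_ren_up", "q2_both_up",
                                     "q3_ff_up", "q4_both_down",
                                     "selective_hit")))
    inside <- out$distance <= 0.48
    expect_true(all(out$class[inside] == "inert"))
    expect_true(all(out$class[!inside] != "inert"))
    # equal shift of both reporters is never selective (band = radius)
    eq <- make_points(ff = rlnorm(10, 0.7, 0.3), ren = 1,
                      q_ff = rep(1e-6, 10), q_ren = rep(1, 10))
    eq$ren_fold <- eq$ff_fold
    eq$distance <- sqrt(2) * abs(eq$ff_fold - 1)
    out_eq <- classify_strains(eq, radius = 0.48, wt_ren_band = 0.48)
    expect_false(any(out_eq$class == "selective_hit"))
  }
})

test_that("run_screen recovers a planted selective strain", {
  m <- build_strain_manifest(10, 10)
  eff <- list(effect_spec("G1", ff_multiplier = 2.7))
  tbl <- simulate_screen(m, eff, sim_config(seed = 5))
  res <- suppressMessages(run_screen(tbl, m))
  expect_s3_class(res, "lux_screen")
  p <- res$points[res$points$strain_id == "G1", ]
  expect_gt(p$ff_fold, 2)
  expect_identical(res$hits, "G1")
  expect_equal(sum(res$class_counts), 30)
  expect_true(all(!is.na(res$points$class[!res$points$is_wildtype])))
  # a strain shifted equally in both reporters is never a hit
  eff2 <- list(effect_spec("G2", ff_multiplier = 2.7, ren_multiplier = 2.7))
  res2 <- suppressMessages(run_screen(simulate_screen(m, eff2,
                                                      sim_config(seed = 6)), m))
  p2 <- res2$points[res2$points$strain_id == "G2", ]
  expect_identical(p2$class, "q2_both_up")
  expect_false("G2" %in% res2$hits)
})

test_that("all-null screens rarely call hits", {
  m <- build_strain_manifest(10, 10)
  n_hit <- vapply(1:40, function(i) {
    tbl <- simulate_screen(m, list(), sim_config(seed = 700 + i))
    length(suppressMessages(suppressWarnings(run_screen(tbl, m)))$hits)
  }, numeric(1))
  expect_gte(mean(n_hit == 0), 0.95)
})

test_that("radius fallback and overrides behave", {
  tbl <- const_readouts(ff = c(WT = 1e4, S1 = 2.7e4, S2 = 1.05e4, S3 = 0.98e4),
                        ren = c(WT = 8e7, S1 = 8e7, S2 = 8e7, S3 = 8e7))
  m <- build_strain_manifest(3, 0)
  ids <- c(S1 = "G1", S2 = "G2", S3 = "G3")
  tbl$group_id <- ifelse(tbl$group_id %in% names(ids),
                         ids[tbl$group_id], tbl$group_id)
  # zero noise: spread cannot be estimated, falls back to the nominal 0.5
  w <- capture_warnings(
    res <- suppressMessages(run_screen(lux_readouts(tbl), m)))
  expect_match(w, "falling back", all = FALSE)
  expect_equal(res$radius, 0.5)
  expect_identical(res$hits, "G1")
  expect_identical(res$points$class[res$points$strain_id == "G2"], "inert")
  # explicit override wins
  res2 <- suppressWarnings(suppressMessages(
    run_screen(lux_readouts(tbl), m, radius = 0.01, ren_band = 0.5)))
  expect_equal(res2$radius, 0.01)
})

test_that("screen results expose tidy, glance and autoplot", {
  m <- build_strain_manifest(4, 3)
  tbl <- simulate_screen(m, list(effect_spec("G1", ff_multiplier = 2.7)),
                         sim_config(seed = 5))
  res <- suppressMessages(suppressWarnings(run_screen(tbl, m)))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 11)  # 10 strains + WT
  gl <- glance(res)
  expect_equal(gl$n_strains, 10)
  expect_true(gl$rho >= -1 && gl$rho <= 1)
  expect_equal(gl$n_hits, length(res$hits))
  expect_s3_class(autoplot(res), "ggplot")
})
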