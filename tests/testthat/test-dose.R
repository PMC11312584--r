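test_that("control normalization reproduces planted folds exactly at zero noise", {
  cfg <- sim_config(assay = "dual_glo", cv_total = 0, seed = 1)
  tbl <- simulate_dose_panel(
    list(effect_spec("C17", dose_model = list(m_top_ff = 1.7))), cfg)
  eff <- normalize_to_control(tbl)
  expect_equal(nrow(eff), 6)
  top <- eff[which.max(eff$dose), ]
  expect_equal(top$ff_fold, 1.7)
  expect_equal(top$ren_fold, 1)
  expect_equal(top$p_ff, 0)
  expect_equal(top$p_ren, 1)
  # folds follow the planted power-law curve at every dose
  expect_equal(eff$ff_fold, dose_multiplier(eff$dose, max(eff$dose), 1.7))

  # treated identical to control: folds exactly 1, nothing significant
  null_tbl <- simulate_dose_panel(list(effect_spec("C22")), cfg)
  null_eff <- normalize_to_control(null_tbl)
  expect_true(all(null_eff$ff_fold == 1))
  expect_true(all(null_eff$ren_fold == 1))
  expect_true(all(null_eff$p_ff == 1))
})

test_that("missing or deficient controls are rejected", {
  cfg <- sim_config(assay = "dual_glo", seed = 1)
  tbl <- simulate_dose_panel(list(effect_spec("C1")), cfg)
  no_ctrl <- lux_readouts(tbl[tbl$group_id != "control", ],
                          assay_variant = "dual_glo_compound")
  expect_error(normalize_to_control(no_ctrl), "control")
  # control lacking one reporter is named in the error
  no_ren <- tbl[!(tbl$group_id == "control" & tbl$reporter == "REN"), ]
  expect_error(normalize_to_control(no_ren), "control lacks REN")
})

test_that("dose trend test is one-sided for increasing response", {
  low <- sim_config(assay = "dual_glo", cv_total = 0.05, seed = 3)
  up <- simulate_dose_panel(
    list(effect_spec("C1", dose_model = list(m_top_ff = 1.7))), low)
  expect_lt(trend_test(up, "C1", "FF"), 0.05)

  down <- simulate_dose_panel(
    list(effect_spec("C2", dose_model = list(m_top_ff = 0.5))), low)
  expect_gt(trend_test(down, "C2", "FF"), 0.5)

  flat <- simulate_dose_panel(
    list(effect_spec("C3")), sim_config(assay = "dual_glo", cv_total = 0,
                                        seed = 4))
  expect_gte(trend_test(flat, "C3", "FF"), 0.5)

  short <- simulate_dose_panel(
    list(effect_spec("C4")),
    sim_config(assay = "dual_glo", doses = c(1e-6, 1e-5), seed = 5))
  expect_error(trend_test(short, "C4", "FF"), "at least 3 doses")
})

test_that("compound classification follows the triage rules", {
  eff <- tibble::tibble(
    compound_id = "C", dose = 10^seq(-9, -4),
    ff_fold = c(1, 1, 1, 1.01, 1.07, 1.7),
    ren_fold = 1, n_ff = 3L, n_ren = 3L,
    p_ff = c(0.9, 0.8, 0.7, 0.6, 0.3, 0.001),
    p_ren = rep(0.8, 6)
  )
  expect_identical(classify_compound(eff, trend_p_ff = 0.01), "selective_hit")
  # no dose trend: not called active
  expect_identical(classify_compound(eff, trend_p_ff = 0.4), "inactive")
  # companion reporter also shifted: only a minor active
  eff_ren <- eff
  eff_ren$p_ren[6] <- 0.001
  expect_identical(classify_compound(eff_ren, trend_p_ff = 0.01),
                   "minor_active")
  # significant decrease is not an activation call
  eff_down <- eff
  eff_down$ff_fold[6] <- 0.5
  expect_identical(classify_compound(eff_down, trend_p_ff = 0.01), "inactive")
  # all-null profile
  eff_null <- eff
  eff_null$p_ff <- 0.9
  eff_null$ff_fold <- 1
  expect_identical(classify_compound(eff_null, trend_p_ff = 0.6), "inactive")
})

test_that("panel run recovers the planted composition at low noise", {
  cfg <- sim_config(assay = "dual_glo", cv_total = 0.05, seed = 9)
  tbl <- simulate_dose_panel(default_panel_compounds(29), cfg)
  res <- run_compound_panel(tbl)
  expect_s3_class(res, "lux_panel")
  expect_equal(nrow(res$compounds), 29)
  cls <- setNames(res$compounds$class, res$compounds$compound_id)
  expect_identical(unname(cls["C17"]), "selective_hit")
  expect_identical(unname(cls[c("C7", "C25")]),
                   c("minor_active", "minor_active"))
  expect_equal(sum(cls != "inactive"), 3)
  gl <- glance(res)
  expect_equal(gl$n_active, 3)
  expect_equal(gl$n_compounds, 29)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res, compounds = c("C17", "C22")), "ggplot")
})

test_that("empty panels give empty results", {
  cfg <- sim_config(assay = "dual_glo", seed = 1)
  tbl <- simulate_dose_panel(list(), cfg)
  res <- run_compound_panel(tbl)
  expect_equal(nrow(res$compounds), 0)
  expect_equal(nrow(res$effects), 0)
})

test_that("null panels have an alpha-governed false-active rate", {
  n_active <- integer(30)
  for (i in 1:30) {
    cfg <- sim_config(assay = "dual_glo", seed = 3000 + i)
    tbl <- simulate_dose_panel(lapply(paste0("N", 1:6), effect_spec), cfg)
    res <- run_compound_panel(tbl)
    n_active[i] <- sum(res$compounds$class != "inactive")
  }
  rate <- sum(n_active) / (30 * 6)
  expect_lte(rate, 0.05)
})

test_that("panel analysis is deterministic given the seed", {
  cfg <- sim_config(assay = "dual_glo", seed = 77)
  tbl <- simulate_dose_panel(default_panel_compounds(5), cfg)
  r1 <- run_compound_panel(tbl)
  r2 <- run_compound_panel(simulate_dose_panel(default_panel_compounds(5), cfg))
  expect_identical(r1$compounds, r2$compounds)
  expect_identical(r1$effects, r2$effects)
})
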