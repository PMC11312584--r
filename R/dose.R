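# panel-wide pooled residual variance of log counts per reporter; the
# generator's noise model is homoscedastic on the log scale, and pooling
# across the many small groups of a panel is the standard way to stabilise
# t-tests at triplicate sample sizes
pooled_log_variance <- function(summaries) {
  per_rep <- function(rep) {
    used <- summaries$used[summaries$reporter == rep]
    ss <- 0
    df <- 0
    for (u in used) {
      if (length(u) > 1) {
        lx <- log(u)
        ss <- ss + sum((lx - mean(lx))^2)
        df <- df + length(lx) - 1
      }
    }
    list(v = if (df > 0) ss / df else 0, df = df)
  }
  list(FF = per_rep("FF"), REN = per_rep("REN"))
}

pooled_t_p <- function(mx, nx, my, ny, pool) {
  if (pool$v == 0) {
    return(if (isTRUE(all.equal(mx, my))) 1 else 0)
  }
  t <- (mx - my) / sqrt(pool$v * (1 / nx + 1 / ny))
  2 * pt(-abs(t), df = pool$df)
}

panel_internals <- function(table, control_id, alpha, qc_policy, min_n) {
  validate_readouts(table)
  summaries <- summarize_groups(table, alpha = alpha, policy = qc_policy,
                                min_n = min_n)
  conditions <- parse_conditions(unique(table$group_id), control_id = control_id)
  if (!control_id %in% conditions$group_id) {
    stop("untreated control group '", control_id, "' missing from readouts",
         call. = FALSE)
  }
  ctrl <- summaries[summaries$group_id == control_id, , drop = FALSE]
  for (rep in c("FF", "REN")) {
    row <- ctrl[ctrl$reporter == rep, , drop = FALSE]
    if (nrow(row) != 1) {
      stop("control group lacks ", rep, " records", call. = FALSE)
    }
    if (row$n_used < min_n) {
      stop("control group has fewer than ", min_n, " usable ", rep,
           " readouts", call. = FALSE)
    }
  }
  list(summaries = summaries, conditions = conditions,
       pool = pooled_log_variance(summaries), control_id = control_id)
}

effects_from_internals <- function(int, var_method) {
  summ <- dplyr::left_join(int$summaries, int$conditions, by = "group_id")
  ctrl <- summ[summ$group_id == int$control_id, , drop = FALSE]
  treated <- summ[!is.na(summ$compound_id), , drop = FALSE]
  if (nrow(treated) == 0) {
    return(tibble::tibble(compound_id = character(), dose = double(),
                          ff_fold = double(), ren_fold = double(),
                          n_ff = integer(), n_ren = integer(),
                          p_ff = double(), p_ren = double()))
  }
  one_rep <- function(rep) {
    ctrl_row <- ctrl[ctrl$reporter == rep, ]
    ctrl_used <- ctrl_row$used[[1]]
    ctrl_logmean <- mean(log(ctrl_used))
    tr <- treated[treated$reporter == rep, , drop = FALSE]
    p <- if (var_method == "pooled") {
      pool <- int$pool[[rep]]
      purrr::map_dbl(tr$used, function(u) {
        pooled_t_p(mean(log(u)), length(u), ctrl_logmean, length(ctrl_used),
                   pool)
      })
    } else {
      purrr::map_dbl(tr$used, welch_log_p, y = ctrl_used)
    }
    tibble::tibble(compound_id = tr$compound_id, dose = tr$dose,
                   fold = tr$mean / ctrl_row$mean, n = tr$n_used, p = p)
  }
  ff <- one_rep("FF")
  ren <- one_rep("REN")
  out <- dplyr::full_join(
    dplyr::rename(ff, ff_fold = "fold", n_ff = "n", p_ff = "p"),
    dplyr::rename(ren, ren_fold = "fold", n_ren = "n", p_ren = "p"),
    by = c("compound_id", "dose")
  )
  dplyr::arrange(out, .data$compound_id, .data$dose)[
    , c("compound_id", "dose", "ff_fold", "ren_fold", "n_ff", "n_ren",
        "p_ff", "p_ren")]
}

#' Normalize a compound panel to the untreated control
#'
#' For each compound and dose, the mean reporter signal (after Grubbs
#' outlier screening) is divided by the mean of the shared untreated
#' control, and a two-sample test of treated vs control is run per reporter
#' on log counts. With `var_method = "pooled"` (the default) the test
#' variance is the residual log-scale variance pooled across every group of
#' the panel — appropriate for the homoscedastic multiplicative noise of
#' luminescence readouts and far more stable than per-pair variances at
#' triplicate sample sizes; `"welch"` uses unequal-variance two-sample tests
#' instead.
#'
#' @param table A panel readout table (groups `"<compound>:<dose>"` plus the
#'   control).
#' @param compound_id Optional single compound to restrict to.
#' @param control_id Group id of the untreated control.
#' @param alpha Significance level used during outlier screening.
#' @param qc_policy,min_n Outlier-screening settings; `min_n` also sets the
#'   minimal usable readouts required of the control.
#' @param var_method `"pooled"` or `"welch"`.
#' @return A tibble with one row per compound x dose: folds, usable counts
#'   and p-values per reporter, ordered by compound and increasing dose.
#' @export
#' @examples
#' cfg <- sim_config(assay = "dual_glo", seed = 2)
#' tbl <- simulate_dose_panel(
#'   list(effect_spec("C17", dose_model = list(m_top_ff = 1.7))), cfg)
#' normalize_to_control(tbl)
normalize_to_control <- function(table, compound_id = NULL,
                                 control_id = "control", alpha = 0.05,
                                 qc_policy = c("iterative", "single_pass"),
                                 min_n = 2,
                                 var_method = c("pooled", "welch")) {
  qc_policy <- match.arg(qc_policy)
  var_method <- match.arg(var_method)
  int <- panel_internals(table, control_id, alpha, qc_policy, min_n)
  out <- effects_from_internals(int, var_method)
  if (!is.null(compound_id)) {
    out <- out[out$compound_id %in% compound_id, , drop = FALSE]
  }
  out
}

trend_from_internals <- function(int, compound_id, reporter, var_method) {
  summ <- dplyr::left_join(int$summaries, int$conditions, by = "group_id")
  rows <- summ[!is.na(summ$compound_id) & summ$compound_id == compound_id &
                 summ$reporter == reporter, , drop = FALSE]
  if (nrow(rows) < 3) {
    stop("dose trend needs at least 3 doses for compound ", compound_id,
         call. = FALSE)
  }
  x <- rep(log10(rows$dose), times = lengths(rows$used))
  y <- log(unlist(rows$used))
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * y) / sxx
  if (var_method == "pooled") {
    pool <- int$pool[[reporter]]
    if (pool$v == 0) {
      return(if (slope > 1e-12) 0 else 1)
    }
    z <- slope / sqrt(pool$v / sxx)
    pt(z, df = pool$df, lower.tail = FALSE)
  } else {
    fit <- lm(y ~ x)
    tv <- coef(summary(fit))["x", "t value"]
    if (!is.finite(tv)) {
      return(if (slope > 1e-12) 0 else 1)
    }
    pt(tv, df = fit$df.residual, lower.tail = FALSE)
  }
}

#' Test for a positive dose trend
#'
#' One-sided p-value for a positive slope of log reporter signal against
#' log10 dose, over a compound's replicate-level (outlier-screened) readouts
#' across its dose groups. The shared control enters only through the
#' intercept and therefore cancels out of the slope. With
#' `var_method = "pooled"` the slope's standard error uses the panel-wide
#' pooled residual log variance.
#'
#' @param table A panel readout table.
#' @param compound_id Compound to test.
#' @param reporter `"FF"` or `"REN"`.
#' @inheritParams normalize_to_control
#' @return One-sided p-value; small values indicate reporter signal rising
#'   with dose.
#' @export
trend_test <- function(table, compound_id, reporter = c("FF", "REN"),
                       control_id = "control", alpha = 0.05,
                       qc_policy = c("iterative", "single_pass"), min_n = 2,
                       var_method = c("pooled", "welch")) {
  reporter <- match.arg(reporter)
  qc_policy <- match.arg(qc_policy)
  var_method <- match.arg(var_method)
  int <- panel_internals(table, control_id, alpha, qc_policy, min_n)
  trend_from_internals(int, compound_id, reporter, var_method)
}

#' Classify one compound from its dose-response profile
#'
#' Activity requires pharmacology-like evidence on the Firefly (protein of
#' interest) reporter: a significant increase at the top dose
#' (`p_ff <= alpha` with `ff_fold > 1`) together with a significant positive
#' dose trend (`trend_p_ff <= alpha`). An active compound is a
#' `selective_hit` when the Renilla control reporter stays unaltered at
#' every dose (`p_ren > alpha` throughout) and `minor_active` when Renilla
#' is also shifted somewhere; everything else is `inactive`. The class is a
#' deterministic function of the effects table, the trend p-value and
#' `alpha`.
#'
#' @param effects Per-dose effects of one compound, as returned by
#'   [normalize_to_control()] (rows for a single `compound_id`).
#' @param trend_p_ff One-sided dose-trend p-value for the Firefly reporter,
#'   see [trend_test()].
#' @param alpha Significance level.
#' @return `"selective_hit"`, `"minor_active"` or `"inactive"`.
#' @export
classify_compound <- function(effects, trend_p_ff, alpha = 0.05) {
  stopifnot(nrow(effects) >= 1, length(unique(effects$compound_id)) == 1)
  effects <- dplyr::arrange(effects, .data$dose)
  top <- effects[nrow(effects), ]
  active <- isTRUE(top$p_ff <= alpha && top$ff_fold > 1 &&
                     trend_p_ff <= alpha)
  if (!active) {
    "inactive"
  } else if (all(effects$p_ren > alpha)) {
    "selective_hit"
  } else {
    "minor_active"
  }
}

#' Run the full compound-panel analysis
#'
#' Composes the compound stage: control normalization with per-dose tests,
#' Firefly dose-trend tests, per-compound triage ([classify_compound()]) and
#' a panel-level Benjamini-Hochberg adjustment of the top-dose Firefly
#' p-values across compounds (reported as `q_top_ff` for panel-wide FDR
#' reading; the triage gate itself uses the per-compound rule).
#'
#' @inheritParams normalize_to_control
#' @param alpha Significance level for tests and triage.
#' @return An object of class `lux_panel`: a list with `effects` (per
#'   compound x dose), `compounds` (one row per compound: top-dose fold and
#'   p-value, trend p-value, `q_top_ff`, `class`), `alpha` and `var_method`.
#'   Supports [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `print()`.
#' @export
#' @examples
#' cfg <- sim_config(assay = "dual_glo", seed = 8)
#' tbl <- simulate_dose_panel(list(
#'   effect_spec("C17", dose_model = list(m_top_ff = 1.7)),
#'   effect_spec("C22")), cfg)
#' res <- run_compound_panel(tbl)
#' res$compounds
run_compound_panel <- function(table, control_id = "control", alpha = 0.05,
                               qc_policy = c("iterative", "single_pass"),
                               min_n = 2,
                               var_method = c("pooled", "welch")) {
  qc_policy <- match.arg(qc_policy)
  var_method <- match.arg(var_method)
  int <- panel_internals(table, control_id, alpha, qc_policy, min_n)
  effects <- effects_from_internals(int, var_method)
  compound_ids <- unique(effects$compound_id)
  if (length(compound_ids) == 0) {
    return(structure(list(
      effects = effects,
      compounds = tibble::tibble(compound_id = character(),
                                 top_dose = double(), top_ff_fold = double(),
                                 top_p_ff = double(), trend_p_ff = double(),
                                 q_top_ff = double(), class = character()),
      alpha = alpha, var_method = var_method
    ), class = "lux_panel"))
  }
  compounds <- purrr::map_dfr(compound_ids, function(id) {
    eff <- effects[effects$compound_id == id, , drop = FALSE]
    eff <- dplyr::arrange(eff, .data$dose)
    trend_p <- trend_from_internals(int, id, "FF", var_method)
    top <- eff[nrow(eff), ]
    tibble::tibble(
      compound_id = id,
      top_dose = top$dose,
      top_ff_fold = top$ff_fold,
      top_p_ff = top$p_ff,
      trend_p_ff = trend_p,
      class = classify_compound(eff, trend_p, alpha = alpha)
    )
  })
  compounds$q_top_ff <- p.adjust(compounds$top_p_ff, method = "BH")
  compounds <- compounds[, c("compound_id", "top_dose", "top_ff_fold",
                             "top_p_ff", "trend_p_ff", "q_top_ff", "class")]
  structure(list(effects = effects, compounds = compounds, alpha = alpha,
                 var_method = var_method),
            class = "lux_panel")
}

#' @export
print.lux_panel <- function(x, ...) {
  cat("Compound dose-panel result\n")
  cat("  compounds: ", nrow(x$compounds), "\n", sep = "")
  if (nrow(x$compounds) > 0) {
    counts <- table(factor(x$compounds$class,
                           levels = c("selective_hit", "minor_active",
                                      "inactive")))
    cat("  classes: ", paste(names(counts), as.integer(counts), sep = "=",
                             collapse = ", "), "\n", sep = "")
    act <- x$compounds$compound_id[x$compounds$class != "inactive"]
    cat("  active: ",
        if (length(act) > 0) paste(act, collapse = ", ") else "(none)",
        "\n", sep = "")
  }
  invisible(x)
}
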