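#' Simulation configuration for synthetic plate readouts
#'
#' Bundles the calibration and noise model of the synthetic readout
#' generator. Defaults reproduce the validated wild-type assay calibrations:
#' the library screen is read with the dual-luciferase assay (mean wild-type
#' Firefly signal `1.0e4` counts, Renilla `8.0e7` counts, 2 biological x 3
#' technical replicates), compound panels with the homogeneous Dual-Glo
#' variant (Firefly `2.5e3`, Renilla `1.7e5`, triplicate independent
#' cultures). The per-measurement coefficient of variation defaults to 0.24,
#' which makes twice the standard deviation of normalized wild-type Firefly
#' measurements equal 48%.
#'
#' Noise is multiplicative lognormal with a mean-one parameterization
#' (log-mean `-sigma^2/2`), split into a per-biological-replicate factor and
#' a per-measurement technical factor; `bio_fraction` is the share of the
#' total log-variance assigned to the biological level. The biological factor
#' of a given culture is shared between its Firefly and Renilla readouts
#' (both reporters are measured from the same extract).
#'
#' @param assay `"screen"` (dual-luciferase library screen) or `"dual_glo"`
#'   (compound panels); sets replicate and calibration defaults.
#' @param n_bio,n_tech Biological and technical replicate counts
#'   (`n_bio * n_tech >= 2`).
#' @param calib_ff,calib_ren Mean wild-type/untreated counts per reporter.
#' @param cv_total Coefficient of variation of a single measurement
#'   (`>= 0`; 0 gives the exact-calibration, zero-noise limit).
#' @param bio_fraction Fraction of log-variance at the biological level,
#'   in `[0, 1]`.
#' @param seed Integer seed; every simulation run is fully determined by the
#'   configuration including this seed.
#' @param doses Strictly increasing dose grid in molar units for panels.
#'   Default 1 nM to 100 uM in decade steps.
#' @return A list of class `lux_sim_config`.
#' @export
#' @examples
#' sim_config()                  # screen defaults
#' sim_config(assay = "dual_glo")  # compound-panel defaults
sim_config <- function(assay = c("screen", "dual_glo"),
                       n_bio = NULL, n_tech = NULL,
                       calib_ff = NULL, calib_ren = NULL,
                       cv_total = 0.24, bio_fraction = 0.5,
                       seed = 1L,
                       doses = 10^seq(-9, -4)) {
  assay <- match.arg(assay)
  defaults <- switch(assay,
    screen = list(n_bio = 2L, n_tech = 3L, calib_ff = 1.0e4, calib_ren = 8.0e7),
    dual_glo = list(n_bio = 3L, n_tech = 1L, calib_ff = 2.5e3, calib_ren = 1.7e5)
  )
  cfg <- list(
    assay = assay,
    n_bio = as.integer(n_bio %||% defaults$n_bio),
    n_tech = as.integer(n_tech %||% defaults$n_tech),
    calib_ff = as.double(calib_ff %||% defaults$calib_ff),
    calib_ren = as.double(calib_ren %||% defaults$calib_ren),
    cv_total = as.double(cv_total),
    bio_fraction = as.double(bio_fraction),
    seed = as.integer(seed),
    doses = as.double(doses)
  )
  if (cfg$n_bio < 1 || cfg$n_tech < 1 || cfg$n_bio * cfg$n_tech < 2) {
    stop("need n_bio, n_tech >= 1 with n_bio * n_tech >= 2", call. = FALSE)
  }
  if (cfg$calib_ff <= 0 || cfg$calib_ren <= 0) {
    stop("calibration means must be positive", call. = FALSE)
  }
  if (is.na(cfg$cv_total) || cfg$cv_total < 0) {
    stop("`cv_total` must be non-negative", call. = FALSE)
  }
  if (cfg$bio_fraction < 0 || cfg$bio_fraction > 1) {
    stop("`bio_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$doses) > 0) {
    if (any(cfg$doses <= 0)) stop("doses must be positive", call. = FALSE)
    if (any(diff(cfg$doses) <= 0)) {
      stop("doses must be strictly increasing", call. = FALSE)
    }
  }
  class(cfg) <- "lux_sim_config"
  cfg
}

#' Planted effect specification
#'
#' Describes the effect a strain (or compound) exerts on the mean reporter
#' signals. Multipliers are fold effects on the calibration mean; an absent
#' effect is the null (multiplier 1). For compounds, `dose_model` describes a
#' dose-dependent effect: at dose `d` the multiplier is
#' `1 + (m_top - 1) * (d / d_max)^h`, so the top dose attains `m_top` exactly
#' and the effect vanishes as the dose goes to zero (see
#' [dose_multiplier()]).
#'
#' @param target_id Strain gene id or compound id.
#' @param ff_multiplier,ren_multiplier Positive fold effects on the Firefly
#'   and Renilla means (constant across doses when no `dose_model`).
#' @param dose_model Optional list with elements `m_top_ff`, `m_top_ren`
#'   (top-dose multipliers, default 1) and exponent `h` (default 1, positive).
#' @return A list of class `lux_effect`.
#' @export
#' @examples
#' effect_spec("RPL40A", ff_multiplier = 2.7)              # selective strain
#' effect_spec("C17", dose_model = list(m_top_ff = 1.7))   # selective compound
effect_spec <- function(target_id, ff_multiplier = 1, ren_multiplier = 1,
                        dose_model = NULL) {
  stopifnot(is.character(target_id), length(target_id) == 1)
  if (!is.numeric(ff_multiplier) || ff_multiplier <= 0 ||
      !is.numeric(ren_multiplier) || ren_multiplier <= 0) {
    stop("effect multipliers must be positive", call. = FALSE)
  }
  if (!is.null(dose_model)) {
    dose_model <- modifyList(list(m_top_ff = 1, m_top_ren = 1, h = 1),
                             dose_model)
    if (dose_model$m_top_ff <= 0 || dose_model$m_top_ren <= 0 ||
        dose_model$h <= 0) {
      stop("dose model needs positive m_top_ff, m_top_ren and h", call. = FALSE)
    }
  }
  structure(list(target_id = target_id,
                 ff_multiplier = as.double(ff_multiplier),
                 ren_multiplier = as.double(ren_multiplier),
                 dose_model = dose_model),
            class = "lux_effect")
}

#' Dose-dependent effect multiplier
#'
#' Power-law interpolation between the null effect at vanishing dose and the
#' planted top-dose multiplier: `m(d) = 1 + (m_top - 1) * (d / d_max)^h`.
#'
#' @param dose Dose(s), same units as `d_max`; must be positive.
#' @param d_max Top dose of the grid.
#' @param m_top Multiplier attained exactly at `d_max`.
#' @param h Positive exponent steering how fast the effect sets in.
#' @return Numeric vector of multipliers.
#' @export
#' @examples
#' dose_multiplier(1e-4, 1e-4, m_top = 1.7)   # 1.7 at the top dose
#' dose_multiplier(1e-9, 1e-4, m_top = 1.7)   # ~1 five decades below
dose_multiplier <- function(dose, d_max, m_top, h = 1) {
  if (any(dose <= 0) || d_max <= 0) {
    stop("doses must be positive", call. = FALSE)
  }
  if (h <= 0) stop("`h` must be positive", call. = FALSE)
  1 + (m_top - 1) * (dose / d_max)^h
}

# mean-one lognormal noise factors; sdlog 0 degenerates to exactly 1
rlnorm1 <- function(n, sigma2) {
  rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
}

split_log_variance <- function(config) {
  sigma2 <- log(1 + config$cv_total^2)
  list(bio = config$bio_fraction * sigma2,
       tech = (1 - config$bio_fraction) * sigma2)
}

effects_by_target <- function(effects) {
  if (inherits(effects, "lux_effect")) effects <- list(effects)
  if (length(effects) == 0) {
    return(list())
  }
  if (!all(vapply(effects, inherits, logical(1), "lux_effect"))) {
    stop("`effects` must be a list of effect_spec() objects", call. = FALSE)
  }
  setNames(effects, vapply(effects, `[[`, character(1), "target_id"))
}

# draw one group's records for both reporters; B (bio factor) shared across
# reporters within a biological replicate
draw_group <- function(group_id, mult_ff, mult_ren, config, s2) {
  nb <- config$n_bio
  nt <- config$n_tech
  b <- rlnorm1(nb, s2$bio)
  t_ff <- rlnorm1(nb * nt, s2$tech)
  t_ren <- rlnorm1(nb * nt, s2$tech)
  bio_idx <- rep(seq_len(nb), each = nt)
  tibble::tibble(
    group_id = group_id,
    reporter = rep(c("FF", "REN"), each = nb * nt),
    bio_rep = rep(bio_idx, 2L),
    tech_rep = rep(rep(seq_len(nt), nb), 2L),
    counts = c(config$calib_ff * mult_ff * b[bio_idx] * t_ff,
               config$calib_ren * mult_ren * b[bio_idx] * t_ren)
  )
}

#' Simulate a library-screen readout table
#'
#' Draws synthetic dual-luciferase readouts for every usable vehicle of a
#' strain manifest (wild type plus each viable strain): one record per
#' vehicle x reporter x biological x technical replicate. Counts are
#' `calibration mean x planted multiplier x B_b x T_t` with mean-one
#' lognormal biological (`B`) and technical (`T`) factors whose log-variances
#' are split by `bio_fraction` so a single measurement has coefficient of
#' variation `cv_total`; the expectation of every count is therefore exactly
#' the calibration mean times the planted multiplier.
#'
#' @param manifest A `lux_manifest` (see [build_strain_manifest()]).
#' @param effects List of [effect_spec()] objects planting fold effects on
#'   viable strains. Effects on non-viable strains or unknown ids are errors.
#' @param config A [sim_config()]; the `seed` it carries makes the output
#'   bit-reproducible.
#' @return A `lux_readouts` tibble with
#'   `(1 + viable strains) * 2 * n_bio * n_tech` rows.
#' @export
#' @examples
#' m <- build_strain_manifest(2, 1)
#' tbl <- simulate_screen(m, list(effect_spec("G1", ff_multiplier = 2.7)),
#'                        sim_config(seed = 7))
#' nrow(tbl)  # 4 vehicles x 2 reporters x 6 replicates
simulate_screen <- function(manifest, effects = list(), config = sim_config()) {
  validate_manifest(manifest)
  stopifnot(inherits(config, "lux_sim_config"))
  eff <- effects_by_target(effects)
  wt <- manifest_wildtype(manifest)
  viable_ids <- manifest$gene_id[manifest$viable]
  unknown <- setdiff(names(eff), viable_ids)
  if (length(unknown) > 0) {
    nonv <- intersect(unknown, manifest$gene_id)
    if (length(nonv) > 0) {
      stop("effect planted on non-viable strain(s): ",
           paste(nonv, collapse = ", "), call. = FALSE)
    }
    stop("effect planted on unknown strain(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  s2 <- split_log_variance(config)
  groups <- c(wt, viable_ids)
  set.seed(config$seed)
  rows <- lapply(groups, function(g) {
    e <- eff[[g]]
    draw_group(g,
               mult_ff = if (is.null(e)) 1 else e$ff_multiplier,
               mult_ren = if (is.null(e)) 1 else e$ren_multiplier,
               config = config, s2 = s2)
  })
  lux_readouts(dplyr::bind_rows(rows),
               assay_variant = "dual_luciferase_screen")
}

#' Encode / decode panel condition ids
#'
#' Panel readout groups are encoded as `"<compound>:<dose>"` (dose in molar,
#' `format()`ed) with the shared untreated control as `"control"`.
#'
#' @param compound_id Compound identifier (must not contain `:`).
#' @param dose Dose in molar units.
#' @return `condition_id()` returns the encoded group id;
#'   `parse_conditions()` a tibble with `group_id`, `compound_id`, `dose`
#'   (`NA` for the control).
#' @export
condition_id <- function(compound_id, dose) {
  if (any(grepl(":", compound_id, fixed = TRUE))) {
    stop("compound ids must not contain ':'", call. = FALSE)
  }
  paste0(compound_id, ":", vapply(dose, format, character(1), scientific = TRUE))
}

#' @rdname condition_id
#' @param group_id Character vector of group ids.
#' @param control_id Group id of the untreated control.
#' @export
parse_conditions <- function(group_id, control_id = "control") {
  ids <- unique(group_id)
  is_ctrl <- ids == control_id
  has_colon <- grepl(":", ids, fixed = TRUE)
  if (any(!is_ctrl & !has_colon)) {
    stop("unparseable panel group id(s): ",
         paste(utils::head(ids[!is_ctrl & !has_colon], 5), collapse = ", "),
         call. = FALSE)
  }
  compound <- ifelse(is_ctrl, NA_character_, sub(":[^:]*$", "", ids))
  dose <- ifelse(is_ctrl, NA_real_,
                 suppressWarnings(as.numeric(sub("^.*:", "", ids))))
  if (any(!is_ctrl & (is.na(dose) | dose <= 0))) {
    stop("non-positive or unparseable dose in panel group id(s): ",
         paste(utils::head(ids[!is_ctrl & (is.na(dose) | dose <= 0)], 5),
               collapse = ", "), call. = FALSE)
  }
  tibble::tibble(group_id = ids, compound_id = compound, dose = dose)
}

#' Simulate a compound dose-panel readout table
#'
#' Draws synthetic Dual-Glo readouts for a compound panel: one untreated
#' control group plus one group per compound x dose, each with
#' `n_bio x n_tech` records per reporter. A compound's planted multiplier at
#' dose `d` follows its `dose_model` via [dose_multiplier()] (exactly
#' `m_top` at the top dose, approaching 1 at vanishing dose); compounds
#' without a dose model apply their constant multipliers at every dose, and
#' the null compound leaves all means at the control calibration.
#'
#' @param compounds List of [effect_spec()] objects, one per compound.
#' @param config A [sim_config()]; use `assay = "dual_glo"` for the
#'   compound-assay calibration. `config$doses` must be non-empty.
#' @param control_id Group id for the untreated control.
#' @return A `lux_readouts` tibble with assay variant `"dual_glo_compound"`
#'   and `(1 + n_compounds * n_doses) * 2 * n_bio * n_tech` rows.
#' @export
#' @examples
#' cfg <- sim_config(assay = "dual_glo", seed = 11)
#' tbl <- simulate_dose_panel(
#'   list(effect_spec("C17", dose_model = list(m_top_ff = 1.7))), cfg)
#' dplyr::count(tbl, group_id)
simulate_dose_panel <- function(compounds, config = sim_config(assay = "dual_glo"),
                                control_id = "control") {
  stopifnot(inherits(config, "lux_sim_config"))
  if (length(config$doses) == 0) {
    stop("`config$doses` must be non-empty", call. = FALSE)
  }
  eff <- effects_by_target(compounds)
  if (any(names(eff) == control_id)) {
    stop("compound id clashes with the control id", call. = FALSE)
  }
  if (any(grepl(":", names(eff), fixed = TRUE))) {
    stop("compound ids must not contain ':'", call. = FALSE)
  }
  s2 <- split_log_variance(config)
  d_max <- max(config$doses)
  set.seed(config$seed)
  rows <- vector("list", 1L + length(eff) * length(config$doses))
  rows[[1]] <- draw_group(control_id, 1, 1, config, s2)
  k <- 1L
  for (id in names(eff)) {
    e <- eff[[id]]
    for (d in config$doses) {
      if (is.null(e$dose_model)) {
        mf <- e$ff_multiplier
        mr <- e$ren_multiplier
      } else {
        mf <- dose_multiplier(d, d_max, e$dose_model$m_top_ff, e$dose_model$h)
        mr <- dose_multiplier(d, d_max, e$dose_model$m_top_ren, e$dose_model$h)
      }
      k <- k + 1L
      rows[[k]] <- draw_group(condition_id(id, d), mf, mr, config, s2)
    }
  }
  lux_readouts(dplyr::bind_rows(rows), assay_variant = "dual_glo_compound")
}
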