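#' Grubbs test statistic
#'
#' Computes `G = max_i |x_i - mean(x)| / s` with `s` the sample standard
#' deviation (n - 1 denominator), together with the index of the candidate
#' outlier (the value furthest from the mean). `G` is invariant under affine
#' transformations of the data.
#'
#' @param values Numeric vector, `n >= 3`, with positive sample variance.
#' @return A list with elements `G` and `candidate` (index into `values`).
#' @export
#' @examples
#' grubbs_statistic(c(1, 2, 3))$G           # 1
#' grubbs_statistic(c(0, 0, 0, 0, 0, 9))$G  # ~2.041
grubbs_statistic <- function(values) {
  values <- as.double(values)
  n <- length(values)
  if (n < 3) stop("Grubbs test needs at least 3 values", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate sample: zero variance", call. = FALSE)
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  list(G = dev[idx] / s, candidate = idx)
}

#' Two-sided Grubbs critical value
#'
#' Closed form `((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` with `t` the
#' upper `alpha / (2 n)` quantile of Student's t on `n - 2` degrees of
#' freedom. As `alpha` tends to 0 the critical value approaches its upper
#' bound `(n - 1) / sqrt(n)`.
#'
#' @param n Sample size, `>= 3`.
#' @param alpha Significance level in `(0, 1)`.
#' @return Positive scalar critical value.
#' @export
#' @examples
#' grubbs_critical(6, 0.05)  # ~1.887
#' grubbs_critical(3, 0.05)  # ~1.1543
grubbs_critical <- function(n, alpha = 0.05) {
  if (length(n) != 1 || is.na(n) || n < 3 || n != round(n)) {
    stop("`n` must be an integer >= 3", call. = FALSE)
  }
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  t <- qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))
}

#' Run the Grubbs outlier test once
#'
#' @param values Numeric vector (`n >= 3`, non-degenerate).
#' @param alpha Significance level.
#' @return A list with `G`, `G_crit`, `n`, `alpha` and `outlier_index`
#'   (`NA` unless `G > G_crit`).
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  g <- grubbs_statistic(values)
  crit <- grubbs_critical(length(values), alpha)
  list(G = g$G, G_crit = crit, n = length(values), alpha = alpha,
       outlier_index = if (g$G > crit) g$candidate else NA_integer_)
}

#' Flag outlying readouts in one replicate group
#'
#' Applies the two-sided Grubbs test to a group of readouts and returns the
#' keys of flagged values in removal order. Under the `"iterative"` policy
#' (the default) the test is re-run after each removal until no value exceeds
#' the critical value or a further removal would leave fewer than `min_n`
#' values; `"single_pass"` tests at most once.
#'
#' @param values Numeric vector (optionally named; names are used as keys,
#'   otherwise positions are).
#' @param alpha Significance level of each pass.
#' @param policy `"iterative"` or `"single_pass"`.
#' @param min_n Minimum number of retained values per group.
#' @return Character or integer vector of removed keys (possibly empty).
#' @export
#' @examples
#' flag_outliers(c(1, 2, 3))                 # none: G = 1 < 1.1543
#' flag_outliers(c(0, 0, 0, 0, 0, 9))        # the 9 is flagged
flag_outliers <- function(values, alpha = 0.05,
                          policy = c("iterative", "single_pass"),
                          min_n = 4) {
  policy <- match.arg(policy)
  keys <- names(values) %||% seq_along(values)
  x <- as.double(values)
  if (length(x) < 3) stop("Grubbs test needs at least 3 values", call. = FALSE)
  removed <- keys[0]
  repeat {
    if (length(x) < 3 || length(x) - 1 < min_n) break
    s <- sd(x)
    if (!is.finite(s) || s == 0) break
    res <- grubbs_test(x, alpha)
    if (is.na(res$outlier_index)) break
    removed <- c(removed, keys[res$outlier_index])
    keys <- keys[-res$outlier_index]
    x <- x[-res$outlier_index]
    if (policy == "single_pass") break
  }
  removed
}

#' Per-group descriptive statistics after outlier removal
#'
#' For every group x reporter the readouts are screened with the Grubbs test
#' (see [flag_outliers()]); the mean and standard deviation are then computed
#' on the retained raw counts. Groups too small for the test (`n < 3`) are
#' summarized without outlier screening.
#'
#' Because luminescence noise is multiplicative, the Grubbs screening is
#' performed on the log-transformed counts, where the test's normality
#' assumption actually holds; on the raw scale the test systematically
#' over-flags the long right tail of the lognormal and biases the trimmed
#' means. Reported means and standard deviations are computed on the raw
#' retained counts.
#'
#' @param table A readout table.
#' @param alpha,policy,min_n Outlier-screening settings, see
#'   [flag_outliers()].
#' @return A tibble with one row per group x reporter: `group_id`,
#'   `reporter`, `n_raw`, `n_used`, `mean`, `sd`, `outliers` (list column of
#'   flagged replicate keys `"bio.tech"`), and `used` (list column of
#'   retained counts, named by replicate key).
#' @export
summarize_groups <- function(table, alpha = 0.05,
                             policy = c("iterative", "single_pass"),
                             min_n = 4) {
  policy <- match.arg(policy)
  validate_readouts(table)
  table |>
    dplyr::group_by(.data$group_id, .data$reporter) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      res = {
        x <- setNames(.data$counts, paste(.data$bio_rep, .data$tech_rep, sep = "."))
        out <- if (length(x) >= 3) {
          flag_outliers(log(x), alpha = alpha, policy = policy, min_n = min_n)
        } else {
          character(0)
        }
        used <- x[!(names(x) %in% out)]
        list(list(outliers = out, used = used))
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      outliers = purrr::map(.data$res, "outliers"),
      used = purrr::map(.data$res, "used"),
      n_used = purrr::map_int(.data$used, length),
      mean = purrr::map_dbl(.data$used, mean),
      sd = purrr::map_dbl(.data$used, function(u) if (length(u) > 1) sd(u) else NA_real_)
    ) |>
    dplyr::select("group_id", "reporter", "n_raw", "n_used", "mean", "sd",
                  "outliers", "used")
}

#' Drop non-viable strains from a screen readout table
#'
#' Removes all records of strains flagged non-viable in the manifest; the
#' wild-type vehicle is always kept. Records for groups absent from the
#' manifest (other than the wild type) are an error.
#'
#' @param table A readout table.
#' @param manifest A `lux_manifest`.
#' @return The filtered readout table; the number of usable vehicles is
#'   reported via a message.
#' @export
filter_viable <- function(table, manifest) {
  validate_manifest(manifest)
  wt <- manifest_wildtype(manifest)
  groups <- unique(table$group_id)
  unknown <- setdiff(groups, c(wt, manifest$gene_id))
  if (length(unknown) > 0) {
    stop("readout group(s) not in manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  nonviable <- manifest$gene_id[!manifest$viable]
  dropped <- intersect(groups, nonviable)
  out <- lux_readouts(table[!(table$group_id %in% nonviable), , drop = FALSE],
                      assay_variant = assay_variant(table), validate = FALSE)
  message(length(dropped), " non-viable strain(s) removed; ",
          length(unique(out$group_id)), " usable vehicle(s) remain")
  out
}
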