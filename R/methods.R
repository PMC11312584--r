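#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a screen result
#'
#' One row per analysed vehicle with folds, distance, test results and
#' class; the wild type appears with `is_wildtype = TRUE` and class `NA`.
#'
#' @param x A `lux_screen` object from [run_screen()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lux_screen <- function(x, ...) {
  x$points
}

#' Glance at a screen result
#'
#' @param x A `lux_screen` object.
#' @param ... Unused.
#' @return A one-row tibble with the reporter concordance `rho`, the inert
#'   radius, the Renilla band, strain counts per class and the hit count.
#' @export
glance.lux_screen <- function(x, ...) {
  counts <- as.list(as.integer(x$class_counts))
  names(counts) <- paste0("n_", names(x$class_counts))
  tibble::tibble(
    n_strains = sum(!x$points$is_wildtype),
    rho = x$rho,
    radius = x$radius,
    ren_band = x$ren_band,
    !!!counts,
    n_hits = length(x$hits),
    alpha = x$alpha
  )
}

#' Tidy a panel result
#'
#' @param x A `lux_panel` object from [run_compound_panel()].
#' @param ... Unused.
#' @return The per compound x dose effects tibble, joined with each
#'   compound's class.
#' @export
tidy.lux_panel <- function(x, ...) {
  dplyr::left_join(x$effects,
                   x$compounds[, c("compound_id", "class")],
                   by = "compound_id")
}

#' Glance at a panel result
#'
#' @param x A `lux_panel` object.
#' @param ... Unused.
#' @return A one-row tibble with compound counts per class.
#' @export
glance.lux_panel <- function(x, ...) {
  counts <- table(factor(x$compounds$class,
                         levels = c("selective_hit", "minor_active",
                                    "inactive")))
  tibble::tibble(
    n_compounds = nrow(x$compounds),
    n_selective_hit = as.integer(counts[["selective_hit"]]),
    n_minor_active = as.integer(counts[["minor_active"]]),
    n_inactive = as.integer(counts[["inactive"]]),
    n_active = nrow(x$compounds) - as.integer(counts[["inactive"]]),
    alpha = x$alpha
  )
}

#' Correlation plot of a screen result
#'
#' Reproduces the screen's fold-space view: one point per strain at
#' (Firefly fold, Renilla fold), the square of two-fold change up and down,
#' the inert circle of the estimated radius centred on the wild type at
#' (1, 1), and labels on the selective hits.
#'
#' @param object A `lux_screen` object.
#' @param label_hits Label selective hits with their strain ids?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lux_screen <- function(object, label_hits = TRUE, ...) {
  pts <- object$points[!object$points$is_wildtype, , drop = FALSE]
  theta <- seq(0, 2 * pi, length.out = 181)
  circle <- tibble::tibble(x = 1 + object$radius * cos(theta),
                           y = 1 + object$radius * sin(theta))
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$ff_fold,
                                         y = .data$ren_fold)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 2, ymin = 0, ymax = 2,
                      fill = NA, colour = "grey60", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 1, colour = "grey80") +
    ggplot2::geom_path(data = circle, ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2) +
    ggplot2::annotate("point", x = 1, y = 1, shape = 3, size = 3) +
    ggplot2::labs(x = "Firefly fold change (vs wild type)",
                  y = "Renilla fold change (vs wild type)",
                  colour = "class") +
    ggplot2::theme_minimal()
  hits <- pts[!is.na(pts$class) & pts$class == "selective_hit", , drop = FALSE]
  if (label_hits && nrow(hits) > 0) {
    p <- p + ggplot2::geom_text(data = hits,
                                ggplot2::aes(label = .data$strain_id),
                                vjust = -1, size = 3)
  }
  p
}

#' Dose-response plot of a panel result
#'
#' Grouped bars of the control-normalized Firefly and Renilla folds per
#' dose, one facet per compound, with the control level at 1 marked.
#'
#' @param object A `lux_panel` object.
#' @param compounds Optional character vector restricting the facets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lux_panel <- function(object, compounds = NULL, ...) {
  eff <- object$effects
  if (!is.null(compounds)) {
    eff <- eff[eff$compound_id %in% compounds, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    eff[, c("compound_id", "dose", "ff_fold", "ren_fold")],
    cols = c("ff_fold", "ren_fold"),
    names_to = "reporter", values_to = "fold"
  )
  long$reporter <- ifelse(long$reporter == "ff_fold", "FF", "REN")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$dose), y = .data$fold,
                                     fill = .data$reporter)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~compound_id) +
    ggplot2::labs(x = "dose (M)", y = "fold change vs untreated control",
                  fill = "reporter") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
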