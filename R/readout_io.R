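#' Construct a readout table
#'
#' A readout table is the long-form record of a plate-reader run: one row per
#' luminescence measurement, keyed by vehicle/condition (`group_id`),
#' reporter (`"FF"` for Firefly, `"REN"` for Renilla), biological replicate
#' and technical replicate, with the measured luciferase light-unit counts.
#'
#' @param x A data frame with columns `group_id`, `reporter`, `bio_rep`,
#'   `tech_rep`, `counts`.
#' @param assay_variant Which assay produced the readouts:
#'   `"dual_luciferase_screen"` (library screen) or `"dual_glo_compound"`
#'   (homogeneous compound panels). Stored as an attribute.
#' @param validate Run [validate_readouts()] on the result?
#' @return A tibble of class `lux_readouts`.
#' @export
lux_readouts <- function(x, assay_variant = c("dual_luciferase_screen",
                                              "dual_glo_compound"),
                         validate = TRUE) {
  assay_variant <- match.arg(assay_variant)
  req <- c("group_id", "reporter", "bio_rep", "tech_rep", "counts")
  missing <- setdiff(req, names(x))
  if (length(missing) > 0) {
    stop("readout table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    group_id = as.character(x$group_id),
    reporter = as.character(x$reporter),
    bio_rep = as.integer(x$bio_rep),
    tech_rep = as.integer(x$tech_rep),
    counts = as.double(x$counts)
  )
  attr(out, "assay_variant") <- assay_variant
  class(out) <- c("lux_readouts", class(out))
  if (validate) validate_readouts(out)
  out
}

#' Assay variant of a readout table
#' @param table A readout table.
#' @return `"dual_luciferase_screen"` or `"dual_glo_compound"`.
#' @export
assay_variant <- function(table) {
  attr(table, "assay_variant") %||% "dual_luciferase_screen"
}

#' Validate a readout table
#'
#' Enforces the structural invariants of a plate readout: positive counts,
#' unique (`group_id`, `reporter`, `bio_rep`, `tech_rep`) keys, both
#' reporters present for every group, and replicate indices that form
#' contiguous ranges starting at 1 within each group and reporter. Errors
#' name the offending rows or groups.
#'
#' @param table A readout table (see [lux_readouts()]).
#' @return The table, invisibly, or an error.
#' @export
validate_readouts <- function(table) {
  req <- c("group_id", "reporter", "bio_rep", "tech_rep", "counts")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0) {
    stop("readout table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(table) == 0) {
    return(invisible(table))
  }
  bad_rep <- which(!table$reporter %in% c("FF", "REN"))
  if (length(bad_rep) > 0) {
    stop("invalid reporter (must be FF or REN) in row(s): ",
         paste(utils::head(bad_rep, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(table$counts) | table$counts <= 0)
  if (length(bad) > 0) {
    stop("non-positive counts in row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(table$group_id, table$reporter, table$bio_rep, table$tech_rep,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    first <- match(key[dup], key)
    stop("duplicate readout key in row(s): ",
         paste(utils::head(paste0(dup, " (first at ", first, ")"), 5),
               collapse = ", "), call. = FALSE)
  }
  by_group <- split(table$reporter, table$group_id)
  lacking <- names(by_group)[!vapply(by_group, function(r)
    all(c("FF", "REN") %in% r), logical(1))]
  if (length(lacking) > 0) {
    miss <- vapply(lacking, function(g) {
      setdiff(c("FF", "REN"), by_group[[g]])[1]
    }, character(1))
    stop("group(s) lack records for one reporter: ",
         paste(utils::head(paste0(lacking, " lacks ", miss), 5), collapse = "; "),
         call. = FALSE)
  }
  grp <- paste(table$group_id, table$reporter, sep = "\r")
  for (g in unique(grp)) {
    sel <- grp == g
    bio <- sort(unique(table$bio_rep[sel]))
    if (!identical(bio, seq_len(max(bio)))) {
      stop("non-contiguous biological replicate indices in group ",
           table$group_id[sel][1], call. = FALSE)
    }
    for (b in bio) {
      tech <- sort(unique(table$tech_rep[sel & table$bio_rep == b]))
      if (!identical(tech, seq_len(max(tech)))) {
        stop("non-contiguous technical replicate indices in group ",
             table$group_id[sel][1], call. = FALSE)
      }
    }
  }
  invisible(table)
}

#' Read plate readouts from CSV
#'
#' Reads the package's readout dialect: a UTF-8, comma-delimited file with
#' header `group_id,reporter,bio_rep,tech_rep,counts`. Scientific notation is
#' accepted for counts. The file is validated on read; duplicate keys,
#' non-positive counts and groups missing a reporter are rejected with
#' informative errors.
#'
#' @param path Path to a CSV file.
#' @param assay_variant Assay variant to attach (not stored in the file).
#' @return A validated `lux_readouts` tibble.
#' @export
read_readouts <- function(path, assay_variant = c("dual_luciferase_screen",
                                                  "dual_glo_compound")) {
  assay_variant <- match.arg(assay_variant)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE))
  req <- c("group_id", "reporter", "bio_rep", "tech_rep", "counts")
  missing <- setdiff(req, header)
  if (length(missing) > 0) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    group_id = readr::col_character(),
    reporter = readr::col_character(),
    bio_rep = readr::col_integer(),
    tech_rep = readr::col_integer(),
    counts = readr::col_double()
  ), progress = FALSE)
  lux_readouts(df, assay_variant = assay_variant, validate = TRUE)
}

#' Write plate readouts to CSV
#'
#' Writes the fixed dialect read by [read_readouts()]: UTF-8,
#' comma-delimited, header `group_id,reporter,bio_rep,tech_rep,counts`, rows
#' in deterministic (group, reporter, bio, tech) order. Output is
#' byte-identical across runs for the same table, and an empty table yields a
#' header-only file.
#'
#' @param table A readout table.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_readouts <- function(table, path) {
  validate_readouts(table)
  ord <- order(table$group_id, table$reporter, table$bio_rep, table$tech_rep,
               method = "radix")
  out <- as.data.frame(table[ord, c("group_id", "reporter", "bio_rep",
                                    "tech_rep", "counts")])
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
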