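#' Packaged ribosomal-protein gene catalogue
#'
#' Returns the gene list shipped with the package: 19 single-copy genes and
#' 59 duplicated (A/B paralog) gene pairs, 137 genes in total, in the naming
#' style of the yeast cytoplasmic ribosomal-protein genes. The list is a
#' constructed (synthetic) stand-in for the real library catalogue: gene and
#' protein identifiers follow the RPL/RPS convention and include the nine
#' gene ids that are non-viable under screening culture conditions
#' (`nonviable_rp_genes()`), but the exact membership of the real collection
#' is not reproduced.
#'
#' @return A tibble with columns `gene_id`, `protein_id`, `copy_class`
#'   (`"single"` or `"duplicated"`) and `paralog_partner` (`NA` for
#'   single-copy genes).
#' @export
#' @examples
#' rp_gene_catalog()
rp_gene_catalog <- function() {
  path <- system.file("extdata", "rp_genes_synthetic.csv", package = "luxscreen",
                      mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  df$paralog_partner[df$paralog_partner == ""] <- NA_character_
  tibble::as_tibble(df)
}

#' Gene ids of the non-viable library strains
#'
#' The nine ribosomal-protein gene deletions that did not grow under the
#' screening culture conditions and are excluded from the usable library.
#'
#' @return Character vector of nine gene ids.
#' @export
nonviable_rp_genes <- function() {
  c("RPL4B", "RPL5", "RPS8B", "RPL9B", "RPL11A",
    "RPL14B", "RPS26A", "RPL31B", "RPL36B")
}

#' Build a strain manifest for a reporter screen library
#'
#' Assembles the manifest of a ribosomal-variant-strain (RVS) library:
#' `n_single` single-copy genes plus `n_pairs` duplicated paralog pairs,
#' i.e. `n_single + 2 * n_pairs` strains, each heterozygous for deletion of
#' one gene, plus one wild-type vehicle. Strains listed in `nonviable_ids`
#' are flagged non-viable and are excluded from screening by
#' [filter_viable()].
#'
#' When `genes` is `NULL`, gene names are taken from the packaged catalogue
#' ([rp_gene_catalog()]) if it holds enough singles and pairs; otherwise
#' systematic names (`G1`, ..., and `P1A`/`P1B`, ...) are generated.
#'
#' @param n_single Number of single-copy genes.
#' @param n_pairs Number of duplicated paralog pairs (each contributes two
#'   genes).
#' @param nonviable_ids Character vector of gene ids flagged non-viable. Must
#'   all occur in the generated gene list.
#' @param genes Optional gene table (columns `gene_id`, `protein_id`,
#'   `copy_class`, `paralog_partner`) to draw names from.
#' @param wildtype_id Identifier of the wild-type vehicle; must differ from
#'   every gene id.
#' @return A tibble of class `lux_manifest` with one row per strain and
#'   columns `gene_id`, `protein_id`, `copy_class`, `paralog_partner` and
#'   `viable`; the wild-type id is stored in the `wildtype_id` attribute.
#' @seealso [n_usable_vehicles()], [filter_viable()]
#' @export
#' @examples
#' m <- build_strain_manifest(19, 59, nonviable_rp_genes())
#' nrow(m)               # 137 strains
#' n_usable_vehicles(m)  # 129 = 1 wild type + 128 viable strains
build_strain_manifest <- function(n_single, n_pairs,
                                  nonviable_ids = character(),
                                  genes = NULL,
                                  wildtype_id = "WT") {
  stopifnot(length(n_single) == 1, length(n_pairs) == 1)
  n_single <- as.integer(n_single)
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_single) || is.na(n_pairs) || n_single < 0 || n_pairs < 0) {
    stop("`n_single` and `n_pairs` must be non-negative integers", call. = FALSE)
  }
  if (n_single + n_pairs == 0) {
    stop("manifest must contain at least one strain", call. = FALSE)
  }

  if (is.null(genes)) {
    catalog <- rp_gene_catalog()
    n_cat_single <- sum(catalog$copy_class == "single")
    n_cat_pairs <- sum(catalog$copy_class == "duplicated") / 2
    # the catalogue names the full library; smaller toy manifests get
    # systematic synthetic names (G1, ..., GkA/GkB)
    genes <- if (n_single == n_cat_single && n_pairs == n_cat_pairs) {
      catalog
    } else {
      synthetic_gene_table(n_single, n_pairs)
    }
  }
  singles <- genes[genes$copy_class == "single", , drop = FALSE]
  pairs <- genes[genes$copy_class == "duplicated", , drop = FALSE]
  if (nrow(singles) < n_single || nrow(pairs) < 2 * n_pairs) {
    stop("gene table does not hold enough singles/pairs for the requested manifest",
         call. = FALSE)
  }
  pair_stems <- unique(pairs$protein_id)[seq_len(n_pairs)]
  out <- dplyr::bind_rows(
    singles[seq_len(n_single), , drop = FALSE],
    pairs[pairs$protein_id %in% pair_stems, , drop = FALSE]
  )

  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene ids in manifest", call. = FALSE)
  }
  if (wildtype_id %in% out$gene_id) {
    stop("`wildtype_id` must differ from all gene ids", call. = FALSE)
  }
  unknown <- setdiff(nonviable_ids, out$gene_id)
  if (length(unknown) > 0) {
    stop("unknown non-viable gene id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out$viable <- !(out$gene_id %in% nonviable_ids)
  out <- tibble::as_tibble(out)
  attr(out, "wildtype_id") <- wildtype_id
  class(out) <- c("lux_manifest", class(out))
  validate_manifest(out)
}

synthetic_gene_table <- function(n_single, n_pairs) {
  empty <- tibble::tibble(gene_id = character(), protein_id = character(),
                          copy_class = character(), paralog_partner = character())
  singles <- if (n_single > 0) {
    stems <- paste0("G", seq_len(n_single))
    tibble::tibble(gene_id = stems, protein_id = paste0("p", stems),
                   copy_class = "single", paralog_partner = NA_character_)
  } else {
    empty
  }
  pairs <- if (n_pairs > 0) {
    stems <- paste0("G", n_single + seq_len(n_pairs))
    a <- paste0(stems, "A")
    b <- paste0(stems, "B")
    tibble::tibble(gene_id = c(rbind(a, b)),
                   protein_id = rep(paste0("p", stems), each = 2),
                   copy_class = "duplicated",
                   paralog_partner = c(rbind(b, a)))
  } else {
    empty
  }
  dplyr::bind_rows(singles, pairs)
}

#' Validate a strain manifest
#'
#' Checks the structural invariants of a manifest: unique gene ids, paralog
#' partners that exist and point back at each other, single-copy genes
#' without a partner, and a wild-type id distinct from all gene ids.
#'
#' @param manifest A `lux_manifest` tibble.
#' @return The manifest, invisibly unchanged, or an error.
#' @export
validate_manifest <- function(manifest) {
  req <- c("gene_id", "protein_id", "copy_class", "paralog_partner", "viable")
  missing <- setdiff(req, names(manifest))
  if (length(missing) > 0) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(manifest$gene_id)) {
    stop("duplicate gene ids in manifest", call. = FALSE)
  }
  if (!all(manifest$copy_class %in% c("single", "duplicated"))) {
    stop("copy_class must be 'single' or 'duplicated'", call. = FALSE)
  }
  sing <- manifest$copy_class == "single"
  if (any(!is.na(manifest$paralog_partner[sing]))) {
    stop("single-copy genes must not have a paralog partner", call. = FALSE)
  }
  dup <- manifest[!sing, , drop = FALSE]
  if (nrow(dup) > 0) {
    if (any(is.na(dup$paralog_partner)) ||
        !all(dup$paralog_partner %in% manifest$gene_id)) {
      stop("every duplicated gene needs a partner present in the manifest",
           call. = FALSE)
    }
    back <- manifest$paralog_partner[match(dup$paralog_partner, manifest$gene_id)]
    if (!identical(back, dup$gene_id)) {
      stop("paralog partners must point back at each other", call. = FALSE)
    }
  }
  wt <- manifest_wildtype(manifest)
  if (wt %in% manifest$gene_id) {
    stop("`wildtype_id` must differ from all gene ids", call. = FALSE)
  }
  invisible(manifest)
}

#' Wild-type vehicle id of a manifest
#' @param manifest A `lux_manifest` tibble.
#' @return The wild-type identifier (scalar character).
#' @export
manifest_wildtype <- function(manifest) {
  attr(manifest, "wildtype_id") %||% "WT"
}

#' Count usable screening vehicles
#'
#' One wild-type vehicle plus every viable library strain.
#'
#' @param manifest A `lux_manifest` tibble.
#' @return Integer count.
#' @export
n_usable_vehicles <- function(manifest) {
  1L + sum(manifest$viable)
}

#' Write / read a strain manifest as CSV
#'
#' The on-disk format is a plain comma-separated file with columns
#' `gene_id`, `protein_id`, `copy_class`, `paralog_partner`, `viable`.
#' The wild-type id is not part of the table; supply it again on read.
#'
#' @param manifest A `lux_manifest` tibble.
#' @param path File path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   returns a validated `lux_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  readr::write_csv(as.data.frame(manifest), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param wildtype_id Wild-type vehicle id to attach on read.
#' @export
read_manifest <- function(path, wildtype_id = "WT") {
  df <- readr::read_csv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    protein_id = readr::col_character(),
    copy_class = readr::col_character(),
    paralog_partner = readr::col_character(),
    viable = readr::col_logical()
  ), progress = FALSE)
  out <- tibble::as_tibble(df)
  attr(out, "wildtype_id") <- wildtype_id
  class(out) <- c("lux_manifest", class(out))
  validate_manifest(out)
  out
}
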