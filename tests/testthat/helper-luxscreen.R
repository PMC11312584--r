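# Builders for small in-code fixtures.

# A readout table with constant (noise-free) counts per group x reporter.
# `ff` and `ren` are named vectors of per-group mean counts.
const_readouts <- function(ff, ren, n_bio = 2, n_tech = 3,
                           assay = "dual_luciferase_screen") {
  stopifnot(identical(names(ff), names(ren)))
  rows <- lapply(names(ff), function(g) {
    tibble::tibble(
      group_id = g,
      reporter = rep(c("FF", "REN"), each = n_bio * n_tech),
      bio_rep = rep(rep(seq_len(n_bio), each = n_tech), 2),
      tech_rep = rep(rep(seq_len(n_tech), n_bio), 2),
      counts = c(rep(ff[[g]], n_bio * n_tech), rep(ren[[g]], n_bio * n_tech))
    )
  })
  lux_readouts(dplyr::bind_rows(rows), assay_variant = assay)
}

# A random but valid readout table (for round-trip properties).
random_readouts <- function(seed, n_groups = 4) {
  set.seed(seed)
  rows <- lapply(seq_len(n_groups), function(i) {
    n_bio <- sample(1:3, 1)
    n_tech <- sample(1:4, 1)
    if (n_bio * n_tech < 2) n_tech <- 2
    tibble::tibble(
      group_id = paste0("grp", i),
      reporter = rep(c("FF", "REN"), each = n_bio * n_tech),
      bio_rep = rep(rep(seq_len(n_bio), each = n_tech), 2),
      tech_rep = rep(rep(seq_len(n_tech), n_bio), 2),
      counts = rlnorm(2 * n_bio * n_tech, meanlog = log(1e4), sdlog = 1.5)
    )
  })
  lux_readouts(dplyr::bind_rows(rows))
}

# Normalized-points tibble for direct classification/correlation tests.
make_points <- function(ff, ren, q_ff = rep(1, length(ff)),
                        q_ren = rep(1, length(ff)), wildtype = FALSE) {
  tibble::tibble(
    strain_id = paste0("S", seq_along(ff)),
    ff_fold = ff, ren_fold = ren,
    distance = sqrt((ff - 1)^2 + (ren - 1)^2),
    n_ff = 6L, n_ren = 6L,
    p_ff = q_ff, p_ren = q_ren, q_ff = q_ff, q_ren = q_ren,
    is_wildtype = wildtype
  )
}

# Published two-sided Grubbs critical values at alpha = 0.05 (reference
# tables), used as an independent oracle for small n.
GRUBBS_TABLE_05 <- c(`3` = 1.1543, `4` = 1.4812, `5` = 1.7150,
                     `6` = 1.8871, `7` = 2.0200, `8` = 2.1266)
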