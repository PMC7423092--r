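#' Precompute the atom-voxel cache for one entry
#'
#' For every usable atom, stores the significant voxels within
#' `max_radius`, so that density clouds at any radius up to that bound can
#' be evaluated by filtering on distance. Used by [analyze_entry()] and the
#' radius optimizer.
#'
#' @param structure An `ed_structure`.
#' @param map The 2Fo-Fc `ed_map`.
#' @param significance Sigma multiple defining significant voxels (1.5,
#'   the 2Fo-Fc convention); only consulted when `threshold_sum` is TRUE.
#' @param threshold_sum If TRUE, cloud sums run over significant voxels
#'   only. The default (FALSE) sums all voxels within the radius: on
#'   zero-meaned maps the negative background then penalizes oversized
#'   radii, which keeps the radius optimization identifiable (see the
#'   methods vignette).
#' @param max_radius Upper bound for any attribution radius (default 1.5).
#' @return An object of class `ed_cache`.
#' @export
entry_cache <- function(structure, map, significance = 1.5,
                        threshold_sum = FALSE, max_radius = 1.5) {
  atoms <- structure$atoms
  if (!nrow(atoms)) abort("structure has no typed atoms")
  stats <- map_statistics(map)
  thr <- if (threshold_sum) significance * stats$sigma else -Inf
  meta <- atoms %>%
    mutate(
      atom = row_number(),
      res = paste0(.data$chain, ":", .data$resseq, .data$icode),
      usable = .data$occ > 0 & .data$b > 0,
      partial = FALSE
    )
  if (any(!meta$usable)) {
    inform(sprintf("%d atoms excluded (zero occupancy or non-positive B-factor)",
                   sum(!meta$usable)))
  }
  xyz <- as.matrix(meta[, c("x", "y", "z")])
  pair_list <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    if (!meta$usable[i]) next
    vox <- voxels_within_radius(map, xyz[i, ], max_radius)
    if (isTRUE(attr(vox, "partial"))) meta$partial[i] <- TRUE
    vox <- vox[vox$value > thr, c("id", "dist", "value")]
    if (!nrow(vox)) next
    pair_list[[i]] <- data.table::data.table(atom = i, id = vox$id,
                                             dist = vox$dist, value = vox$value)
  }
  pairs <- data.table::rbindlist(pair_list)
  if (!nrow(pairs)) pairs <- data.table::data.table(atom = integer(), id = integer(),
                                                    dist = numeric(), value = numeric())
  pairs[, `:=`(chain = meta$chain[atom], res = meta$res[atom])]
  chain_electrons <- meta %>%
    filter(.data$usable, !.data$partial) %>%
    group_by(chain = .data$chain) %>%
    summarise(n_atoms = n(), electrons = sum(.data$z_e * .data$occ),
              .groups = "drop")
  structure(list(pairs = pairs, meta = meta, stats = stats, thr = thr,
                 significance = significance, max_radius = max_radius,
                 chain_electrons = chain_electrons,
                 voxel_volume = map$voxel_volume), class = "ed_cache")
}

# Core evaluation at a given radii set. fixed_slopes: named per-type vector
# to use instead of refitting (radius scans keep the incumbent slopes).
eval_cache <- function(cache, radii, slopes = default_slopes(),
                       fixed_slopes = NULL, residue_floor = 4L, chain_floor = 50L) {
  meta <- cache$meta
  pairs <- cache$pairs
  rad_atom <- unname(radii[meta$atom_type])
  if (anyNA(rad_atom)) abort("radii set does not cover all atom types present")
  if (max(radii) > cache$max_radius + 1e-9) {
    abort("radii exceed the cache max_radius; rebuild the cache")
  }
  sel <- pairs[dist <= rad_atom[atom]]
  at <- sel[, list(V = .N, total = sum(value)), by = "atom"]
  atoms <- meta %>%
    mutate(V = 0L, total = 0) %>%
    select("atom", "serial", "name", "resname", "chain", "resseq", "icode",
           "res", "atom_type", "z_e", "occ", "b", "usable", "partial",
           "V", "total")
  atoms$V[at$atom] <- at$V
  atoms$total[at$atom] <- at$total
  atoms <- atoms %>%
    mutate(
      contrib = .data$usable & !.data$partial,
      electrons = .data$z_e * .data$occ,
      r = if_else(.data$V > 0 & .data$electrons > 0,
                  .data$total / .data$electrons, NA_real_)
    )
  contrib <- atoms$contrib
  # chain aggregation: union of member voxel sets, each voxel counted once
  selc <- sel[contrib[atom]]
  uch <- unique(selc[, c("chain", "id", "value")], by = c("chain", "id"))
  ch_tot <- uch[, list(total = sum(value), V = .N), by = "chain"]
  chains <- atoms %>%
    filter(.data$contrib) %>%
    group_by(chain = .data$chain) %>%
    summarise(n_atoms = n(), electrons = sum(.data$electrons), .groups = "drop") %>%
    left_join(as.data.frame(ch_tot), by = "chain") %>%
    mutate(V = dplyr::coalesce(.data$V, 0L),
           total = dplyr::coalesce(.data$total, 0),
           r = if_else(.data$electrons > 0, .data$total / .data$electrons, NA_real_),
           qualifies = .data$n_atoms >= chain_floor)
  conv <- conversion_factor(chains$r[chains$qualifies])
  # residue aggregation
  ures <- unique(sel[contrib[atom], c("res", "id", "value")], by = c("res", "id"))
  re_tot <- ures[, list(total = sum(value), V = .N), by = "res"]
  residues <- atoms %>%
    filter(.data$contrib) %>%
    group_by(res = .data$res) %>%
    summarise(chain = .data$chain[1], resname = .data$resname[1],
              resseq = .data$resseq[1], icode = .data$icode[1],
              n_atoms = n(), electrons = sum(.data$electrons), .groups = "drop") %>%
    left_join(as.data.frame(re_tot), by = "res") %>%
    mutate(V = dplyr::coalesce(.data$V, 0L),
           total = dplyr::coalesce(.data$total, 0),
           r = if_else(.data$electrons > 0, .data$total / .data$electrons, NA_real_),
           qualifies = .data$n_atoms >= residue_floor)
  # volume normalization: per-type median volume over clean atom clouds
  clean <- atoms$contrib & atoms$V > 0
  med_v <- tapply(atoms$V[clean], atoms$atom_type[clean], median)
  atoms$median_vt <- as.numeric(med_v[atoms$atom_type])
  atoms <- atoms %>%
    mutate(
      r_norm = normalize_volume(.data$r, .data$V, .data$median_vt),
      f = if_else(is.na(.data$r_norm), NA_real_,
                  chain_deviation_fraction(.data$r_norm, conv$value))
    )
  fit_idx <- clean
  if (is.null(fixed_slopes)) {
    slope_fit <- fit_bfactor_slopes(atoms$f[fit_idx], atoms$b[fit_idx],
                                    atoms$atom_type[fit_idx], fallback = slopes)
    slope_vec <- setNames(slope_fit$slope, slope_fit$type)
  } else {
    slope_vec <- fixed_slopes
    slope_fit <- tibble(type = names(slope_vec), slope = unname(slope_vec),
                        n = NA_integer_, source = "fixed")
  }
  # B-correction anchor: the structure-wide median log B. Anchoring per
  # type would re-inject each type's B-factor sampling noise into its
  # median corrected deviation fraction; the structure-wide anchor cancels
  # it to first order (see the methods vignette).
  log_b_anchor <- median(log(atoms$b[fit_idx]))
  atoms$log_b_anchor <- log_b_anchor
  atoms <- atoms %>%
    mutate(
      f_corrected = .data$f -
        (log(if_else(.data$b > 0, .data$b, NA_real_)) - .data$log_b_anchor) *
        unname(slope_vec[.data$atom_type]),
      r_corrected = .data$f_corrected * conv$value + conv$value,
      flag = case_when(
        !.data$usable ~ "excluded",
        .data$partial ~ "partial",
        .data$V == 0L ~ "empty",
        TRUE ~ "ok"
      )
    )
  type_stats <- atoms %>%
    filter(.data$contrib, .data$V > 0) %>%
    group_by(type = .data$atom_type) %>%
    summarise(
      n = n(),
      median_v = median(.data$V),
      median_log_b = median(log(.data$b)),
      median_f = median(.data$f, na.rm = TRUE),
      median_f_corrected = median(.data$f_corrected, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    left_join(slope_fit %>% select("type", "slope", slope_source = "source"),
              by = "type")
  structure(list(
    atoms = atoms %>% select(-"contrib"),
    residues = residues, chains = chains, type_stats = type_stats,
    conversion = conv,
    slopes = slope_vec,
    params = list(significance = cache$significance,
                  residue_floor = residue_floor, chain_floor = chain_floor,
                  radii = radii)
  ), class = "ed_analysis")
}

#' Analyze one entry: model plus 2Fo-Fc map
#'
#' Runs the full workflow: whole-map statistics, significant-voxel clouds
#' per atom at the per-type radii, residue and chain aggregation (voxel
#' unions, atom-count floors of 4 and 50), volume normalization, chain
#' deviation fractions, per-type B-factor slope fits, and the B-factor
#' corrected ratios, with the median chain ratio as the structure's
#' conversion factor. Deterministic for fixed inputs.
#'
#' @inheritParams entry_cache
#' @param radii A [radii_set()] (default: the optimized shipped set).
#' @param slopes Fallback [slope_table()] for under-determined types.
#' @param threshold_sum Restrict cloud sums to significant voxels
#'   (default FALSE: sum all voxels within the radius).
#' @param residue_floor,chain_floor Minimum member atoms for residue and
#'   chain clouds (defaults 4 and 50).
#' @param cache Optional precomputed [entry_cache()] (overrides
#'   `structure`/`map`).
#' @param keep_cache If `TRUE`, attach the atom-voxel cache to the result
#'   (used by the radius optimizer).
#' @return An `ed_analysis` object: tibbles `atoms`, `residues`, `chains`,
#'   `type_stats`, plus `conversion` (the median chain density ratio) and
#'   the fitted per-type `slopes`. Use [tidy()], [glance()], [autoplot()]
#'   to explore it.
#' @examples
#' \donttest{
#' fx <- synth_entry(fixture_spec(seed = 7))
#' an <- analyze_entry(fx$structure, fx$map, radii = fx$spec$radii)
#' glance(an)
#' }
#' @export
analyze_entry <- function(structure, map, radii = default_radii(),
                          slopes = default_slopes(), significance = 1.5,
                          threshold_sum = FALSE,
                          residue_floor = 4L, chain_floor = 50L,
                          cache = NULL, keep_cache = FALSE) {
  if (is.null(cache)) {
    cache <- entry_cache(structure, map, significance = significance,
                         threshold_sum = threshold_sum,
                         max_radius = max(1.5, max(radii)))
  }
  out <- eval_cache(cache, radii, slopes = slopes,
                    residue_floor = residue_floor, chain_floor = chain_floor)
  out$map_stats <- cache$stats
  if (keep_cache) out$cache <- cache
  out
}

#' @export
print.ed_analysis <- function(x, ...) {
  cat(sprintf("<ed_analysis> %d atoms, %d residues, %d chains\n",
              nrow(x$atoms), nrow(x$residues), nrow(x$chains)))
  print(x$conversion)
  cat(sprintf("  max |per-type median f_corrected| = %.4f\n",
              max(abs(x$type_stats$median_f_corrected), na.rm = TRUE)))
  invisible(x)
}

#' Tidy an analysis into a tibble
#'
#' @param x An `ed_analysis`.
#' @param level `"atom"`, `"residue"` or `"chain"`.
#' @param ... Unused.
#' @return A tibble with one row per atom/residue/chain.
#' @method tidy ed_analysis
#' @export
tidy.ed_analysis <- function(x, level = c("atom", "residue", "chain"), ...) {
  level <- match.arg(level)
  switch(level, atom = x$atoms, residue = x$residues, chain = x$chains)
}

#' One-row summary of an analysis
#'
#' @param x An `ed_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: conversion factor, chains used, atom counts
#'   and the largest per-type |median f_corrected|.
#' @method glance ed_analysis
#' @export
glance.ed_analysis <- function(x, ...) {
  tibble(
    conversion_factor = x$conversion$value,
    n_chains = x$conversion$n_chains,
    n_atoms = nrow(x$atoms),
    n_atoms_ok = sum(x$atoms$flag == "ok"),
    max_abs_median_f = max(abs(x$type_stats$median_f_corrected), na.rm = TRUE)
  )
}

#' Plot per-type corrected deviation fractions
#'
#' Jittered per-atom chain deviation fractions (after B-factor correction)
#' by atom type, with the per-type medians marked; the analogue of the
#' per-structure distribution plots used to judge radii consistency.
#'
#' @param object An `ed_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ed_analysis
#' @export
autoplot.ed_analysis <- function(object, ...) {
  d <- object$atoms %>% filter(.data$flag == "ok")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$atom_type, y = .data$f_corrected)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = median, geom = "point", colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "corrected chain deviation fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write analysis report files
#'
#' Writes atom, residue and chain tables as CSV plus a JSON summary
#' (conversion factor, per-type statistics, parameters).
#'
#' @param x An `ed_analysis`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default `"entry"`).
#' @return Invisibly, the paths written.
#' @export
write_analysis <- function(x, dir, prefix = "entry") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    atoms = file.path(dir, paste0(prefix, "_atoms.csv")),
    residues = file.path(dir, paste0(prefix, "_residues.csv")),
    chains = file.path(dir, paste0(prefix, "_chains.csv")),
    summary = file.path(dir, paste0(prefix, "_summary.json"))
  )
  write.csv(x$atoms, paths["atoms"], row.names = FALSE)
  write.csv(x$residues, paths["residues"], row.names = FALSE)
  write.csv(x$chains, paths["chains"], row.names = FALSE)
  jsonlite::write_json(list(
    conversion_factor = x$conversion$value,
    n_chains = x$conversion$n_chains,
    type_stats = x$type_stats,
    parameters = x$params[c("significance", "residue_floor", "chain_floor")],
    radii = as.list(x$params$radii)
  ), paths["summary"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
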