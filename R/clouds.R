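#' Density cloud around a single atom
#'
#' Collects the significant voxels (value above `significance` times the
#' whole-map sigma) whose centers lie within `radius` of the atom, and
#' computes the electron density ratio `r = sum(rho) / (Z * occupancy)`:
#' the occupancy adjustment enters as effective electrons so the raw
#' density sum stays auditable.
#'
#' @param map An `ed_map`.
#' @param stats Map statistics from [map_statistics()] (computed if `NULL`).
#' @param atom A one-row tibble or list with `x`, `y`, `z`, `z_e`, `occ`
#'   (as in `ed_structure$atoms`).
#' @param radius Attribution radius in Angstrom (from the atom type's
#'   [radii_set()] entry).
#' @param significance Sigma multiple defining significant voxels
#'   (default 1.5, the 2Fo-Fc convention); consulted when `threshold_sum`
#'   is TRUE.
#' @param threshold_sum Restrict the sum to significant voxels (default
#'   FALSE: all voxels within the radius are summed).
#' @return An object of class `ed_cloud`: list with `voxels` (tibble `id`,
#'   `dist`, `value`), `V` (voxel count), `total_density`, `electrons`
#'   (occupancy-adjusted), `r`, `partial` and `empty` flags.
#' @export
atom_cloud <- function(map, stats = NULL, atom, radius, significance = 1.5,
                       threshold_sum = FALSE) {
  if (is.null(stats)) stats <- map_statistics(map)
  thr <- if (threshold_sum) significance * stats$sigma else -Inf
  vox <- voxels_within_radius(map, c(atom$x, atom$y, atom$z), radius)
  partial <- isTRUE(attr(vox, "partial"))
  vox <- vox %>% filter(.data$value > thr)
  total <- sum(vox$value)
  electrons <- atom$z_e * atom$occ
  structure(list(
    owner = atom, voxels = vox[, c("id", "dist", "value")],
    V = nrow(vox), total_density = total, electrons = electrons,
    r = if (nrow(vox) && electrons > 0) total / electrons else NA_real_,
    partial = partial, empty = nrow(vox) == 0L
  ), class = "ed_cloud")
}

#' Aggregate atom clouds into a residue or chain cloud
#'
#' Takes the union of the member atoms' voxel sets (overlapping voxels are
#' counted once), sums the density over the union, adds the
#' occupancy-adjusted electron counts, and forms the aggregate density
#' ratio. Returns `NULL` when the member count is below the floor (4 atoms
#' for residues, 50 for chains).
#'
#' @param clouds List of `ed_cloud` objects from one residue or one chain.
#' @param level `"residue"` or `"chain"` (sets the default atom-count floor).
#' @param min_atoms Atom-count floor; defaults to 4 or 50 by `level`.
#' @return An `ed_cloud` for the aggregate, or `NULL` if the floor is not
#'   met.
#' @export
aggregate_cloud <- function(clouds, level = c("residue", "chain"), min_atoms = NULL) {
  level <- match.arg(level)
  if (is.null(min_atoms)) min_atoms <- if (level == "residue") 4L else 50L
  if (length(clouds) < min_atoms) return(NULL)
  vox <- bind_rows(lapply(clouds, `[[`, "voxels")) %>%
    arrange(.data$dist) %>% filter(!duplicated(.data$id))
  electrons <- sum(vapply(clouds, `[[`, numeric(1), "electrons"))
  total <- sum(vox$value)
  structure(list(
    owner = level, voxels = vox, V = nrow(vox), total_density = total,
    electrons = electrons,
    r = if (electrons > 0) total / electrons else NA_real_,
    partial = any(vapply(clouds, `[[`, logical(1), "partial")),
    empty = nrow(vox) == 0L
  ), class = "ed_cloud")
}

#' The density-ratio equation chain
#'
#' Small vectorized helpers implementing the correction chain:
#' `normalize_volume()` smooths voxel discretization by the per-type median
#' cloud volume, `r_norm = r * median(V_t) / V`; `chain_deviation_fraction()`
#' expresses a normalized ratio as a fractional deviation from the median
#' chain ratio, `f = (r_norm - median(r_c)) / median(r_c)`;
#' `correct_bfactor()` removes the fitted B-factor trend,
#' `f_corr = f - (log(b) - median(log(b_t))) * s_t` (s_t being the slope of
#' f against log b, subtracting it extrapolates every atom to the median
#' B-factor of its type), and maps back to a ratio,
#' `r_corr = f_corr * median(r_c) + median(r_c)`;
#' `conversion_factor()` is the median chain ratio itself (even counts:
#' mean of the middle pair).
#'
#' @param r,r_norm,f Density ratios / deviation fractions (vectorized).
#' @param v Cloud volume(s) in voxels.
#' @param median_vt Median volume of the atom's type in this structure.
#' @param median_rc Median chain density ratio (the conversion factor).
#' @param log_b Natural log of the atom B-factor.
#' @param median_log_bt Median log B-factor of the atom's type.
#' @param slope Per-type B-factor slope `s_t`.
#' @name equation_chain
NULL

#' @rdname equation_chain
#' @export
normalize_volume <- function(r, v, median_vt) {
  out <- r * median_vt / v
  out[v <= 0] <- NA_real_
  out
}

#' @rdname equation_chain
#' @export
chain_deviation_fraction <- function(r_norm, median_rc) {
  if (!isTRUE(median_rc > 0)) abort("conversion factor must be positive")
  (r_norm - median_rc) / median_rc
}

#' @rdname equation_chain
#' @export
correct_bfactor <- function(f, log_b, median_log_bt, slope, median_rc = NULL) {
  f_corr <- f - (log_b - median_log_bt) * slope
  if (is.null(median_rc)) return(f_corr)
  list(f_corrected = f_corr, r_corrected = f_corr * median_rc + median_rc)
}

#' @rdname equation_chain
#' @param chain_ratios Numeric vector of qualifying chain density ratios.
#' @export
conversion_factor <- function(chain_ratios) {
  chain_ratios <- chain_ratios[is.finite(chain_ratios)]
  if (!length(chain_ratios)) {
    abort("no qualifying chain cloud: conversion factor undefined")
  }
  structure(list(value = median(chain_ratios), n_chains = length(chain_ratios)),
            class = "ed_conversion")
}

#' @export
print.ed_conversion <- function(x, ...) {
  cat(sprintf("<ed_conversion> median chain density ratio %.6g (from %d chains)\n",
              x$value, x$n_chains))
  invisible(x)
}

#' Fit per-type B-factor slopes
#'
#' Ordinary least-squares slope of chain deviation fraction against the
#' natural log of the B-factor, per atom type, over one structure's atoms.
#' Types with fewer than three points, or with no B-factor spread, take the
#' fallback slope.
#'
#' @param f Chain deviation fractions.
#' @param b B-factors (Angstrom^2, positive).
#' @param type Atom types (character, parallel to `f` and `b`).
#' @param fallback A [slope_table()] used for under-determined types.
#' @return A tibble with `type`, `slope`, `n`, `source`
#'   (`"fitted"`/`"default"`).
#' @export
fit_bfactor_slopes <- function(f, b, type, fallback = default_slopes()) {
  df <- tibble(f = f, b = b, type = type) %>%
    filter(is.finite(.data$f), is.finite(.data$b), .data$b > 0)
  purrr::map_dfr(atom_types(), function(tp) {
    d <- df %>% filter(.data$type == tp)
    lb <- log(d$b)
    if (nrow(d) >= 3 && sd(lb) > 0) {
      sl <- sum((lb - mean(lb)) * (d$f - mean(d$f))) / sum((lb - mean(lb))^2)
      tibble(type = tp, slope = sl, n = nrow(d), source = "fitted")
    } else {
      tibble(type = tp, slope = unname(fallback[tp]), n = nrow(d), source = "default")
    }
  })
}
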