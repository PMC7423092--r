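#' Per-atom-type radii
#'
#' A radii set assigns each of the 13 atom types the radius (Angstrom)
#' within which map voxels are attributed to an atom of that type. Two
#' shipped sets are available: `"optimized"` (the default; radii optimized
#' so that per-type median corrected chain deviation fractions vanish
#' across structures) and `"literature"` (covalent radii used as the
#' starting point of that optimization).
#'
#' @param radii Named numeric vector covering the 13 types, or a single
#'   number recycled to all types; values must lie in (0.3, 1.5) Angstrom.
#' @param provenance One of `"literature"`, `"optimized"`, `"user"`,
#'   `"synthetic"`.
#' @return A named numeric vector of class `ed_radii` with a `provenance`
#'   attribute, ordered as [atom_types()].
#' @examples
#' default_radii()
#' radii_set(0.8)
#' @export
radii_set <- function(radii, provenance = "user") {
  tps <- atom_types()
  if (length(radii) == 1 && is.null(names(radii))) {
    radii <- setNames(rep(radii, length(tps)), tps)
  }
  if (!all(tps %in% names(radii))) {
    abort(sprintf("radii set incomplete; missing: %s",
                  paste(setdiff(tps, names(radii)), collapse = ", ")))
  }
  r <- radii[tps]
  if (any(r <= 0.3 | r >= 1.5)) abort("all radii must lie in (0.3, 1.5) Angstrom")
  structure(r, class = "ed_radii", provenance = provenance)
}

#' @rdname radii_set
#' @param which `"optimized"` or `"literature"`.
#' @export
default_radii <- function(which = c("optimized", "literature")) {
  which <- match.arg(which)
  lit <- c(C_single = 0.77, C_single_bb = 0.77, C_double = 0.67,
           C_double_bb = 0.67, C_intermediate = 0.72, O_single = 0.67,
           O_double = 0.60, O_double_bb = 0.60, O_intermediate = 0.64,
           N_single = 0.70, N_single_bb = 0.70, N_intermediate = 0.62,
           S_single = 1.04)
  opt <- c(C_single = 0.84, C_single_bb = 0.72, C_double = 0.67,
           C_double_bb = 0.61, C_intermediate = 0.72, O_single = 0.80,
           O_double = 0.71, O_double_bb = 0.77, O_intermediate = 0.71,
           N_single = 0.95, N_single_bb = 0.70, N_intermediate = 0.77,
           S_single = 0.75)
  if (which == "optimized") radii_set(opt, "optimized") else radii_set(lit, "literature")
}

#' Per-atom-type B-factor slopes
#'
#' The slope `s_t` of chain deviation fraction against log B-factor, used
#' as fallback when a structure has fewer than three atoms of a type. The
#' shipped default table was derived as the median per-structure slope over
#' a seeded synthetic calibration sample (see the methods vignette;
#' re-derivable with [calibrate_synthetic_defaults()]).
#'
#' @param slopes Named numeric vector over the 13 types, or single number
#'   recycled.
#' @return Named numeric vector of class `ed_slopes`.
#' @export
slope_table <- function(slopes) {
  tps <- atom_types()
  if (length(slopes) == 1 && is.null(names(slopes))) {
    slopes <- setNames(rep(slopes, length(tps)), tps)
  }
  if (!all(tps %in% names(slopes))) abort("slope table incomplete")
  s <- slopes[tps]
  if (any(!is.finite(s))) abort("slopes must be finite")
  structure(s, class = "ed_slopes")
}

#' @rdname slope_table
#' @export
default_slopes <- function() {
  slope_table(.synthetic_defaults$slopes)
}

#' @export
print.ed_radii <- function(x, ...) {
  cat(sprintf("<ed_radii> (%s)\n", attr(x, "provenance")))
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @export
print.ed_slopes <- function(x, ...) {
  cat("<ed_slopes>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}
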