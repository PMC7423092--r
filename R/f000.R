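#' Estimate the F000 term and the absolute density offset
#'
#' F000 is the zero-frequency structure factor: the total electron count of
#' the unit cell. It is estimated by summing occupancy-weighted electron
#' counts over all atoms of the asymmetric unit -- typed protein atoms and
#' waters with their hydrogens folded in, other hetero atoms with
#' element-only counts -- and multiplying by the space-group operator
#' count. Dividing by the cell volume gives the density offset (e/Angstrom^3)
#' that would put a zero-meaned map on an absolute scale. Standard maps omit
#' this term, which is why they are zero-meaned; the chain-median conversion
#' factor, not F000, anchors the absolute scale in this package (the F000
#' estimate also misses the bulk-solvent contribution).
#'
#' @param structure An `ed_structure` with a unit cell.
#' @param n_ops Space-group operator count; defaults to the operator table
#'   entry for the structure's space group (1 if unknown).
#' @return A list with `f000` (electrons per unit cell), `offset`
#'   (e/Angstrom^3), `n_ops` and `asu_electrons`.
#' @examples
#' # one carbon, occupancy 1, P 1, V = 1000 A^3 -> offset 0.006 e/A^3
#' @export
f000_estimate <- function(structure, n_ops = NULL) {
  if (is.null(structure$cell)) abort("unit cell required for F000")
  if (is.null(n_ops)) {
    n_ops <- tryCatch(length(space_group_ops(structure$spacegroup)),
                      error = function(e) 1L)
  }
  asu <- sum(structure$atoms$z_e * structure$atoms$occ) +
    sum(structure$waters$z_e * structure$waters$occ) +
    sum(structure$hetero$z_e * structure$hetero$occ)
  f000 <- asu * n_ops
  list(f000 = f000, offset = f000 / structure$cell$volume,
       n_ops = n_ops, asu_electrons = asu)
}

#' Add the F000 offset to a map copy
#'
#' @param map An `ed_map`.
#' @param offset Density offset in the map's units (e.g.
#'   `f000_estimate(structure)$offset` after conversion to map units).
#' @return A new `ed_map` with the offset added to every voxel.
#' @export
add_f000 <- function(map, offset) {
  map$grid <- map$grid + offset
  map
}
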