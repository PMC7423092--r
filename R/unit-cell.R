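#' Crystallographic unit cell
#'
#' Constructs a unit-cell object holding the cell edges, angles, volume and
#' the orthogonalization / fractionalization transforms between fractional
#' and Cartesian coordinates (standard PDB convention: `a` along x, `b` in
#' the xy plane).
#'
#' @param a,b,c Cell edge lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#'
#' @return An object of class `ed_cell`: a list with elements `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma`, `volume` (Angstrom^3), `orth` (3x3 matrix,
#'   fractional -> Cartesian) and `frac` (its inverse).
#' @examples
#' cell <- unit_cell(10, 10, 10)
#' cell$volume
#' frac_to_cart(cell, c(0.5, 0.5, 0.5))
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  a <- unname(a); b <- unname(b); c <- unname(c)
  alpha <- unname(alpha); beta <- unname(beta); gamma <- unname(gamma)
  stopifnot(a > 0, b > 0, c > 0)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180); cg <- cos(gamma * pi / 180)
  sg <- sin(gamma * pi / 180)
  disc <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (disc <= 0) abort("degenerate unit cell: angles are not realizable")
  vol <- a * b * c * sqrt(disc)
  orth <- matrix(c(
    a, b * cg, c * cb,
    0, b * sg, c * (ca - cb * cg) / sg,
    0, 0,      vol / (a * b * sg)
  ), nrow = 3, byrow = TRUE)
  structure(list(
    a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
    volume = vol, orth = orth, frac = solve(orth)
  ), class = "ed_cell")
}

#' @export
print.ed_cell <- function(x, ...) {
  cat(sprintf("<ed_cell> a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f  V=%.1f A^3\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Convert between fractional and Cartesian coordinates
#'
#' @param cell An [unit_cell()] object.
#' @param x A length-3 vector or an n x 3 matrix of coordinates.
#' @return Coordinates in the other frame, same shape as the input.
#' @export
frac_to_cart <- function(cell, x) .cell_apply(cell$orth, x)

#' @rdname frac_to_cart
#' @export
cart_to_frac <- function(cell, x) .cell_apply(cell$frac, x)

.cell_apply <- function(m, x) {
  if (is.matrix(x)) {
    t(m %*% t(x))
  } else {
    drop(m %*% x)
  }
}
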