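#' Crystallographic symmetry operators
#'
#' `parse_symop()` turns an `"x,y,z"`-style triplet string into an operator
#' (3x3 rotation part acting on fractional coordinates plus a translation);
#' `space_group_ops()` looks a Hermann-Mauguin symbol up in the shipped
#' operator table covering the Sohncke space groups (standard settings);
#' `map_symmetry_ops()` extracts operators for a map, preferring the CCP4
#' header's embedded symmetry records over the symbol table.
#'
#' @param triplet A triplet string such as `"-x,y+1/2,-z"` (case
#'   insensitive); vectorized over a character vector in
#'   `parse_symops()`.
#' @return A single operator is a list with `R` (3x3 matrix) and `t`
#'   (length-3 translation, fractional); operator sets are lists of these
#'   with the identity first.
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub(" ", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) abort(sprintf("invalid symmetry triplet: %s", triplet))
  R <- matrix(0, 3, 3); tv <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    m <- gregexpr("[+-]?[^+-]+", expr)[[1]]
    terms <- regmatches(expr, list(m))[[1]]
    for (term in terms) {
      sgn <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        R[i, match(body, c("x", "y", "z"))] <- sgn
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        fr <- as.numeric(strsplit(body, "/")[[1]])
        tv[i] <- tv[i] + sgn * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", body)) {
        tv[i] <- tv[i] + sgn * as.numeric(body)
      } else {
        abort(sprintf("cannot parse symmetry term '%s' in %s", term, triplet))
      }
    }
  }
  list(R = R, t = tv)
}

#' @rdname parse_symop
#' @param triplets Character vector of triplet strings.
#' @export
parse_symops <- function(triplets) {
  ops <- lapply(triplets, parse_symop)
  # identity first (added if absent), preserve order otherwise
  is_id <- vapply(ops, function(o) all(o$R == diag(3)) && all(o$t %% 1 == 0), logical(1))
  c(list(list(R = diag(3), t = numeric(3))), ops[!is_id])
}

sohncke_table <- function() {
  cached <- .edmapr_cache$sohncke
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "spacegroups.txt", package = "edmapr")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, " | ", fixed = TRUE)
  tab <- tibble(
    symbol = vapply(fields, `[[`, character(1), 1),
    number = as.integer(vapply(fields, `[[`, character(1), 2)),
    triplets = lapply(fields, function(f) trimws(strsplit(f[[3]], ";")[[1]]))
  )
  .edmapr_cache$sohncke <- tab
  tab
}

#' @rdname parse_symop
#' @param symbol Hermann-Mauguin space-group symbol (e.g. `"P 21 21 21"`)
#'   or an International Tables number.
#' @export
space_group_ops <- function(symbol) {
  tab <- sohncke_table()
  if (is.numeric(symbol)) {
    i <- match(symbol, tab$number)
  } else {
    key <- toupper(gsub(" ", "", symbol))
    i <- match(key, toupper(gsub(" ", "", tab$symbol)))
  }
  if (is.na(i)) abort(sprintf("unknown space group: %s", symbol))
  parse_symops(tab$triplets[[i]])
}

#' @rdname parse_symop
#' @param map An `ed_map`; its header symmetry records take precedence.
#' @param fallback_symbol Hermann-Mauguin symbol used when the map carries
#'   no symmetry records (e.g. from CRYST1); if also absent, the map's
#'   ISPG number is tried, then `"P 1"`.
#' @export
map_symmetry_ops <- function(map, fallback_symbol = NULL) {
  if (length(map$symmetry)) return(parse_symops(map$symmetry))
  if (!is.null(fallback_symbol) && !is.na(fallback_symbol)) {
    return(space_group_ops(fallback_symbol))
  }
  if (isTRUE(map$spacegroup >= 1)) return(space_group_ops(map$spacegroup))
  space_group_ops("P 1")
}

apply_symop <- function(op, frac) {
  sweep(frac %*% t(op$R), 2, op$t, `+`)
}

#' Symmetry environment of a model
#'
#' Generates symmetry mates and unit-cell translations (operators x the 27
#' neighbor-cell shifts) of all typed atoms and keeps the images that fall
#' within `buffer` Angstrom of the map's Cartesian bounding box, excluding
#' images that coincide with original atoms (within 1e-3 Angstrom). Images
#' carry their source atom's type, electron count, occupancy and B-factor.
#'
#' @param structure An `ed_structure` with a valid unit cell.
#' @param ops Operator list from [space_group_ops()] / [map_symmetry_ops()].
#' @param map An `ed_map` defining the region of interest.
#' @param buffer Distance in Angstrom beyond the map bounding box within
#'   which images are retained (default 5).
#' @return A tibble of image atoms (same columns as `structure$atoms` plus
#'   `op` and `shift`); zero rows when no image comes near the map.
#' @export
expand_environment <- function(structure, ops, map, buffer = 5) {
  if (is.null(structure$cell)) abort("structure has no unit cell (CRYST1 missing)")
  atoms <- structure$atoms
  if (!nrow(atoms)) return(atoms)
  cell <- structure$cell
  frac <- cart_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
  box <- map_bounding_box(map)
  lo <- box$lo - buffer; hi <- box$hi + buffer
  shifts <- as.matrix(expand.grid(sx = -1:1, sy = -1:1, sz = -1:1))
  orig_key <- round(as.matrix(atoms[, c("x", "y", "z")]) / 1e-3)
  okey <- paste(orig_key[, 1], orig_key[, 2], orig_key[, 3])
  out <- list()
  for (io in seq_along(ops)) {
    base <- apply_symop(ops[[io]], frac)
    for (is in seq_len(nrow(shifts))) {
      fr <- sweep(base, 2, shifts[is, ], `+`)
      xyz <- frac_to_cart(cell, fr)
      keep <- xyz[, 1] >= lo[1] & xyz[, 1] <= hi[1] &
        xyz[, 2] >= lo[2] & xyz[, 2] <= hi[2] &
        xyz[, 3] >= lo[3] & xyz[, 3] <= hi[3]
      if (!any(keep)) next
      img <- atoms[keep, ]
      img$x <- xyz[keep, 1]; img$y <- xyz[keep, 2]; img$z <- xyz[keep, 3]
      img$op <- io
      img$shift <- paste(shifts[is, ], collapse = ",")
      ikey <- paste(round(img$x / 1e-3), round(img$y / 1e-3), round(img$z / 1e-3))
      img <- img[!(ikey %in% okey), ]
      out[[length(out) + 1L]] <- img
    }
  }
  if (!length(out)) return(atoms[0, ])
  res <- bind_rows(out)
  # drop duplicate images (special positions)
  rkey <- paste(round(res$x / 1e-3), round(res$y / 1e-3), round(res$z / 1e-3))
  res[!duplicated(rkey), ]
}

map_bounding_box <- function(map) {
  d <- dim(map$grid)
  fr_lo <- map$start / map$ngrid
  fr_hi <- (map$start + d) / map$ngrid
  corners <- as.matrix(expand.grid(x = c(fr_lo[1], fr_hi[1]),
                                   y = c(fr_lo[2], fr_hi[2]),
                                   z = c(fr_lo[3], fr_hi[3])))
  xyz <- frac_to_cart(map$cell, corners)
  list(lo = apply(xyz, 2, min), hi = apply(xyz, 2, max))
}
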