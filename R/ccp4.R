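#' Electron density maps in the CCP4 format
#'
#' `read_ccp4()` reads a binary CCP4 map (mode 2, 32-bit float) and returns a
#' density map whose grid is re-ordered so that storage axes map onto the
#' crystallographic x/y/z axes regardless of the header's axis permutation.
#' `write_ccp4()` writes a map back out, optionally with a non-identity axis
#' order; round trips are bit exact for mode-2 data.
#'
#' Voxel semantics: grid point `(i, j, k)` (0-based, absolute grid indices
#' along the crystal axes, honoring the header start indices) is treated as a
#' voxel covering one grid cell, with its center at fractional coordinates
#' `((i + 0.5)/NX, (j + 0.5)/NY, (k + 0.5)/NZ)`. The voxel center is the
#' reference point for all atom-to-voxel distances.
#'
#' @param path Path to a CCP4 map file.
#' @return `read_ccp4()` returns an object of class `ed_map`: a list with
#'   `grid` (3D array in crystal x/y/z order), `start` (length-3 integer,
#'   0-based grid start per axis), `ngrid` (sampling intervals per full cell
#'   edge), `cell` ([unit_cell()]), `spacegroup` (ISPG number), `symmetry`
#'   (character vector of "x,y,z"-style operator records, possibly empty) and
#'   `voxel_volume` (Angstrom^3).
#' @seealso [map_statistics()], [voxels_within_radius()]
#' @export
read_ccp4 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 1024) abort("not a CCP4 map: file shorter than the 1024-byte header")
  magic <- raw[209:212]
  if (!(all(magic[1:3] == charToRaw("MAP")) && magic[4] %in% as.raw(c(0x20, 0x00)))) {
    abort("not a CCP4 map: magic word at word 53 is not 'MAP '")
  }
  endian <- if (as.integer(raw[213]) == 0x11) "big" else "little"
  ints <- function(w, n = 1L) readBin(raw[(4L * (w - 1L) + 1L):(4L * (w + n - 1L))],
                                      "integer", n = n, size = 4L, endian = endian)
  flts <- function(w, n = 1L) readBin(raw[(4L * (w - 1L) + 1L):(4L * (w + n - 1L))],
                                      "double", n = n, size = 4L, endian = endian)
  nc <- ints(1L, 3L)                      # columns, rows, sections
  mode <- ints(4L)
  if (mode != 2L) abort(sprintf("unsupported CCP4 mode %d (only mode 2, 32-bit float)", mode))
  start_crs <- ints(5L, 3L)
  ngrid <- ints(8L, 3L)
  cellp <- flts(11L, 6L)
  axmap <- ints(17L, 3L)                  # crystal axis (1=x,2=y,3=z) per col/row/sec
  if (!setequal(axmap, 1:3)) abort("invalid axis mapping in CCP4 header words 17-19")
  ispg <- ints(23L)
  nsymbt <- ints(24L)
  nvox <- prod(nc)
  need <- 1024L + nsymbt + 4L * nvox
  if (length(raw) < need) {
    abort(sprintf("truncated CCP4 data section: need %d bytes, have %d", need, length(raw)))
  }
  sym <- character(0)
  if (nsymbt > 0) {
    symraw <- raw[1025:(1024 + nsymbt)]
    nrec <- nsymbt %/% 80L
    sym <- vapply(seq_len(nrec), function(i) {
      trimws(rawToChar(symraw[(80L * (i - 1L) + 1L):(80L * i)]))
    }, character(1))
    sym <- sym[nzchar(sym)]
  }
  vals <- readBin(raw[(1025L + nsymbt):need], "double", n = nvox, size = 4L, endian = endian)
  if (!all(is.finite(vals))) abort("CCP4 data section contains non-finite values")
  a <- array(vals, dim = nc)              # column index fastest, per format
  perm <- integer(3); perm[axmap] <- 1:3
  grid <- aperm(a, perm)
  start <- integer(3); start[axmap] <- start_crs
  cell <- unit_cell(cellp[1], cellp[2], cellp[3], cellp[4], cellp[5], cellp[6])
  new_ed_map(grid, start, ngrid, cell, spacegroup = ispg, symmetry = sym)
}

new_ed_map <- function(grid, start, ngrid, cell, spacegroup = 1L, symmetry = character(0)) {
  stopifnot(length(dim(grid)) == 3, length(start) == 3, length(ngrid) == 3)
  structure(list(
    grid = grid,
    start = as.integer(start),
    ngrid = as.integer(ngrid),
    cell = cell,
    spacegroup = as.integer(spacegroup),
    symmetry = symmetry,
    voxel_volume = cell$volume / prod(ngrid)
  ), class = "ed_map")
}

#' @export
print.ed_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<ed_map> extent %d x %d x %d of %d x %d x %d grid, start (%d,%d,%d)\n",
              d[1], d[2], d[3], x$ngrid[1], x$ngrid[2], x$ngrid[3],
              x$start[1], x$start[2], x$start[3]))
  print(x$cell)
  s <- map_statistics(x)
  cat(sprintf("  values: mean %.4g, sigma %.4g, range [%.4g, %.4g]\n",
              s$mean, s$sigma, s$min, s$max))
  invisible(x)
}

#' @rdname read_ccp4
#' @param map An `ed_map` object.
#' @param axis_order Length-3 integer: crystal axis stored as columns, rows,
#'   sections (default `c(1, 2, 3)`).
#' @export
write_ccp4 <- function(map, path, axis_order = c(1L, 2L, 3L)) {
  stopifnot(inherits(map, "ed_map"), setequal(axis_order, 1:3))
  perm <- integer(3); perm[axis_order] <- 1:3
  a <- aperm(map$grid, order(perm))       # storage array: inverse of the read permutation
  nc <- dim(a)
  start_crs <- map$start[axis_order]
  sym <- map$symmetry
  symraw <- raw(0)
  if (length(sym)) {
    symraw <- unlist(lapply(sym, function(s) {
      charToRaw(formatC(substr(s, 1, 80), width = -80))
    }))
  }
  stats <- map_statistics(map)
  hdr <- raw(1024)
  put_i <- function(w, v) {
    b <- writeBin(as.integer(v), raw(), size = 4L, endian = "little")
    hdr[(4L * (w - 1L) + 1L):(4L * (w - 1L) + length(b))] <<- b
  }
  put_f <- function(w, v) {
    b <- writeBin(as.double(v), raw(), size = 4L, endian = "little")
    hdr[(4L * (w - 1L) + 1L):(4L * (w - 1L) + length(b))] <<- b
  }
  put_i(1L, nc)
  put_i(4L, 2L)
  put_i(5L, start_crs)
  put_i(8L, map$ngrid)
  put_f(11L, with(map$cell, c(a, b, c, alpha, beta, gamma)))
  put_i(17L, axis_order)
  put_f(20L, c(stats$min, stats$max, stats$mean))
  put_i(23L, map$spacegroup)
  put_i(24L, length(symraw))
  hdr[209:212] <- charToRaw("MAP ")
  hdr[213:216] <- as.raw(c(0x44, 0x41, 0x00, 0x00))   # little-endian machine stamp
  put_f(55L, stats$sigma)
  put_i(56L, 1L)
  lab <- formatC("edmapr density map", width = -80)
  hdr[225:304] <- charToRaw(lab)                       # label 1 at word 57
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  if (length(symraw)) writeBin(symraw, con)
  writeBin(as.double(a), con, size = 4L, endian = "little")
  invisible(path)
}

#' Whole-map statistics
#'
#' Mean, population standard deviation, minimum and maximum over all voxels
#' of the map. The standard deviation is computed from the data block (the
#' header's stored RMS field is ignored); this is the sigma used by the
#' significance thresholds (1.5 sigma for 2Fo-Fc maps, 3 sigma for Fo-Fc
#' maps).
#'
#' @param map An `ed_map` object.
#' @return An object of class `ed_mapstats`: list with `mean`, `sigma`,
#'   `min`, `max`, `n_voxels`.
#' @export
map_statistics <- function(map) {
  g <- map$grid
  m <- mean(g)
  structure(list(
    mean = m,
    sigma = sqrt(mean((g - m)^2)),
    min = min(g),
    max = max(g),
    n_voxels = length(g)
  ), class = "ed_mapstats")
}

#' @export
print.ed_mapstats <- function(x, ...) {
  cat(sprintf("<ed_mapstats> mean %.6g  sigma %.6g  min %.6g  max %.6g  (n=%d)\n",
              x$mean, x$sigma, x$min, x$max, x$n_voxels))
  invisible(x)
}

# TRUE per axis when the stored extent covers at least one full cell edge,
# so out-of-extent indices may be wrapped by unit-cell translation.
map_wraps <- function(map) dim(map$grid) >= map$ngrid

#' Map voxels to Cartesian points and back
#'
#' `xyz_to_crs()` returns the (0-based, absolute) grid index of the voxel
#' whose cell contains a Cartesian point; `crs_to_xyz()` returns the
#' Cartesian coordinates of a voxel center. Indices outside the stored
#' extent are wrapped by unit-cell translation along axes where the map
#' covers a full cell, and are `NA` otherwise.
#'
#' @param map An `ed_map`.
#' @param xyz Length-3 Cartesian point or n x 3 matrix (Angstrom).
#' @param crs Length-3 voxel index triple or n x 3 matrix (0-based grid
#'   indices along the crystal axes).
#' @return `xyz_to_crs()`: integer matrix (n x 3) of grid indices;
#'   `crs_to_xyz()`: numeric matrix (n x 3) of voxel centers.
#' @export
xyz_to_crs <- function(map, xyz) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3)
  fr <- cart_to_frac(map$cell, xyz)
  g <- floor(sweep(fr, 2, map$ngrid, `*`))
  wrap_crs(map, g)
}

#' @rdname xyz_to_crs
#' @export
crs_to_xyz <- function(map, crs) {
  if (!is.matrix(crs)) crs <- matrix(crs, ncol = 3)
  fr <- sweep(crs + 0.5, 2, map$ngrid, `/`)
  frac_to_cart(map$cell, fr)
}

# Wrap absolute grid indices into the stored extent; NA when outside a
# non-wrapping axis. Input/output are 0-based absolute indices.
wrap_crs <- function(map, g) {
  d <- dim(map$grid)
  wraps <- map_wraps(map)
  out <- g
  for (ax in 1:3) {
    rel <- g[, ax] - map$start[ax]
    if (wraps[ax]) {
      rel <- rel %% map$ngrid[ax]
      bad <- rel >= d[ax]                  # beyond-extent remainder on over-full maps
    } else {
      bad <- rel < 0 | rel >= d[ax]
    }
    rel[bad] <- NA_integer_
    out[, ax] <- rel + map$start[ax]
  }
  storage.mode(out) <- "integer"
  out
}

# 1-based linear index into map$grid for 0-based absolute grid triples
crs_to_id <- function(map, crs) {
  d <- dim(map$grid)
  rel <- sweep(crs, 2, map$start, `-`)
  1L + rel[, 1] + d[1] * (rel[, 2] + d[2] * rel[, 3])
}

id_to_crs <- function(map, id) {
  d <- dim(map$grid)
  r <- id - 1L
  i <- r %% d[1]; r <- r %/% d[1]
  j <- r %% d[2]; k <- r %/% d[2]
  cbind(i + map$start[1], j + map$start[2], k + map$start[3])
}

#' Voxels whose centers lie within a radius of a point
#'
#' Returns exactly the stored voxels whose centers are at Euclidean distance
#' `<= radius` from `center`, including voxels reached by wrapping across
#' periodic map boundaries along axes where the map covers a full unit cell.
#' Along non-wrapping axes, candidates outside the stored extent are skipped
#' and the result is flagged partial.
#'
#' @param map An `ed_map`.
#' @param center Length-3 Cartesian point (Angstrom).
#' @param radius Search radius in Angstrom (> 0).
#' @return A tibble with one row per voxel: `id` (linear index into the
#'   grid), `ix`, `iy`, `iz` (0-based absolute grid indices), `dist`
#'   (Angstrom) and `value`. Attribute `partial` is `TRUE` when part of the
#'   search sphere fell outside the stored extent.
#' @export
voxels_within_radius <- function(map, center, radius) {
  stopifnot(radius > 0)
  if (radius > min(map$cell$a, map$cell$b, map$cell$c) / 2) {
    warn("radius exceeds half the shortest cell edge; periodic wrap is ambiguous")
  }
  fr <- cart_to_frac(map$cell, center)
  # per-axis fractional half-widths of a box containing the sphere
  halfw <- radius * sqrt(rowSums(map$cell$frac^2))
  lo <- floor((fr - halfw) * map$ngrid)
  hi <- floor((fr + halfw) * map$ngrid)
  cand <- as.matrix(expand.grid(ix = lo[1]:hi[1], iy = lo[2]:hi[2], iz = lo[3]:hi[3],
                                KEEP.OUT.ATTRS = FALSE))
  centers <- crs_to_xyz(map, cand)         # centers of the unwrapped images
  dif <- sweep(centers, 2, center, `-`)
  dist <- sqrt(rowSums(dif^2))
  keep <- dist <= radius
  cand <- cand[keep, , drop = FALSE]
  dist <- dist[keep]
  wrapped <- wrap_crs(map, cand)
  ok <- stats::complete.cases(wrapped)
  partial <- any(!ok)
  wrapped <- wrapped[ok, , drop = FALSE]
  dist <- dist[ok]
  id <- unname(crs_to_id(map, wrapped))
  out <- tibble(id = id, ix = unname(wrapped[, 1]), iy = unname(wrapped[, 2]),
                iz = unname(wrapped[, 3]), dist = unname(dist),
                value = map$grid[id])
  # set semantics: a stored voxel reachable via two periodic images counts once
  if (anyDuplicated(id)) {
    out <- out %>% arrange(.data$dist) %>% filter(!duplicated(.data$id))
  }
  attr(out, "partial") <- partial
  out
}

# Snap doubles to their 32-bit float representation (the precision at which
# mode-2 maps are stored), so in-memory grids match their on-disk round trip.
float32 <- function(x) {
  dm <- dim(x)
  y <- readBin(writeBin(as.double(x), raw(), size = 4L), "double",
               n = length(x), size = 4L)
  dim(y) <- dm
  y
}
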