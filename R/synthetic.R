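#' Specification for a synthetic entry
#'
#' Describes a toy protein model plus the forward model used to render its
#' maps: extended-chain geometry, Gaussian atoms whose width is set by the
#' atomic B-factor (plus a grid-softening constant), an arbitrary global
#' scale, and zero-meaning -- emulating the sigma-scaled, zero-meaned maps
#' distributed for PDB entries. All outputs are deterministic under `seed`.
#'
#' @param sequences Named character vector of one-letter sequences, one per
#'   chain (names become chain identifiers). The default is two 46-residue
#'   chains containing all twenty amino acids, with the residues that carry
#'   rare atom types (Asn/Gln, Lys, Ser/Thr, Asp/Glu, Cys/Met) repeated so
#'   every one of the 13 types is populated by at least ten atoms per
#'   entry and per-structure B-factor slopes are fittable for all types.
#' @param repeats Number of times each chain's sequence cassette is
#'   repeated (default 1). Longer chains average the per-type statistics
#'   over more atoms; the shipped calibration uses `repeats = 3`.
#' @param spacing Grid spacing in Angstrom (must be <= 0.5 so atom clouds
#'   span tens of voxels).
#' @param spacegroup `"P 1"` (default) or `"P 21 21 21"`.
#' @param radii The "true" [radii_set()] recorded for oracle use; defaults
#'   to the calibrated synthetic set (see [synthetic_true_radii()]).
#' @param b_log_mean,b_log_sd Parameters of the log-normal per-atom
#'   B-factor distribution (default: median 20 Angstrom^2, sd of log 0.25).
#' @param coord_jitter Standard deviation (Angstrom) of the seeded Gaussian
#'   displacement added to every coordinate (default 0.12), so entries with
#'   different seeds differ in geometry and grid alignment, not only in
#'   B-factors -- mimicking the positional diversity of real structures.
#' @param b_grid Grid-softening constant (Angstrom^2) added to each atomic
#'   B so even low-B atoms span several voxels (default 10).
#' @param occupancy Default occupancy for all atoms.
#' @param scale Global map scale factor `k` (arbitrary units per e/A^3).
#' @param zero_mean Subtract the grid mean after scaling (default TRUE).
#' @param noise_sd Per-voxel Gaussian noise sigma for difference maps, in
#'   e/Angstrom^3 before scaling (default 0.02).
#' @param seed Integer seed driving B-factors and difference-map noise.
#' @return A list of class `ed_fixture_spec`.
#' @export
fixture_spec <- function(sequences = c(A = "DKNDNKKTEEDSMTLNVFNHSRQCGSPCMEIKTESTQNWYAQKQDC",
                                       B = "EIKPTQDHNLTASKWSDCQDFTMKKRQMCQNSSGNVEENYTDKCNE"),
                         repeats = 1L,
                         spacing = 0.4, spacegroup = "P 1",
                         radii = synthetic_true_radii(),
                         b_log_mean = log(20), b_log_sd = 0.25,
                         coord_jitter = 0.12,
                         b_grid = 10, occupancy = 1, scale = 1,
                         zero_mean = TRUE, noise_sd = 0.02, seed = 1L) {
  if (spacing > 0.5) abort("grid spacing must be <= 0.5 Angstrom")
  if (is.null(names(sequences))) {
    names(sequences) <- LETTERS[seq_along(sequences)]
  }
  if (repeats > 1) {
    sequences <- vapply(sequences, function(s) paste(rep(s, repeats), collapse = ""),
                        character(1))
  }
  structure(list(sequences = sequences, spacing = spacing,
                 spacegroup = spacegroup, radii = radii_set(radii, "synthetic"),
                 b_log_mean = b_log_mean, b_log_sd = b_log_sd,
                 coord_jitter = coord_jitter,
                 b_grid = b_grid, occupancy = occupancy, scale = scale,
                 zero_mean = zero_mean, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "ed_fixture_spec")
}

aa1to3 <- function(x) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- unname(map[strsplit(x, "")[[1]]])
  if (anyNA(out)) abort("sequence contains a non-standard residue code")
  out
}

# Side-chain atom offsets from CA (local frame: x along the chain, z away
# from the backbone). Idealized bond lengths; rings are planar polygons in
# the xz plane. Geometry realism beyond interatomic distances is irrelevant
# to the density math.
.sc_offsets <- function() {
  cb <- c(0, 0.55, 1.42)
  step <- function(k) {
    # k-th atom along a zigzag side chain, starting after CB
    dz <- 1.35 * k
    dy <- 0.7 * (k %% 2)
    cb + c(0, dy, dz)
  }
  penta <- function(from, names) {
    ctr <- from + c(0, 0, 1.18)
    ang <- (270 + 72 * seq(0, 4)) * pi / 180
    out <- lapply(ang, function(a) ctr + 1.18 * c(cos(a), 0, sin(a)))
    setNames(out[-1], names)   # first vertex is `from` itself
  }
  hexa <- function(from, names) {
    ctr <- from + c(0, 0, 1.39)
    ang <- (270 + 60 * seq(0, 5)) * pi / 180
    out <- lapply(ang, function(a) ctr + 1.39 * c(cos(a), 0, sin(a)))
    setNames(out[-1], names)
  }
  g1 <- step(1); g2 <- step(2); g3 <- step(3); g4 <- step(4)
  out <- list(
    ALA = list(CB = cb),
    ARG = list(CB = cb, CG = g1, CD = g2, NE = g3, CZ = g4,
               NH1 = g4 + c(1.15, 0.35, 0.45), NH2 = g4 + c(-1.15, 0.35, 0.45)),
    ASN = list(CB = cb, CG = g1, OD1 = g1 + c(1.05, -0.4, 0.55),
               ND2 = g1 + c(-1.05, -0.4, 0.55)),
    ASP = list(CB = cb, CG = g1, OD1 = g1 + c(1.05, -0.4, 0.55),
               OD2 = g1 + c(-1.05, -0.4, 0.55)),
    CYS = list(CB = cb, SG = cb + c(0, 0.8, 1.62)),
    GLN = list(CB = cb, CG = g1, CD = g2, OE1 = g2 + c(1.05, 0.3, 0.55),
               NE2 = g2 + c(-1.05, 0.3, 0.55)),
    GLU = list(CB = cb, CG = g1, CD = g2, OE1 = g2 + c(1.05, 0.3, 0.55),
               OE2 = g2 + c(-1.05, 0.3, 0.55)),
    GLY = list(),
    HIS = local({
      ring <- penta(g1, c("ND1", "CE1", "NE2", "CD2"))
      c(list(CB = cb, CG = g1), ring)
    }),
    ILE = list(CB = cb, CG1 = g1, CG2 = cb + c(1.25, 0.5, 0.7), CD1 = g2),
    LEU = list(CB = cb, CG = g1, CD1 = g1 + c(1.25, -0.5, 0.7),
               CD2 = g1 + c(-1.25, -0.5, 0.7)),
    LYS = list(CB = cb, CG = g1, CD = g2, CE = g3, NZ = g4),
    MET = list(CB = cb, CG = g1, SD = g1 + c(0, -0.8, 1.62),
               CE = g1 + c(0, 0, 3.1)),
    PHE = c(list(CB = cb, CG = g1), hexa(g1, c("CD1", "CE1", "CZ", "CE2", "CD2"))),
    PRO = list(CB = cb, CG = g1, CD = g1 + c(-1.1, -0.85, 0.2)),
    SER = list(CB = cb, OG = cb + c(0, 0.7, 1.25)),
    THR = list(CB = cb, OG1 = cb + c(1.1, 0.5, 0.75), CG2 = cb + c(-1.25, 0.5, 0.7)),
    TRP = local({
      ring5 <- penta(g1, c("CD1", "NE1", "CE2", "CD2"))
      ce2 <- ring5$CE2; cd2 <- ring5$CD2
      m <- (ce2 + cd2) / 2
      ctr5 <- g1 + c(0, 0, 1.18)
      dirv <- m - ctr5; dirv <- dirv / sqrt(sum(dirv^2))
      edge <- sqrt(sum((ce2 - cd2)^2))
      ctr6 <- m + dirv * edge * sqrt(3) / 2
      phi1 <- atan2(ce2[3] - ctr6[3], ce2[1] - ctr6[1])
      phi2 <- atan2(cd2[3] - ctr6[3], cd2[1] - ctr6[1])
      dlt <- phi2 - phi1
      dlt <- atan2(sin(dlt), cos(dlt))          # wrapped to +/- 60 degrees
      vert <- function(k) ctr6 + edge * c(cos(phi1 - k * dlt), 0, sin(phi1 - k * dlt))
      c(list(CB = cb, CG = g1), ring5,
        list(CZ2 = vert(1), CH2 = vert(2), CZ3 = vert(3), CE3 = vert(4)))
    }),
    TYR = local({
      ring <- hexa(g1, c("CD1", "CE1", "CZ", "CE2", "CD2"))
      c(list(CB = cb, CG = g1), ring, list(OH = ring$CZ + c(0, 0, 1.36)))
    }),
    VAL = list(CB = cb, CG1 = cb + c(1.25, 0.5, 0.7), CG2 = cb + c(-1.25, 0.5, 0.7))
  )
  out
}

#' Build a toy extended-chain structure
#'
#' Places each chain as an extended strand (3.8 Angstrom residue pitch,
#' alternating backbone pucker) with idealized side-chain geometry, assigns
#' log-normal B-factors, and wraps everything in a unit cell with a margin.
#' The PDB text round-trips through [read_pdb_structure()].
#'
#' @param spec A [fixture_spec()].
#' @return A list with `structure` (`ed_structure`), `pdb` (character
#'   lines) and `spec`.
#' @export
synth_structure <- function(spec) {
  sc <- .sc_offsets()
  margin <- 4.5
  chain_gap <- 9
  rows <- list()
  serial <- 0L
  for (ci in seq_along(spec$sequences)) {
    chain_id <- names(spec$sequences)[ci]
    seq3 <- aa1to3(spec$sequences[[ci]])
    y0 <- (ci - 1) * chain_gap
    for (ri in seq_along(seq3)) {
      rn <- seq3[ri]
      mirror <- if (ri %% 2 == 0) -1 else 1
      nx <- 3.8 * (ri - 1)
      ca <- c(nx + 1.2, y0 + mirror * 0.9, 0)
      bb <- list(N = c(nx, y0, 0),
                 CA = ca,
                 C = c(nx + 2.45, y0 + mirror * 0.1, 0),
                 O = c(nx + 2.75, y0 + mirror * (0.1 - 1.19), 0))
      side <- lapply(sc[[rn]], function(off) {
        ca + c(off[1], mirror * off[2], off[3])
      })
      for (nm in c(names(bb), names(side))) {
        p <- if (nm %in% names(bb)) bb[[nm]] else side[[nm]]
        serial <- serial + 1L
        rows[[length(rows) + 1L]] <- tibble(
          serial = serial, name = nm, altloc = " ", resname = rn,
          chain = chain_id, resseq = ri, icode = " ",
          x = p[1], y = p[2], z = p[3],
          occ = spec$occupancy, b = NA_real_,
          element = substr(nm, 1, 1)
        )
      }
    }
  }
  atoms <- bind_rows(rows)
  set.seed(spec$seed)
  atoms$b <- rlnorm(nrow(atoms), spec$b_log_mean, spec$b_log_sd)
  if (spec$coord_jitter > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + rnorm(n, 0, spec$coord_jitter)
    atoms$y <- atoms$y + rnorm(n, 0, spec$coord_jitter)
    atoms$z <- atoms$z + rnorm(n, 0, spec$coord_jitter)
  }
  # shift into the cell with a margin; cell sized to the model extent
  mins <- vapply(atoms[, c("x", "y", "z")], min, numeric(1))
  maxs <- vapply(atoms[, c("x", "y", "z")], max, numeric(1))
  ext <- maxs - mins + 2 * margin
  if (spec$spacegroup != "P 1") ext <- ext * 2   # room for symmetry mates
  for (i in 1:3) {
    v <- c("x", "y", "z")[i]
    atoms[[v]] <- atoms[[v]] - mins[i] + margin
  }
  cell <- unit_cell(ext[1], ext[2], ext[3])
  atoms <- atoms %>%
    mutate(atom_type = classify_atom(.data$resname, .data$name),
           z_e = electron_count(.data$resname, .data$name, .data$element))
  st <- structure(list(atoms = atoms, waters = atoms[0, ], hetero = atoms[0, ],
                       cell = cell, spacegroup = spec$spacegroup),
                  class = "ed_structure")
  list(structure = st, pdb = write_pdb_structure(st), spec = spec)
}

# Gaussian forward model: an atom with B' = b + b_grid contributes
# occ * Z * (4*pi/B')^{3/2} * exp(-4*pi^2 r^2 / B') e/A^3, which integrates
# to occ * Z electrons over all space.
gaussian_peak <- function(z, occ, bprime) occ * z * (4 * pi / bprime)^1.5

#' Analytic capture fraction of a Gaussian atom
#'
#' Fraction of a B-widened Gaussian atom's electrons lying within `radius`
#' of its center: the chi-squared(3) mass inside `8 pi^2 r^2 / B'`. Used as
#' the ground-truth oracle for cloud sums on synthetic maps.
#'
#' @param radius Radius in Angstrom.
#' @param bprime Effective B (atom B + grid softening), Angstrom^2.
#' @export
gaussian_capture_fraction <- function(radius, bprime) {
  pchisq(8 * pi^2 * radius^2 / bprime, df = 3)
}

#' Render the 2Fo-Fc-like synthetic map
#'
#' Sums the Gaussian contributions of all atoms (and their space-group
#' images) at voxel centers over one full unit cell, multiplies by the
#' global scale and, by default, subtracts the grid mean -- yielding a
#' zero-meaned, arbitrarily scaled map like those distributed for real
#' entries. Values are snapped to 32-bit float so in-memory grids equal
#' their CCP4 round trip.
#'
#' @param model Output of [synth_structure()] (or an `ed_structure` plus
#'   `spec`).
#' @param spec The [fixture_spec()]; defaults to `model$spec`.
#' @return An `ed_map` with attribute `truth`: a list holding the scale,
#'   grid mean before zero-meaning, per-electron full-capture voxel sum
#'   (`scale / voxel_volume`) and the spec.
#' @export
synth_density_map <- function(model, spec = model$spec) {
  st <- if (inherits(model, "ed_structure")) model else model$structure
  cell <- st$cell
  ngrid <- as.integer(round(c(cell$a, cell$b, cell$c) / spec$spacing))
  grid <- array(0, dim = ngrid)
  ops <- space_group_ops(spec$spacegroup)
  atoms <- st$atoms
  frac <- cart_to_frac(cell, as.matrix(atoms[, c("x", "y", "z")]))
  spacing3 <- c(cell$a, cell$b, cell$c) / ngrid
  for (op in ops) {
    fr_op <- apply_symop(op, frac)
    xyz <- frac_to_cart(cell, fr_op)
    for (i in seq_len(nrow(atoms))) {
      bprime <- atoms$b[i] + spec$b_grid
      s2 <- bprime / (8 * pi^2)
      rcut <- 6 * sqrt(s2)
      ctr_g <- fr_op[i, ] * ngrid - 0.5       # position in voxel-center units
      lo <- floor(ctr_g - rcut / spacing3)
      hi <- ceiling(ctr_g + rcut / spacing3)
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      cx <- frac_to_cart(cell, cbind((ii + 0.5) / ngrid[1], 0, 0))[, 1]
      # orthorhombic cells only in the generator: per-axis separable distances
      dx2 <- (cx - xyz[i, 1])^2
      dy2 <- (frac_to_cart(cell, cbind(0, (jj + 0.5) / ngrid[2], 0))[, 2] - xyz[i, 2])^2
      dz2 <- (frac_to_cart(cell, cbind(0, 0, (kk + 0.5) / ngrid[3]))[, 3] - xyz[i, 3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      dens <- gaussian_peak(atoms$z_e[i], atoms$occ[i], bprime) *
        exp(-4 * pi^2 * d2 / bprime)
      wi <- (ii %% ngrid[1]) + 1L; wj <- (jj %% ngrid[2]) + 1L; wk <- (kk %% ngrid[3]) + 1L
      grid[wi, wj, wk] <- grid[wi, wj, wk] + dens
    }
  }
  grid <- grid * spec$scale
  pre_mean <- mean(grid)
  if (spec$zero_mean) grid <- grid - pre_mean
  grid <- float32(grid)
  tab <- sohncke_table()
  sgnum <- tab$number[match(spec$spacegroup, tab$symbol)]
  triplets <- vapply(space_group_ops(spec$spacegroup), function(op) {
    op_to_triplet(op)
  }, character(1))
  map <- new_ed_map(grid, start = c(0L, 0L, 0L), ngrid = ngrid, cell = cell,
                    spacegroup = if (is.na(sgnum)) 1L else sgnum,
                    symmetry = triplets)
  attr(map, "truth") <- list(
    scale = spec$scale, pre_mean = pre_mean,
    per_electron_sum = spec$scale / map$voxel_volume,
    spec = spec
  )
  map
}

op_to_triplet <- function(op) {
  axes <- c("X", "Y", "Z")
  comp <- vapply(1:3, function(i) {
    terms <- character(0)
    for (j in 1:3) {
      if (op$R[i, j] == 1) terms <- c(terms, paste0("+", axes[j]))
      if (op$R[i, j] == -1) terms <- c(terms, paste0("-", axes[j]))
    }
    tfrac <- op$t[i] %% 1
    if (abs(tfrac) > 1e-9) {
      fr <- c(`0.5` = "1/2", `0.25` = "1/4", `0.75` = "3/4",
              `0.333333333333333` = "1/3", `0.666666666666667` = "2/3")
      key <- as.character(round(tfrac, 15))
      terms <- c(terms, paste0("+", if (key %in% names(fr)) fr[key] else format(tfrac)))
    }
    sub("^\\+", "", paste(terms, collapse = ""))
  }, character(1))
  paste(comp, collapse = ",")
}

#' Render a synthetic Fo-Fc-like difference map
#'
#' Independent per-voxel Gaussian noise plus injected signed Gaussian blobs
#' of known integrated electron content, scaled and zero-meaned like the
#' model map.
#'
#' @param model Output of [synth_structure()].
#' @param blobs A tibble/data.frame with columns `x`, `y`, `z` (Angstrom),
#'   `electrons` (signed: negative for missing density) and `width`
#'   (Gaussian sigma in Angstrom).
#' @param spec The [fixture_spec()]; defaults to `model$spec`.
#' @return An `ed_map` with attribute `truth` recording the blob table,
#'   noise sigma and scale.
#' @export
synth_difference_map <- function(model, blobs = NULL, spec = model$spec) {
  st <- if (inherits(model, "ed_structure")) model else model$structure
  cell <- st$cell
  ngrid <- as.integer(round(c(cell$a, cell$b, cell$c) / spec$spacing))
  set.seed(spec$seed + 104729L)            # distinct stream from the B-factors
  grid <- array(rnorm(prod(ngrid), 0, spec$noise_sd), dim = ngrid)
  spacing3 <- c(cell$a, cell$b, cell$c) / ngrid
  if (!is.null(blobs) && nrow(blobs)) {
    for (i in seq_len(nrow(blobs))) {
      s <- blobs$width[i]
      amp <- blobs$electrons[i] / ((2 * pi)^1.5 * s^3)
      ctr <- c(blobs$x[i], blobs$y[i], blobs$z[i])
      ctr_g <- cart_to_frac(cell, ctr) * ngrid - 0.5
      rcut <- 6 * s
      lo <- floor(ctr_g - rcut / spacing3)
      hi <- ceiling(ctr_g + rcut / spacing3)
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      dx2 <- (frac_to_cart(cell, cbind((ii + 0.5) / ngrid[1], 0, 0))[, 1] - ctr[1])^2
      dy2 <- (frac_to_cart(cell, cbind(0, (jj + 0.5) / ngrid[2], 0))[, 2] - ctr[2])^2
      dz2 <- (frac_to_cart(cell, cbind(0, 0, (kk + 0.5) / ngrid[3]))[, 3] - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      dens <- amp * exp(-d2 / (2 * s^2))
      wi <- (ii %% ngrid[1]) + 1L; wj <- (jj %% ngrid[2]) + 1L; wk <- (kk %% ngrid[3]) + 1L
      grid[wi, wj, wk] <- grid[wi, wj, wk] + dens
    }
  }
  grid <- grid * spec$scale
  if (spec$zero_mean) grid <- grid - mean(grid)
  grid <- float32(grid)
  map <- new_ed_map(grid, start = c(0L, 0L, 0L), ngrid = ngrid, cell = cell,
                    spacegroup = 1L, symmetry = "X,Y,Z")
  attr(map, "truth") <- list(
    blobs = blobs, noise_sd = spec$noise_sd, scale = spec$scale,
    per_electron_sum = spec$scale / map$voxel_volume, spec = spec
  )
  map
}

#' Fraction of a Gaussian blob's electrons above a density threshold
#'
#' For a Gaussian blob of `electrons` total content and width `width`
#' (sigma, Angstrom) rendered at map scale `scale`, the fraction of its
#' integrated density lying in voxels above the absolute density
#' `threshold` (map units). This is the analytic truncated-Gaussian oracle
#' used to account for tail loss below the significance threshold.
#'
#' @param electrons Blob electron content (absolute value used).
#' @param width Gaussian sigma in Angstrom.
#' @param threshold Absolute density threshold in map units.
#' @param scale Map scale factor.
#' @export
blob_truncated_fraction <- function(electrons, width, threshold, scale = 1) {
  peak <- scale * abs(electrons) / ((2 * pi)^1.5 * width^3)
  if (threshold >= peak) return(0)
  r2_over_s2 <- 2 * log(peak / threshold)
  pchisq(r2_over_s2, df = 3)
}

#' Generate a complete synthetic entry
#'
#' Convenience wrapper: builds the structure, the 2Fo-Fc-like map and
#' (optionally) a difference map with injected blobs.
#'
#' @param spec A [fixture_spec()].
#' @param blobs Optional blob table for [synth_difference_map()].
#' @return List with `structure`, `pdb`, `map`, `diff_map` (or `NULL`) and
#'   `spec`.
#' @export
synth_entry <- function(spec = fixture_spec(), blobs = NULL) {
  model <- synth_structure(spec)
  map <- synth_density_map(model)
  diff_map <- if (!is.null(blobs)) synth_difference_map(model, blobs) else NULL
  list(structure = model$structure, pdb = model$pdb, map = map,
       diff_map = diff_map, spec = spec)
}

#' Write a fixture bundle to disk
#'
#' Emits the PDB file, both CCP4 maps and a JSON sidecar with all
#' ground-truth values needed by oracles.
#'
#' @param entry Output of [synth_entry()].
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_fixture_bundle <- function(entry, dir, prefix = "fixture") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pdb = file.path(dir, paste0(prefix, ".pdb")),
             map = file.path(dir, paste0(prefix, "_2fofc.ccp4")),
             meta = file.path(dir, paste0(prefix, "_truth.json")))
  writeLines(entry$pdb, paths["pdb"])
  write_ccp4(entry$map, paths["map"])
  truth <- attr(entry$map, "truth")
  meta <- list(scale = truth$scale, per_electron_sum = truth$per_electron_sum,
               pre_mean = truth$pre_mean,
               spacing = entry$spec$spacing, b_grid = entry$spec$b_grid,
               seed = entry$spec$seed,
               radii = as.list(entry$spec$radii),
               sequences = as.list(entry$spec$sequences))
  if (!is.null(entry$diff_map)) {
    paths["diff"] <- file.path(dir, paste0(prefix, "_fofc.ccp4"))
    write_ccp4(entry$diff_map, paths["diff"])
    dtruth <- attr(entry$diff_map, "truth")
    meta$diff <- list(noise_sd = dtruth$noise_sd,
                      blobs = if (!is.null(dtruth$blobs)) dtruth$blobs else NULL)
  }
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
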