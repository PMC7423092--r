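# Independent voxel-level oracle for the conversion factor on synthetic
# entries: re-derives each chain's density ratio by direct evaluation of
# the analytic forward model at voxel centers, with its own index
# arithmetic and union bookkeeping (no edmapr cloud code involved).
conversion_oracle <- function(e, significance = 1.5, threshold_sum = FALSE,
                              chain_floor = 50L) {
  st <- e$structure
  spec <- e$spec
  map <- e$map
  cell <- st$cell
  ngrid <- map$ngrid
  h <- c(cell$a, cell$b, cell$c) / ngrid       # orthorhombic generator cells
  atoms <- st$atoms
  rad <- unname(spec$radii[atoms$atom_type])
  sigma <- sqrt(mean((map$grid - mean(map$grid))^2))
  thr <- if (threshold_sum) significance * sigma else -Inf
  # analytic zero-mean offset: all electrons spread over the cell
  offset <- spec$scale * sum(atoms$z_e * atoms$occ) / cell$volume
  # 1) union of in-radius voxel keys per chain
  keys_by_chain <- list()
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  for (i in seq_len(nrow(atoms))) {
    lo <- floor((coords[i, ] - rad[i]) / h - 0.5)
    hi <- ceiling((coords[i, ] + rad[i]) / h - 0.5)
    box <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    ctr <- sweep(box + 0.5, 2, h, `*`)
    d <- sqrt(rowSums(sweep(ctr, 2, coords[i, ])^2))
    sel <- box[d <= rad[i], , drop = FALSE]
    if (!nrow(sel)) next
    k <- paste(sel[, 1], sel[, 2], sel[, 3])
    ch <- atoms$chain[i]
    keys_by_chain[[ch]] <- c(keys_by_chain[[ch]], k)
  }
  ratios <- c()
  for (ch in names(keys_by_chain)) {
    keys <- unique(keys_by_chain[[ch]])
    idx <- do.call(rbind, lapply(strsplit(keys, " "), as.numeric))
    ctr <- sweep(idx + 0.5, 2, h, `*`)
    dens <- numeric(nrow(ctr))
    # analytic density: every atom's Gaussian, with a 6-sigma box prefilter
    for (i in seq_len(nrow(atoms))) {
      bp <- atoms$b[i] + spec$b_grid
      s6 <- 6 * sqrt(bp / (8 * pi^2))
      near <- abs(ctr[, 1] - coords[i, 1]) <= s6 &
        abs(ctr[, 2] - coords[i, 2]) <= s6 &
        abs(ctr[, 3] - coords[i, 3]) <= s6
      if (!any(near)) next
      d2 <- rowSums(sweep(ctr[near, , drop = FALSE], 2, coords[i, ])^2)
      dens[near] <- dens[near] + atoms$z_e[i] * atoms$occ[i] *
        (4 * pi / bp)^1.5 * exp(-4 * pi^2 * d2 / bp)
    }
    val <- spec$scale * dens - offset
    val <- val[val > thr]
    n_at <- sum(atoms$chain == ch)
    if (n_at < chain_floor) next
    ratios <- c(ratios, sum(val) / sum(atoms$z_e[atoms$chain == ch] *
                                         atoms$occ[atoms$chain == ch]))
  }
  median(ratios)
}
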