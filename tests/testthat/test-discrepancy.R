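test_that("significance thresholding is symmetric about zero with the expected tail", {
  m <- random_map(dims = c(40, 40, 40), cell_edges = c(20, 20, 20), seed = 8)
  stats <- map_statistics(m)
  pos <- significant_voxels(m, stats, 3, "positive")
  neg <- significant_voxels(m, stats, 3, "negative")
  n <- length(m$grid)
  p_tail <- pnorm(-3)
  # binomial tolerance: 4 sd around the expected count
  slack <- 4 * sqrt(n * p_tail)
  expect_lt(abs(length(pos) - n * p_tail), slack)
  expect_lt(abs(length(neg) - n * p_tail), slack)
  # negating the grid swaps the sets exactly
  m2 <- m; m2$grid <- -m$grid
  expect_identical(significant_voxels(m2, map_statistics(m2), 3, "negative"), pos)
  expect_identical(significant_voxels(m2, map_statistics(m2), 3, "positive"), neg)
  # an all-zero map yields nothing
  z <- m; z$grid[] <- 0
  expect_length(significant_voxels(z, map_statistics(z), 3, "positive"), 0L)
})

test_that("blob partitioning matches an igraph connected-components oracle", {
  skip_if_not_installed("igraph")
  m <- random_map(dims = c(16, 16, 16), cell_edges = c(8, 8, 8), seed = 21)
  stats <- map_statistics(m)
  ids <- significant_voxels(m, stats, 1.8, "positive")   # denser set than 3 sigma
  blobs <- find_blobs(m, ids)
  crs <- edmapr:::id_to_crs(m, ids)
  # oracle: graph over voxel pairs adjacent under 26-connectivity with wrap
  n <- length(ids)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(crs[i, ] - crs[j, ])
    d <- pmin(d, 16 - d)                  # periodic
    adj[i, j] <- all(d <= 1) && !all(d == 0)
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  expect_identical(nrow(blobs), as.integer(comp$no))
  # identical partition: same multiset of component memberships
  mine <- lapply(blobs$voxels, sort)
  theirs <- lapply(split(ids, comp$membership), sort)
  expect_setequal(
    vapply(mine, paste, character(1), collapse = ","),
    vapply(theirs, paste, character(1), collapse = ",")
  )
  # partition conserves the total |density|
  expect_equal(sum(abs(blobs$total_density)), sum(abs(m$grid[ids])), tolerance = 1e-9)
})

test_that("blob connectivity follows the chosen neighborhood", {
  g <- array(0, dim = c(10, 10, 10))
  g[2, 2, 2] <- 5; g[3, 3, 3] <- 5        # corner contact
  g[7, 7, 7] <- 5                         # isolated, >= 2 voxels away
  m <- edmapr:::new_ed_map(g, c(0L, 0L, 0L), c(10L, 10L, 10L), unit_cell(10, 10, 10))
  ids <- which(g > 0)
  b26 <- find_blobs(m, ids, connectivity = 26)
  expect_identical(nrow(b26), 2L)
  b6 <- find_blobs(m, ids, connectivity = 6)
  expect_identical(nrow(b6), 3L)
  # order of voxel enumeration does not change the partition
  b26b <- find_blobs(m, rev(ids), connectivity = 26)
  expect_identical(b26b$total_density, b26$total_density)
  expect_identical(nrow(find_blobs(m, integer(0))), 0L)
})

test_that("blob electron estimates recover injected content and cancel scale", {
  spec <- fixture_spec(seed = 13, scale = 2.4)
  mod <- synth_structure(spec)
  ctr <- colMeans(mod$structure$atoms[, c("x", "y", "z")])
  blobs_in <- tibble::tibble(
    x = c(ctr[1] - 15, ctr[1] + 15), y = ctr[2] + c(0, 3), z = ctr[3] + c(5, 5),
    electrons = c(12, -10), width = c(0.55, 0.55)
  )
  dm <- synth_difference_map(mod, blobs_in)
  truth <- attr(dm, "truth")
  stats <- map_statistics(dm)
  found <- analyze_difference(mod$structure, dm, conv = truth$per_electron_sum,
                              n_sigma = 3)
  top2 <- found[order(-found$n_voxels), ][1:2, ]
  expect_setequal(top2$sign, c("positive", "negative"))
  thr <- 3 * stats$sigma
  for (i in 1:2) {
    bi <- blobs_in[c(which(blobs_in$electrons > 0), which(blobs_in$electrons < 0))[
      match(top2$sign[i], c("positive", "negative"))], ]
    frac <- blob_truncated_fraction(bi$electrons, bi$width, thr, truth$scale)
    expect_gt(frac, 0.85)
    expect_lt(abs(top2$electrons[i] - abs(bi$electrons) * frac) / abs(bi$electrons),
              0.1)
    # centroid lands on the injected center
    got <- c(top2$cx[i], top2$cy[i], top2$cz[i])
    expect_lt(sqrt(sum((got - c(bi$x, bi$y, bi$z))^2)), 0.5)
  }
  # co-scaling both maps leaves the electron estimate unchanged
  dm2 <- dm; dm2$grid <- dm$grid * 3
  found2 <- analyze_difference(mod$structure, dm2, conv = truth$per_electron_sum * 3,
                               n_sigma = 3)
  t2 <- found2[order(-found2$n_voxels), ][1:2, ]
  expect_equal(sort(t2$electrons), sort(top2$electrons), tolerance = 1e-5)
})

test_that("blob assignment matches exhaustive nearest-neighbor search", {
  mod <- synth_structure(fixture_spec(sequences = c(A = "AGSDKLNQERT"),
                                      coord_jitter = 0, seed = 6))
  st <- mod$structure
  set.seed(31)
  blobs <- tibble::tibble(
    blob = 1:12, sign = "positive", n_voxels = 10L, volume = 1,
    total_density = 1,
    cx = runif(12, -5, max(st$atoms$x) + 5),
    cy = runif(12, -5, max(st$atoms$y) + 5),
    cz = runif(12, -5, max(st$atoms$z) + 5),
    voxels = replicate(12, integer(0), simplify = FALSE)
  )
  got <- assign_blobs(blobs, st, cutoff = 5)
  pm <- as.matrix(st$atoms[, c("x", "y", "z")])
  for (i in 1:12) {
    d <- sqrt((pm[, 1] - blobs$cx[i])^2 + (pm[, 2] - blobs$cy[i])^2 +
                (pm[, 3] - blobs$cz[i])^2)
    j <- which.min(d)
    expect_equal(got$distance[i], min(d), tolerance = 1e-12)
    if (min(d) <= 5) {
      expect_identical(got$nearest_atom[i], st$atoms$name[j])
      expect_true(got$assigned[i])
    } else {
      expect_false(got$assigned[i])
    }
  }
})

test_that("F000 arithmetic matches hand computation on enumerable cells", {
  mk <- function(atoms, waters, hetero, cell, sg) {
    structure(list(atoms = atoms, waters = waters, hetero = hetero,
                   cell = cell, spacegroup = sg), class = "ed_structure")
  }
  proto <- tibble::tibble(serial = 1L, name = "C1", altloc = " ", resname = "LIG",
                          chain = "X", resseq = 1L, icode = " ",
                          x = 0, y = 0, z = 0, occ = 1, b = 10, element = "C",
                          z_e = 6L)
  none <- proto[0, ]
  # one carbon, P 1, V = 1000 -> 0.006 e/A^3
  st1 <- mk(none, none, proto, unit_cell(10, 10, 10), "P 1")
  est1 <- f000_estimate(st1)
  expect_equal(est1$f000, 6)
  expect_equal(est1$offset, 0.006)
  # one water (folded 10 electrons), P 1, V = 1000 -> 0.010
  wat <- proto; wat$element <- "O"; wat$resname <- "HOH"; wat$z_e <- 10L
  est2 <- f000_estimate(mk(none, wat, none, unit_cell(10, 10, 10), "P 1"))
  expect_equal(est2$offset, 0.010)
  # P 21 21 21 (4 operators), asymmetric-unit sum 100 e, V = 8000 -> 0.05
  hund <- proto; hund$z_e <- 100L
  est3 <- f000_estimate(mk(none, none, hund, unit_cell(20, 20, 20), "P 21 21 21"))
  expect_equal(est3$n_ops, 4L)
  expect_equal(est3$offset, 0.05)
  # linear in occupancy, additive over atoms
  half <- proto; half$occ <- 0.5
  est4 <- f000_estimate(mk(none, none, dplyr::bind_rows(proto, half),
                           unit_cell(10, 10, 10), "P 1"))
  expect_equal(est4$f000, 6 + 3)
  # multiplicity route equals explicit expansion for the synthetic model
  mod <- synth_structure(fixture_spec(sequences = c(A = "AG"),
                                      spacegroup = "P 21 21 21",
                                      coord_jitter = 0, seed = 9))
  est5 <- f000_estimate(mod$structure)
  expect_equal(est5$f000,
               4 * sum(mod$structure$atoms$z_e * mod$structure$atoms$occ))
  # offset shifts a map's mean by exactly the offset
  m <- random_map()
  m2 <- add_f000(m, est1$offset)
  expect_equal(map_statistics(m2)$mean, map_statistics(m)$mean + 0.006,
               tolerance = 1e-9)
  expect_error(f000_estimate(mk(none, none, proto, NULL, "P 1")), "cell")
})
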