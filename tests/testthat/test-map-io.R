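test_that("unit cell volume and transforms satisfy the crystallographic identities", {
  cells <- list(
    unit_cell(10, 10, 10),
    unit_cell(12.3, 8.7, 21.4),
    unit_cell(10, 12, 14, 90, 90, 120),
    unit_cell(11, 13, 17, 83.2, 97.5, 105.1)
  )
  for (cl in cells) {
    ca <- cos(cl$alpha * pi / 180); cb <- cos(cl$beta * pi / 180)
    cg <- cos(cl$gamma * pi / 180)
    expect_equal(cl$volume,
                 cl$a * cl$b * cl$c * sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg),
                 tolerance = 1e-12)
    expect_gt(cl$volume, 0)
    set.seed(4)
    fr <- matrix(runif(30), ncol = 3)
    expect_equal(cart_to_frac(cl, frac_to_cart(cl, fr)), fr, tolerance = 1e-9)
  }
})

test_that("CCP4 write/read round trip is bit exact, including axis permutations", {
  m <- random_map(dims = c(6, 8, 10), cell_edges = c(6, 8, 10))
  perms <- list(c(1L, 2L, 3L), c(3L, 1L, 2L), c(2L, 3L, 1L), c(3L, 2L, 1L))
  for (p in perms) {
    f <- withr::local_tempfile(fileext = ".ccp4")
    write_ccp4(m, f, axis_order = p)
    m2 <- read_ccp4(f)
    expect_identical(m2$grid, m$grid)
    expect_identical(m2$start, m$start)
    expect_identical(m2$ngrid, m$ngrid)
    expect_equal(m2$cell$volume, m$cell$volume, tolerance = 1e-6)
  }
  # oracle: the permuted storage array equals direct index permutation
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(m, f, axis_order = c(3L, 1L, 2L))
  raw <- readBin(f, "raw", n = file.size(f))
  nsym <- readBin(raw[93:96], "integer", size = 4L)
  vals <- readBin(raw[(1025 + nsym):length(raw)], "double", size = 4L,
                  n = prod(dim(m$grid)))
  stored <- array(vals, dim = dim(m$grid)[c(3, 1, 2)])
  for (i in 1:3) for (j in 1:4) for (k in 1:5) {
    expect_identical(stored[k, i, j], m$grid[i, j, k])
  }
})

test_that("single-voxel and constant maps round trip and report exact statistics", {
  one <- edmapr:::new_ed_map(array(42.5, dim = c(1, 1, 1)), c(0L, 0L, 0L),
                             c(1L, 1L, 1L), unit_cell(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(one, f)
  expect_identical(read_ccp4(f)$grid[1, 1, 1], 42.5)

  const <- edmapr:::new_ed_map(array(1, dim = c(8, 8, 8)), c(0L, 0L, 0L),
                               c(8L, 8L, 8L), unit_cell(10, 10, 10))
  s <- map_statistics(const)
  expect_identical(s$mean, 1)
  expect_identical(s$sigma, 0)

  spike <- array(0, dim = c(10, 10, 10)); spike[3, 4, 5] <- 100
  sm <- map_statistics(edmapr:::new_ed_map(spike, c(0L, 0L, 0L), c(10L, 10L, 10L),
                                           unit_cell(10, 10, 10)))
  expect_equal(sm$max, 100)
  expect_equal(sm$mean, 0.1)
})

test_that("malformed map streams are rejected with informative errors", {
  m <- random_map(dims = c(4, 4, 4), cell_edges = c(4, 4, 4))
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(m, f)
  raw <- readBin(f, "raw", n = file.size(f))
  # corrupt the magic word
  bad <- raw; bad[209] <- as.raw(0x58)
  f1 <- withr::local_tempfile(); writeBin(bad, f1)
  expect_error(read_ccp4(f1), "magic")
  # unsupported mode
  bad <- raw; bad[13:16] <- writeBin(1L, raw(), size = 4L)
  f2 <- withr::local_tempfile(); writeBin(bad, f2)
  expect_error(read_ccp4(f2), "mode")
  # truncated data section
  f3 <- withr::local_tempfile(); writeBin(raw[1:(length(raw) - 40)], f3)
  expect_error(read_ccp4(f3), "truncat")
})

test_that("map statistics match an independent two-pass computation and scale with k", {
  m <- random_map(dims = c(7, 9, 5), cell_edges = c(7, 9, 5), seed = 11)
  s <- map_statistics(m)
  v <- as.numeric(m$grid)
  mu <- sum(v) / length(v)
  expect_equal(s$mean, mu, tolerance = 1e-12)
  expect_equal(s$sigma, sqrt(sum((v - mu)^2) / length(v)), tolerance = 1e-12)
  m2 <- m; m2$grid <- m$grid * -3
  expect_equal(map_statistics(m2)$sigma, 3 * s$sigma, tolerance = 1e-12)
})

test_that("voxel/Cartesian transforms honor starts, centers and inverses", {
  m <- edmapr:::new_ed_map(array(0, dim = c(10, 10, 10)), c(0L, 0L, 0L),
                           c(10L, 10L, 10L), unit_cell(10, 10, 10))
  expect_identical(drop(xyz_to_crs(m, c(2.5, 0.5, 9.5))), c(2L, 0L, 9L))
  expect_equal(drop(crs_to_xyz(m, c(2L, 0L, 9L))), c(2.5, 0.5, 9.5))
  # triclinic: crs -> xyz -> crs is identity on voxel centers
  tri <- edmapr:::new_ed_map(array(0, dim = c(8, 8, 8)), c(0L, 0L, 0L),
                             c(8L, 8L, 8L), unit_cell(10, 12, 14, 90, 90, 120))
  idx <- as.matrix(expand.grid(0:7, 0:7, 0:7))
  expect_identical(xyz_to_crs(tri, crs_to_xyz(tri, idx)), unname(idx) + 0L)
  # start offsets shift the frame
  off <- edmapr:::new_ed_map(array(0, dim = c(5, 5, 5)), c(2L, 3L, 4L),
                             c(10L, 10L, 10L), unit_cell(10, 10, 10))
  expect_equal(drop(crs_to_xyz(off, c(2L, 3L, 4L))), c(2.5, 3.5, 4.5))
  expect_true(all(is.na(xyz_to_crs(off, c(0.1, 0.1, 0.1)))))  # outside partial extent
})

test_that("voxels_within_radius equals the brute-force scan, with wrap and monotonicity", {
  m <- random_map(dims = c(12, 10, 8), cell_edges = c(6, 5, 4), seed = 3)
  all_idx <- as.matrix(expand.grid(0:11, 0:9, 0:7))
  centers <- crs_to_xyz(m, all_idx)
  brute <- function(center, radius) {
    # periodic images: +/- 1 cell along each axis
    sh <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    best <- rep(Inf, nrow(centers))
    for (s in seq_len(nrow(sh))) {
      img <- sweep(centers, 2, sh[s, ] * c(6, 5, 4), `+`)
      d <- sqrt(rowSums(sweep(img, 2, center)^2))
      best <- pmin(best, d)
    }
    sort(which(best <= radius))
  }
  set.seed(9)
  for (i in 1:25) {
    ctr <- runif(3) * c(6, 5, 4)
    rad <- runif(1, 0.3, 1.4)
    got <- voxels_within_radius(m, ctr, rad)
    expect_identical(sort(got$id), brute(ctr, rad), label = sprintf("case %d", i))
  }
  # boundary center exercises wrapping explicitly
  got <- voxels_within_radius(m, c(0.05, 2.5, 2), 1.0)
  expect_identical(sort(got$id), brute(c(0.05, 2.5, 2), 1.0))
  # monotone in radius
  ctr <- c(3, 2.5, 2)
  r1 <- voxels_within_radius(m, ctr, 0.7)$id
  r2 <- voxels_within_radius(m, ctr, 1.2)$id
  expect_true(all(r1 %in% r2))
  # a sub-voxel radius at a voxel center hits exactly that voxel
  got1 <- voxels_within_radius(m, drop(crs_to_xyz(m, c(5L, 5L, 5L))), 0.2)
  expect_identical(nrow(got1), 1L)
})

test_that("partial-coverage maps skip out-of-extent voxels and flag the cloud", {
  # stored extent covers half the cell along x: no wrapping on that axis
  full <- random_map(dims = c(10, 8, 8), cell_edges = c(10, 8, 8), seed = 29)
  part <- edmapr:::new_ed_map(full$grid[1:5, , ], start = c(0L, 0L, 0L),
                              ngrid = c(10L, 8L, 8L), cell = full$cell)
  inside <- voxels_within_radius(part, c(2.5, 4, 4), 1.0)
  expect_false(attr(inside, "partial"))
  edge <- voxels_within_radius(part, c(4.9, 4, 4), 1.0)
  expect_true(attr(edge, "partial"))
  # the returned voxels are exactly the in-extent subset of the full-map set
  ref <- voxels_within_radius(full, c(4.9, 4, 4), 1.0)
  ref_in <- ref[ref$ix < 5, ]
  expect_setequal(paste(edge$ix, edge$iy, edge$iz),
                  paste(ref_in$ix, ref_in$iy, ref_in$iz))
  # wrapping still applies along the fully covered axes
  wrapd <- voxels_within_radius(part, c(2.5, 0.1, 4), 1.0)
  expect_true(any(wrapd$iy == 7))
})
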