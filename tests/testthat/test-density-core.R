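test_that("the equation chain identities hold on hand-computable inputs", {
  # volume normalization: identity at the type-median volume, Eq-2 arithmetic
  expect_identical(normalize_volume(1.5, 25, 25), 1.5)
  expect_identical(normalize_volume(1.0, 20, 25), 1.25)
  expect_identical(normalize_volume(2.0, 10, 25) / normalize_volume(2.0, 20, 25), 2)
  expect_true(is.na(normalize_volume(1.0, 0, 25)))
  # chain deviation fraction: zero at the chain median, plain arithmetic
  expect_identical(chain_deviation_fraction(1.0, 1.0), 0)
  expect_equal(chain_deviation_fraction(1.1, 1.0), 0.1)
  expect_error(chain_deviation_fraction(1.0, 0), "positive")
  # B-factor correction: no-op at the median log B
  expect_identical(correct_bfactor(0.07, log(20), log(20), -0.6), 0.07)
  out <- correct_bfactor(0, log(20) + 0.5, log(20), 0.2, median_rc = 1.0)
  expect_equal(out$f_corrected, -0.1)
  expect_equal(out$r_corrected, 0.9)
  # Eq 5 then Eq 3 round trip: r -> f is the algebraic inverse
  conv <- 2.37
  f <- c(-0.2, 0, 0.15)
  r <- f * conv + conv
  expect_equal(chain_deviation_fraction(r, conv), f, tolerance = 1e-12)
  # conversion factor: order statistics with the stated median convention
  expect_identical(conversion_factor(0.9)$value, 0.9)
  expect_identical(conversion_factor(c(0.8, 1.0, 1.2))$value, 1.0)
  expect_identical(conversion_factor(c(0.8, 1.0, 1.2, 1.4))$value, 1.1)
  expect_error(conversion_factor(numeric(0)), "no qualifying")
})

test_that("slope fitting matches the closed-form normal equations and falls back", {
  # exact line: slope recovered to numerical precision
  b <- exp(seq(2.3, 4, length.out = 12))
  f <- 0.2 * log(b) - 0.55
  fit <- fit_bfactor_slopes(f, b, rep("C_single", 12), fallback = slope_table(0))
  expect_equal(fit$slope[fit$type == "C_single"], 0.2, tolerance = 1e-9)
  expect_identical(fit$source[fit$type == "C_single"], "fitted")
  # noisy case against an independent lm() oracle
  set.seed(42)
  b2 <- rlnorm(100, log(25), 0.4)
  f2 <- -0.3 * log(b2) + rnorm(100, 0, 0.05)
  fit2 <- fit_bfactor_slopes(f2, b2, rep("O_single", 100), fallback = slope_table(0))
  oracle <- unname(coef(lm(f2 ~ log(b2)))[2])
  expect_equal(fit2$slope[fit2$type == "O_single"], oracle, tolerance = 1e-9)
  # fewer than three points or zero variance -> shipped default
  fit3 <- fit_bfactor_slopes(c(0.1, 0.2), c(20, 30), rep("S_single", 2),
                             fallback = slope_table(-0.77))
  expect_identical(fit3$slope[fit3$type == "S_single"], -0.77)
  expect_identical(fit3$source[fit3$type == "S_single"], "default")
  fit4 <- fit_bfactor_slopes(c(0.1, 0.2, 0.3), c(20, 20, 20), rep("S_single", 3),
                             fallback = slope_table(-0.77))
  expect_identical(fit4$slope[fit4$type == "S_single"], -0.77)
})

test_that("atom clouds match direct voxel summation and honor occupancy", {
  # single isolated Gaussian atom on a fine grid
  spec <- fixture_spec(sequences = c(A = "G"), coord_jitter = 0, seed = 2,
                       zero_mean = FALSE, scale = 1.7)
  mod <- synth_structure(spec)
  map <- synth_density_map(mod)
  stats <- map_statistics(map)
  atom <- mod$structure$atoms[2, ]   # CA of the single glycine
  # brute-force oracle: scan every voxel of the map, both threshold modes
  idx <- as.matrix(expand.grid(seq_len(dim(map$grid)[1]) - 1,
                               seq_len(dim(map$grid)[2]) - 1,
                               seq_len(dim(map$grid)[3]) - 1))
  ctr <- crs_to_xyz(map, idx)
  d <- sqrt(rowSums(sweep(ctr, 2, c(atom$x, atom$y, atom$z))^2))
  v <- as.numeric(map$grid)
  cl <- atom_cloud(map, stats, atom, radius = 0.8)
  keep <- d <= 0.8
  expect_identical(cl$V, sum(keep))
  expect_equal(cl$total_density, sum(v[keep]), tolerance = 1e-9)
  expect_equal(cl$r, sum(v[keep]) / atom$z_e, tolerance = 1e-9)
  cl_t <- atom_cloud(map, stats, atom, radius = 0.8, threshold_sum = TRUE)
  keep_t <- d <= 0.8 & v > 1.5 * stats$sigma
  expect_identical(cl_t$V, sum(keep_t))
  expect_equal(cl_t$total_density, sum(v[keep_t]), tolerance = 1e-9)
  # halving the occupancy doubles the ratio at fixed density
  atom_half <- atom; atom_half$occ <- 0.5
  cl_half <- atom_cloud(map, stats, atom_half, radius = 0.8)
  expect_equal(cl_half$r, 2 * cl$r, tolerance = 1e-12)
  # an atom in a zero-density region: no significant voxels, flagged empty
  far <- atom; far$x <- atom$x + 6
  cl_far <- atom_cloud(map, stats, far, radius = 0.5, threshold_sum = TRUE)
  expect_identical(cl_far$V, 0L)
  expect_true(cl_far$empty)
})

test_that("aggregation takes voxel unions with inclusion-exclusion and floors", {
  mk <- function(ids, vals, z = 7L) {
    structure(list(owner = NULL,
                   voxels = tibble::tibble(id = ids, dist = seq_along(ids) * 0.1,
                                           value = vals),
                   V = length(ids), total_density = sum(vals), electrons = z,
                   r = sum(vals) / z, partial = FALSE, empty = !length(ids)),
              class = "ed_cloud")
  }
  a <- mk(c(1L, 2L, 3L), c(0.5, 0.25, 0.25))
  b <- mk(c(4L, 5L), c(0.3, 0.2))
  disj <- aggregate_cloud(list(a, b, a, b), "residue")
  # duplicated members still count each voxel once
  expect_identical(disj$V, 5L)
  expect_equal(disj$total_density, 1.5)
  expect_equal(disj$electrons, 28)
  # sharing exactly one voxel subtracts it once
  c2 <- mk(c(3L, 6L), c(0.25, 0.4))
  both <- aggregate_cloud(list(a, b, c2, mk(7L, 0.1)), "residue")
  expect_equal(both$total_density, 0.5 + 0.25 + 0.25 + 0.3 + 0.2 + 0.4 + 0.1)
  expect_identical(both$V, 7L)
  # three atoms do not meet the 4-atom residue floor
  expect_null(aggregate_cloud(list(a, b, c2), "residue"))
  expect_null(aggregate_cloud(rep(list(a), 49), "chain"))
  expect_false(is.null(aggregate_cloud(rep(list(a), 50), "chain")))
})

test_that("analyze_entry is deterministic and self-consistent at the true radii", {
  e <- default_entry()
  an <- default_analysis()
  expect_tibble(an$atoms); expect_tibble(an$chains); expect_tibble(an$type_stats)
  expect_identical(nrow(an$chains), 2L)
  expect_true(all(is.finite(an$type_stats$median_f_corrected)))
  expect_identical(an$conversion$n_chains, 2L)
  # rerun on identical inputs gives identical output
  an2 <- analyze_entry(e$structure, e$map, radii = e$spec$radii)
  expect_equal(an2$atoms, an$atoms, tolerance = 1e-15)
  expect_identical(an2$conversion$value, an$conversion$value)
  # residue and chain conservation: electrons add over members
  ok <- an$atoms[an$atoms$flag == "ok" | an$atoms$flag == "empty", ]
  by_chain <- tapply(ok$z_e * ok$occ, ok$chain, sum)
  expect_equal(as.numeric(by_chain[an$chains$chain]), an$chains$electrons)
  expect_true(all(an$residues$n_atoms >= 4 | !an$residues$qualifies))
  # union voxel count never exceeds the sum of member counts
  expect_true(all(an$chains$V <=
                    as.numeric(tapply(ok$V, ok$chain, sum)[an$chains$chain])))
  # glance/tidy surface
  g <- glance(an)
  expect_identical(nrow(g), 1L)
  expect_identical(tidy(an, "chain"), an$chains)
  expect_identical(tidy(an, "residue"), an$residues)
})

test_that("f and f_corrected are invariant under global map rescaling", {
  e <- default_entry()
  base <- default_analysis()
  for (k in c(0.5, 2, 10)) {
    m2 <- e$map; m2$grid <- e$map$grid * k
    an2 <- analyze_entry(e$structure, m2, radii = e$spec$radii)
    expect_equal(an2$conversion$value, base$conversion$value * k, tolerance = 1e-6)
    expect_equal(an2$atoms$f, base$atoms$f, tolerance = 1e-9)
    expect_equal(an2$atoms$f_corrected, base$atoms$f_corrected, tolerance = 1e-9)
  }
})

test_that("zero-occupancy and non-positive-B atoms are excluded with a note", {
  mod <- synth_structure(fixture_spec(sequences = c(A = "AGSDKLNQERT"),
                                      coord_jitter = 0, seed = 4))
  st <- mod$structure
  st$atoms$occ[5] <- 0
  st$atoms$b[9] <- -1
  map <- synth_density_map(mod)
  expect_message(an <- analyze_entry(st, map, radii = mod$spec$radii,
                                     chain_floor = 10L),
                 "excluded")
  expect_identical(an$atoms$flag[5], "excluded")
  expect_identical(an$atoms$flag[9], "excluded")
  expect_true(all(is.na(an$atoms$r[c(5, 9)])))
})
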