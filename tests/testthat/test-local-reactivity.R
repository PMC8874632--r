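test_that("grid compatibility checks report what differs", {
  triad <- gaussian_density_triad(c(0, 0, 0), 1, c(1, 2, 3),
                                  grid_shape = 8L, grid_extent = 6)
  g <- triad$rho_n
  expect_true(check_grid_compat(g, g)$pass)

  other <- density_grid(g$origin, g$axes,
                        array(0, dim = c(8L, 8L, 4L)))
  chk <- check_grid_compat(g, other)
  expect_false(chk$pass)
  expect_match(chk$diagnostics, "dimension\\(s\\) 3")

  shifted <- density_grid(g$origin + c(1e-3, 0, 0), g$axes, g$values)
  chk <- check_grid_compat(g, shifted)
  expect_false(chk$pass)
  expect_match(chk$diagnostics, "origin mismatch: max deviation 1.000e-03")
})

test_that("Fukui functions integrate to one added/removed electron", {
  triad <- gaussian_density_triad(
    centers = rbind(c(-1.5, 0, 0), c(1.5, 0, 0)),
    widths = c(0.9, 1.1), electron_counts = c(3, 4, 5),
    grid_shape = 48L, grid_extent = 8
  )
  for (g in unclass(triad)) {
    expect_true(all(g$values >= 0))
    expect_equal(integrate_grid(g), g$n_electrons_nominal, tolerance = 0.005)
  }
  nff <- nucleophilic_fukui(triad)
  eff <- electrophilic_fukui(triad)
  expect_equal(integrate_grid(nff), 1, tolerance = 0.01)
  expect_equal(integrate_grid(eff), 1, tolerance = 0.01)
  dd <- dual_descriptor(nff, eff)
  expect_equal(integrate_grid(dd), 0, tolerance = 0.02)
  # linearity: integral(DD) = integral(NFF) - integral(EFF) exactly
  expect_equal(integrate_grid(dd), integrate_grid(nff) - integrate_grid(eff),
               tolerance = 1e-9)
})

test_that("identical densities give vanishing Fukui grids and equal-shape DD vanishes", {
  g <- gaussian_density_triad(c(0, 0, 0), 1, c(1, 2, 3),
                              grid_shape = 16L, grid_extent = 6)$rho_n
  same <- grid_triad(g, g, g)
  expect_true(all(nucleophilic_fukui(same)$values == 0))
  expect_true(all(electrophilic_fukui(same)$values == 0))

  # equal equal-split occupancy shapes: NFF and EFF coincide, DD is zero
  triad <- gaussian_density_triad(c(0, 0, 0), 1.2, c(1, 2, 3),
                                  grid_shape = 24L, grid_extent = 7)
  dd <- dual_descriptor(nucleophilic_fukui(triad),
                        electrophilic_fukui(triad))
  expect_lt(max(abs(dd$values)), 1e-12)
})

test_that("DD attains both signs and localizes the added electron", {
  centers <- rbind(c(-2.5, 0, 0), c(2.5, 0, 0))
  # N-1: one electron per center; N: extra on center 1; N+1: extra on center 2
  occ <- cbind(c(1, 1), c(2, 1), c(2, 2))
  triad <- gaussian_density_triad(centers, 0.8, c(2, 3, 4),
                                  grid_shape = 48L, grid_extent = 7,
                                  occupancies = occ)
  dd <- dual_descriptor(nucleophilic_fukui(triad),
                        electrophilic_fukui(triad))
  expect_true(any(dd$values > 0) && any(dd$values < 0))
  # value at the voxel nearest each center: + where the (N+1)th electron
  # lands, - where the Nth did
  coord <- function(d, i) dd$origin[d] + dd$axes[d, d] * (i - 1)
  nearest <- function(ctr) {
    idx <- vapply(1:3, function(d) {
      which.min(abs(coord(d, seq_len(dd$shape[d])) - ctr[d]))
    }, integer(1L))
    dd$values[idx[1L], idx[2L], idx[3L]]
  }
  expect_gt(nearest(centers[2L, ]), 0)
  expect_lt(nearest(centers[1L, ]), 0)
})

test_that("grid operations refuse mismatched lattices", {
  a <- gaussian_density_triad(c(0, 0, 0), 1, c(1, 2, 3),
                              grid_shape = 12L, grid_extent = 6)
  b <- gaussian_density_triad(c(0, 0, 0), 1, c(1, 2, 3),
                              grid_shape = 16L, grid_extent = 6)
  expect_error(grid_triad(a$rho_nminus, b$rho_n, a$rho_nplus),
               "incompatible")
  expect_error(dual_descriptor(a$rho_n, b$rho_n), "incompatible grids")
})

test_that("condensed Fukui functions follow the charge-difference convention", {
  got <- condensed_fukui(c("a1", "a2"),
                         q_nminus = c(0.6, 0.4),
                         q_n = c(0.1, -0.1),
                         q_nplus = c(-0.5, -0.5))
  expect_equal(got$f_plus, c(0.6, 0.4))
  expect_equal(got$f_minus, c(0.5, 0.5))
  expect_equal(got$dd, c(0.1, -0.1))
  expect_equal(sum(got$f_plus), 1)
  expect_equal(sum(got$f_minus), 1)

  one <- condensed_fukui("a", 1, 0, -1)
  expect_equal(one$f_plus, 1)
  expect_equal(one$f_minus, 1)
  expect_equal(one$dd, 0)

  expect_error(condensed_fukui(c("a", "b"), c(0, 0), c(0, 0), c(0, 0)),
               "differ by 1 e")
  expect_error(condensed_fukui("a", c(1, 0), 0, -1), "match the number")
})

test_that("condensed values agree with grid Fukui basin integrals", {
  centers <- rbind(c(-3, 0, 0), c(3, 0, 0))
  # electron bookkeeping per center: cation (1,1), neutral (1.6,1.4),
  # anion gains 0.8 on center 2 and 0.2 on center 1
  occ <- cbind(c(1, 1), c(1.6, 1.4), c(1.8, 2.2))
  triad <- gaussian_density_triad(centers, 0.7, c(2, 3, 4),
                                  grid_shape = 56L, grid_extent = 8,
                                  occupancies = occ)
  nff <- nucleophilic_fukui(triad)
  eff <- electrophilic_fukui(triad)

  # nearest-center basins (well-separated narrow Gaussians)
  basin_integral <- function(grid, which_center) {
    xs <- grid$origin[1L] + grid$axes[1L, 1L] * (seq_len(grid$shape[1L]) - 1L)
    in_basin <- if (which_center == 1L) xs < 0 else xs >= 0
    sum(grid$values[in_basin, , ]) * voxel_volume(grid)
  }

  # synthetic Hirshfeld-style charges: q_k = Z_k - (electrons on atom k)
  z <- c(2, 2)
  cf <- condensed_fukui(c("c1", "c2"),
                        q_nminus = z - occ[, 1L],
                        q_n = z - occ[, 2L],
                        q_nplus = z - occ[, 3L])
  for (k in 1:2) {
    expect_equal(basin_integral(nff, k), cf$f_plus[k], tolerance = 0.02,
                 label = sprintf("NFF basin %d", k))
    expect_equal(basin_integral(eff, k), cf$f_minus[k], tolerance = 0.02,
                 label = sprintf("EFF basin %d", k))
  }
})
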