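test_that("energy conversion uses the fixed factors and is linear", {
  expect_identical(convert_energy(1, "hartree"), 27.211386)
  expect_equal(convert_energy(-0.2438, "hartree"), -6.634136, tolerance = 1e-6)
  expect_identical(convert_energy(3.5, "eV"), 3.5)
  expect_equal(convert_energy(1, "kcal/mol"), 0.0433641)
  expect_error(convert_energy(1, "joule"), "unknown energy unit")

  set.seed(11)
  for (unit in c("eV", "hartree", "kcal/mol")) {
    a <- runif(20, -10, 10); b <- runif(20, -10, 10)
    expect_equal(convert_energy(a + b, unit),
                 convert_energy(a, unit) + convert_energy(b, unit),
                 tolerance = 1e-12)
  }
})

test_that("the shipped energetics table yields seven complete triads in eV", {
  triads <- veraguamide_triads()
  expect_length(triads, 7L)
  expect_setequal(names(triads), paste("Veraguamide", LETTERS[1:7]))
  for (tr in triads) {
    expect_false(tr$partial)
    expect_s3_class(tr$neutral, "species_record")
    expect_lt(tr$neutral$homo, tr$neutral$lumo)
    expect_false(is.na(tr$anion$somo))
    # totals unpublished: KID total-energy indices must refuse these records
    expect_error(j_ionization(tr), "total energies required")
    expect_error(j_affinity(tr), "total energies required")
  }
  a <- triads[["Veraguamide A"]]
  expect_equal(a$neutral$homo, -6.635)
  expect_equal(a$anion$somo, -0.892)
  expect_equal(a$solvent$dielectric, 78.36)
})

test_that("grouping is total and partial triads are flagged", {
  header <- paste("molecule_id,functional,solvent_name,solvent_dielectric",
                  "charge,multiplicity,total_energy,energy_unit,homo,lumo,somo",
                  sep = ",")
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(header, tmp)
  expect_length(read_energetics_table(tmp), 0L)

  neutral_rows <- sprintf("m%02d,F,w,78,0,1,0,eV,-6.5,-0.9,", 1:7)
  writeLines(c(header, neutral_rows), tmp)
  triads <- read_energetics_table(tmp)
  expect_length(triads, 7L)
  expect_true(all(vapply(triads, `[[`, logical(1L), "partial")))
  # every input row lands in exactly one triad
  expect_identical(sort(names(triads)), sprintf("m%02d", 1:7))
})

test_that("malformed and duplicate rows are rejected with context", {
  header <- paste("molecule_id,functional,solvent_name,solvent_dielectric",
                  "charge,multiplicity,total_energy,energy_unit,homo,lumo,somo",
                  sep = ",")
  tmp <- withr::local_tempfile(fileext = ".csv")

  writeLines(c(header, "m1,F,w,78,0,1,zero,eV,-6.5,-0.9,"), tmp)
  expect_error(read_energetics_table(tmp), "malformed value 'zero'")

  writeLines(c(header,
               "m1,F,w,78,0,1,0,eV,-6.5,-0.9,",
               "m1,F,w,78,0,1,0,eV,-6.5,-0.9,"), tmp)
  expect_error(read_energetics_table(tmp), "duplicate species row")

  writeLines(c(header, "m1,F,w,78,1,2,1.2,eV,,,"), tmp)
  expect_error(read_energetics_table(tmp), "no neutral")
})

test_that("energetics round-trip and hartree ingest conversion", {
  triads <- list(make_triad("m1", I = 6.2, A = 0.7),
                 make_triad("m2", I = 7.1, A = 1.4))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_energetics_table(triads, tmp)
  back <- read_energetics_table(tmp)
  expect_equal(back[["m1"]]$neutral$homo, -6.2)
  expect_equal(back[["m2"]]$anion$total_energy, -1.4)

  header <- paste("molecule_id,functional,solvent_name,solvent_dielectric",
                  "charge,multiplicity,total_energy,energy_unit,homo,lumo,somo",
                  sep = ",")
  writeLines(c(header, "m1,F,w,78,0,1,-0.5,hartree,-0.2438,-0.03,"), tmp)
  tr <- read_energetics_table(tmp)[["m1"]]
  expect_equal(tr$neutral$total_energy, -13.605693, tolerance = 1e-6)
  expect_equal(tr$neutral$homo, -6.634136, tolerance = 1e-6)
})

test_that("cube files round-trip through write and read", {
  triad <- gaussian_density_triad(c(0, 0, 0), widths = 1,
                                  electron_counts = c(1, 2, 3),
                                  grid_shape = 24L, grid_extent = 6)
  g <- triad$rho_n
  tmp <- withr::local_tempfile(fileext = ".cube")
  write_density_cube(g, tmp)
  back <- read_density_cube(tmp)
  expect_identical(back$shape, g$shape)
  expect_equal(back$origin, g$origin, tolerance = 1e-12)
  expect_equal(back$axes, g$axes, tolerance = 1e-12)
  # values preserved to the 6-significant-figure cube text precision
  expect_equal(back$values, g$values, tolerance = 1e-5)
  expect_equal(integrate_grid(back), 2, tolerance = 0.01)
})

test_that("degenerate and truncated cube files behave as specified", {
  g1 <- density_grid(c(0, 0, 0), diag(3), array(2.5, dim = c(1, 1, 1)))
  tmp <- withr::local_tempfile(fileext = ".cube")
  write_density_cube(g1, tmp)
  back <- read_density_cube(tmp)
  expect_identical(back$shape, c(1L, 1L, 1L))
  expect_equal(back$values[1, 1, 1], 2.5, tolerance = 1e-6)

  lines <- readLines(tmp)
  writeLines(lines[-length(lines)], tmp)  # drop the single data line
  expect_error(read_density_cube(tmp), "expected 1 values, found 0")
})
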