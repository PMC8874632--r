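#' Volumetric density grid
#'
#' A scalar field (electrons/Bohr^3) on a regular voxel grid, following the
#' Gaussian cube convention: an origin, three axis step vectors, and values
#' stored with the third (z) index varying fastest on disk. Lengths are in
#' Bohr throughout; no Angstrom-flag dialect is supported.
#'
#' @param origin Numeric length-3 grid origin (Bohr).
#' @param axes 3x3 numeric matrix whose rows are the voxel step vectors
#'   (Bohr); row i is the step along grid index i.
#' @param values Numeric 3D array, `dim = shape`, of non-negative densities
#'   (sign-indefinite fields such as Fukui differences are also carried in
#'   this container).
#' @param atoms Optional data frame with columns `z` (atomic number),
#'   `charge`, `x`, `y`, `z_coord` (Bohr); defaults to a single dummy atom
#'   at the origin, which cube viewers tolerate.
#' @param n_electrons_nominal Nominal electron count the grid should
#'   integrate to, or `NA`.
#' @return An object of class `density_grid`.
#' @export
density_grid <- function(origin, axes, values, atoms = NULL,
                         n_electrons_nominal = NA_real_) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L)
  axes <- matrix(as.numeric(axes), 3L, 3L)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array", call. = FALSE)
  }
  if (abs(det(axes)) <= 0) stop("voxel volume must be positive", call. = FALSE)
  if (is.null(atoms)) {
    atoms <- data.frame(z = 1L, charge = 0, x = origin[1L], y = origin[2L],
                        z_coord = origin[3L])
  }
  structure(
    list(origin = origin, axes = axes, shape = dim(values),
         values = values, atoms = atoms,
         n_electrons_nominal = as.numeric(n_electrons_nominal)),
    class = "density_grid"
  )
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %d x %d x %d voxels, voxel volume %.6g Bohr^3\n",
              x$shape[1L], x$shape[2L], x$shape[3L], voxel_volume(x)))
  cat(sprintf("  integral = %.6g e (nominal %s)\n", integrate_grid(x),
              fmt_or_na(x$n_electrons_nominal)))
  invisible(x)
}

#' Voxel volume of a density grid
#'
#' @param grid A [density_grid()].
#' @return Scalar volume `|det(axes)|` in Bohr^3.
#' @export
voxel_volume <- function(grid) {
  abs(det(grid$axes))
}

#' Integrate a grid by rectangle-rule quadrature
#'
#' The standard cube-file quadrature: sum of voxel values times the voxel
#' volume. For a density this is the electron count.
#'
#' @param grid A [density_grid()].
#' @return Scalar integral (electrons for a density grid).
#' @export
integrate_grid <- function(grid) {
  sum(grid$values) * voxel_volume(grid)
}

#' Read a Gaussian cube file
#'
#' Parses the fixed cube layout: two comment lines; a line with the atom
#' count and origin; three axis lines (voxel count + step vector, Bohr);
#' the atom block; then the volumetric data with the z index fastest.
#'
#' @param source Path to a cube file.
#' @return A [density_grid()].
#' @export
read_density_cube <- function(source) {
  lines <- readLines(source)
  if (length(lines) < 6L) stop("cube file too short", call. = FALSE)
  nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1L]])

  hdr <- nums(lines[3L])
  natoms <- as.integer(hdr[1L])
  if (is.na(natoms) || natoms < 0L) {
    stop("cube header: negative/invalid atom counts (Angstrom dialect) not supported",
         call. = FALSE)
  }
  origin <- hdr[2:4]
  shape <- integer(3L)
  axes <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    ax <- nums(lines[3L + i])
    shape[i] <- as.integer(ax[1L])
    axes[i, ] <- ax[2:4]
  }
  if (any(shape < 1L)) stop("cube axis counts must be positive", call. = FALSE)

  atom_lines <- if (natoms > 0L) lines[7:(6L + natoms)] else character()
  atoms <- if (natoms > 0L) {
    am <- t(vapply(atom_lines, nums, numeric(5L)))
    data.frame(z = as.integer(am[, 1L]), charge = am[, 2L],
               x = am[, 3L], y = am[, 4L], z_coord = am[, 5L])
  } else NULL

  data_start <- 7L + natoms
  data_lines <- if (data_start <= length(lines)) {
    lines[data_start:length(lines)]
  } else character()
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  vec <- as.numeric(unlist(strsplit(trimws(data_lines), "\\s+")))
  expected <- prod(shape)
  if (length(vec) != expected) {
    stop(sprintf("cube data block malformed: expected %d values, found %d",
                 expected, length(vec)), call. = FALSE)
  }
  # file order is x slowest, z fastest -> fill a (z, y, x) array, transpose
  values <- aperm(array(vec, dim = rev(shape)), c(3L, 2L, 1L))
  density_grid(origin, axes, values, atoms = atoms)
}

#' Write a density grid as a Gaussian cube file
#'
#' Values are written at 6 significant figures (`%13.5E`), six per line,
#' z index fastest, matching what quantum-chemistry codes emit. Reading the
#' file back reproduces origin, axes and shape exactly and values to the
#' printed precision.
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @param comment Character vector (length <= 2) of header comment lines.
#' @return `path`, invisibly.
#' @export
write_density_cube <- function(grid, path,
                               comment = c("density grid", "written by cdftpept")) {
  comment <- c(comment, "", "")[1:2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  f <- function(n, v) sprintf("%5d%12.6f%12.6f%12.6f", n, v[1L], v[2L], v[3L])
  writeLines(f(nrow(grid$atoms), grid$origin), con)
  for (i in 1:3) writeLines(f(grid$shape[i], grid$axes[i, ]), con)
  for (i in seq_len(nrow(grid$atoms))) {
    a <- grid$atoms[i, ]
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f",
                       a$z, a$charge, a$x, a$y, a$z_coord), con)
  }
  vec <- as.vector(aperm(grid$values, c(3L, 2L, 1L)))
  n <- length(vec)
  idx <- seq(1L, n, by = 6L)
  out <- vapply(idx, function(i) {
    paste(sprintf("%13.5E", vec[i:min(i + 5L, n)]), collapse = "")
  }, character(1L))
  writeLines(out, con)
  invisible(path)
}
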