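#' Construct a particle from atomic coordinates
#'
#' @param coords N x 3 numeric matrix of atom positions in Angstrom.
#' @param weights Per-atom scattering weights (default all 1).
#' @param particle_id Identifier string.
#' @return An object of class `speckle_particle`.
#' @export
particle <- function(coords, weights = NULL, particle_id = "particle") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || nrow(coords) < 1L || any(!is.finite(coords))) {
    stop("coords must be a finite N x 3 matrix with N >= 1")
  }
  if (is.null(weights)) weights <- rep(1, nrow(coords))
  if (length(weights) != nrow(coords) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    stop("weights must be positive, one per atom")
  }
  structure(list(coords = unname(coords), weights = as.numeric(weights),
                 particle_id = as.character(particle_id)),
            class = "speckle_particle")
}

#' Random toy particle
#'
#' Draws atoms uniformly inside a ball, a desk-scale stand-in for protein
#' coordinates. Deterministic for a fixed seed.
#'
#' @param n_atoms Number of atoms (>= 1).
#' @param radius_A Ball radius in Angstrom.
#' @param seed Integer seed.
#' @param particle_id Identifier string.
#' @return A `speckle_particle`.
#' @export
random_particle <- function(n_atoms, radius_A, seed = 1L,
                            particle_id = paste0("toy", seed)) {
  if (!is.numeric(n_atoms) || n_atoms < 1) stop("n_atoms must be >= 1")
  assert_positive(radius_A, "radius_A")
  n_atoms <- as.integer(n_atoms)
  coords <- with_seed(seed, {
    # isotropic directions, radius ~ r^(1/3) for uniformity in the ball
    v <- matrix(stats::rnorm(3L * n_atoms), n_atoms, 3L)
    v <- v / sqrt(rowSums(v * v))
    r <- radius_A * stats::runif(n_atoms)^(1 / 3)
    v * r
  })
  particle(coords, particle_id = particle_id)
}

#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM and HETATM records (first model of multi-model files) and
#' returns coordinates in Angstrom with unit scattering weights; occupancy,
#' B-factors and element types are ignored.
#'
#' @param path Path to a PDB file.
#' @return A `speckle_particle` whose `particle_id` is the file name.
#' @export
load_pdb_coordinates <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading PDB files requires the 'bio3d' package")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  atoms <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM/HETATM records in PDB file ", path)
  particle(as.matrix(atoms[, c("x", "y", "z")]),
           particle_id = basename(path))
}

# Uniform random unit quaternion (Shoemake); deterministic under with_seed.
random_quaternion <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

# Rotation matrix from a unit quaternion (w, x, y, z).
quat_to_matrix <- function(q) {
  if (abs(sum(q * q) - 1) > 1e-6) stop("quaternion must have unit norm")
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}
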