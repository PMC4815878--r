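# Shared fixtures, built once per test run. Sizes are kept small: the point
# of each fixture is statistical structure, not instrument realism.

# memoize expensive fixtures across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_geometry <- function() {
  detector_geometry(wavelength_nm = 2, distance_mm = 500, pixel_mm = 2,
                    n_fast = 48, n_slow = 48)
}

# sphere used in centering / simulation tests (~700 beads)
test_sphere <- function() fixture("test_sphere", function()
  make_shape("sphere", radius = 45, spacing = 5))

# small dumbbell for oracle tests
test_dumbbell <- function() fixture("test_dumbbell", function()
  make_shape("dumbbell", radius = 5, separation = 10, spacing = 0.8))

# analytic solid-sphere curve, normalized to 1 at q = 0
analytic_sphere <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# volume-equivalent radius of a lattice bead model: the discretized solid
# occupies n * spacing^3, so this is the radius the analytic curve should be
# compared at
volume_radius <- function(model, spacing) {
  spacing * (3 * n_beads(model) / (4 * pi))^(1 / 3)
}

# 3-atom toy PDB fixture (coordinates in Angstrom)
toy_pdb_file <- function() {
  path <- file.path(tempdir(), "toy3.pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      10.000  20.000  30.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.500  20.000  30.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.000  21.400  30.500  1.00  0.00           C",
    "END"), path)
  path
}
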