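# Fixtures are generated in code; expensive ones are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, expr, envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# regular tetrahedron-ish closed mesh: 4 vertices, 4 faces, outward winding
tetrahedron <- function() {
  trimesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
          rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)))
}

# axis-aligned unit cube, 12 triangles, outward winding
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  trimesh(v, f)
}

# rigid rotation matrix about an arbitrary axis
rotation_matrix <- function(axis = c(1, 2, 3), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

transform_mesh <- function(mesh, scale = 1, shift = c(0, 0, 0),
                           rotate = FALSE) {
  v <- mesh$vertices * scale
  if (rotate) v <- v %*% t(rotation_matrix())
  mesh$vertices <- sweep(v, 2L, shift, `+`)
  mesh
}

# default 209-cell synthetic population and its feature table
default_population_table <- function() {
  cached("default_tab", {
    pop <- simulate_population(population_spec(seed = 1))
    build_feature_table(pop)
  })
}

# clearly separated two-class population (volume contrast 27x, low noise)
separable_table <- function() {
  cached("separable_tab", {
    pop <- simulate_population(population_spec(
      volume_factor = 27, kind_b = "ellipsoid", noise = 0.02,
      subdivisions = 2, seed = 11))
    build_feature_table(pop)
  })
}

# weak-signal imbalanced population (same shape family, 15% volume shift)
weak_signal_table <- function() {
  cached("weak_tab", {
    pop <- simulate_population(population_spec(
      volume_factor = 1.15, kind_b = "ellipsoid",
      subdivisions = 2, seed = 5))
    build_feature_table(pop)
  })
}

# random binary outcome matrix with a fixed seed
random_binary_matrix <- function(n = 209, runs = 100, seed = 42) {
  set.seed(seed)
  matrix(rbinom(n * runs, 1L, runif(n)), n, runs)
}

random_labels <- function(n = 209, n_pos = 51, seed = 42) {
  set.seed(seed)
  sample(c(rep(1L, n_pos), rep(-1L, n - n_pos)))
}
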