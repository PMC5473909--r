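#' Generate an analytic test shape
#'
#' Deterministic mesh generators for the shape families used to exercise and
#' validate the morphometric pipeline: closed surfaces (icosphere, ellipsoid,
#' torus, hooked cap) and open patches (plane, cylinder wall) whose curvature
#' is known in closed form.  An optional smooth random radial "bump" field
#' perturbs the closed shapes while keeping them valid.
#'
#' @param kind one of `"icosphere"`, `"ellipsoid"`, `"torus"`,
#'   `"plane_patch"`, `"cylinder_patch"`, `"hooked_cap"`.
#' @param radius sphere radius / plane half-width / cylinder radius.
#' @param semi_axes length-3 vector of ellipsoid semi-axes.
#' @param ring_radius,tube_radius torus major/minor radii.
#' @param arc_radius,arc_angle,cap_radius,flatten hooked-cap geometry: the
#'   cap is a flattened capsule (elliptical cross-section of in-plane
#'   semi-axis `cap_radius` and out-of-plane semi-axis `flatten *
#'   cap_radius`) swept along a circular arc of radius `arc_radius` spanning
#'   `arc_angle` radians, with rounded closed ends — a closed genus-0
#'   "hairpin" shell.
#' @param subdivisions icosphere subdivision level (0 = icosahedron).
#' @param n_u,n_v grid resolution for swept/gridded shapes.
#' @param height cylinder patch height.
#' @param noise bump-noise amplitude as a fraction of the shape scale,
#'   in \[0, 0.3\]: vertices are displaced radially from the centroid by a
#'   smooth low-order spherical-harmonic random field of that relative
#'   amplitude.
#' @param seed integer seed controlling the bump field (ignored when
#'   `noise = 0`); generation is bitwise-reproducible given the same
#'   arguments.
#' @return a [trimesh()]; closed for the closed kinds (validated), open for
#'   the patch kinds.
#' @examples
#' s <- make_shape("icosphere", radius = 1, subdivisions = 3)
#' sphericity(s)
#' @export
make_shape <- function(kind = c("icosphere", "ellipsoid", "torus",
                                "plane_patch", "cylinder_patch",
                                "hooked_cap"),
                       radius = 1, semi_axes = c(2, 1, 1),
                       ring_radius = 2, tube_radius = 1,
                       arc_radius = 2, arc_angle = 4,
                       cap_radius = 1.3, flatten = 0.7,
                       subdivisions = 3, n_u = 48, n_v = 24,
                       height = 2, noise = 0, seed = 1L) {
  kind <- match.arg(kind)
  if (noise < 0 || noise > 0.3)
    stop("'noise' must lie in [0, 0.3]")
  if (any(c(radius, semi_axes, ring_radius, tube_radius, arc_radius,
            cap_radius, height) <= 0))
    stop("all size parameters must be positive")
  m <- switch(kind,
    icosphere = icosphere(radius, subdivisions),
    ellipsoid = {
      s <- icosphere(1, subdivisions)
      s$vertices <- s$vertices * rep(semi_axes, each = nrow(s$vertices))
      s
    },
    torus = torus_mesh(ring_radius, tube_radius, n_u, n_v),
    plane_patch = plane_patch(radius, n_u),
    cylinder_patch = cylinder_patch(radius, height, n_u, n_v),
    hooked_cap = hooked_cap(arc_radius, arc_angle, cap_radius,
                            flatten, n_u, n_v))
  if (noise > 0)
    m <- add_bump_noise(m, noise, seed)
  m
}

## ---- icosphere ------------------------------------------------------------

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
             c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(v = v, f = f)
}

icosphere <- function(radius = 1, subdivisions = 3) {
  ico <- icosahedron()
  v <- ico$v; f <- ico$f
  for (lvl in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint index cache keyed by undirected edge
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(f[, 1L], f[, 2L])
    e2 <- key(f[, 2L], f[, 3L])
    e3 <- key(f[, 3L], f[, 1L])
    ukeys <- unique(c(e1, e2, e3))
    mid_of <- function(k) nv + match(k, ukeys)
    lo <- (ukeys %/% (nv + 1)); hi <- ukeys %% (nv + 1)
    mids <- (v[lo, , drop = FALSE] + v[hi, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    a <- f[, 1L]; b <- f[, 2L]; cc <- f[, 3L]
    ab <- mid_of(e1); bc <- mid_of(e2); ca <- mid_of(e3)
    f <- rbind(cbind(a, ab, ca), cbind(b, bc, ab),
               cbind(cc, ca, bc), cbind(ab, bc, ca))
  }
  trimesh(v * radius, f)
}

## ---- gridded surfaces -----------------------------------------------------

# index into an n_u x n_v grid (1-based), with optional wrap in u and v
grid_idx <- function(i, j, n_u, n_v, wrap_u, wrap_v) {
  if (wrap_u) i <- (i - 1L) %% n_u + 1L
  if (wrap_v) j <- (j - 1L) %% n_v + 1L
  (j - 1L) * n_u + i
}

# two triangles per quad over an n_u x n_v grid of vertices
grid_faces <- function(n_u, n_v, wrap_u = FALSE, wrap_v = FALSE) {
  iu <- seq_len(if (wrap_u) n_u else n_u - 1L)
  iv <- seq_len(if (wrap_v) n_v else n_v - 1L)
  g <- expand.grid(i = iu, j = iv)
  a <- grid_idx(g$i,      g$j,      n_u, n_v, wrap_u, wrap_v)
  b <- grid_idx(g$i + 1L, g$j,      n_u, n_v, wrap_u, wrap_v)
  cc <- grid_idx(g$i + 1L, g$j + 1L, n_u, n_v, wrap_u, wrap_v)
  d <- grid_idx(g$i,      g$j + 1L, n_u, n_v, wrap_u, wrap_v)
  rbind(cbind(a, b, cc), cbind(a, cc, d))
}

torus_mesh <- function(R = 2, r = 1, n_u = 48, n_v = 24) {
  if (r >= R) stop("torus requires tube_radius < ring_radius")
  u <- 2 * pi * (seq_len(n_u) - 1L) / n_u   # around the ring
  v <- 2 * pi * (seq_len(n_v) - 1L) / n_v   # around the tube
  g <- expand.grid(u = u, v = v)
  x <- (R + r * cos(g$v)) * cos(g$u)
  y <- (R + r * cos(g$v)) * sin(g$u)
  z <- r * sin(g$v)
  trimesh(cbind(x, y, z), grid_faces(n_u, n_v, TRUE, TRUE))
}

plane_patch <- function(half_width = 1, n = 24) {
  s <- seq(-half_width, half_width, length.out = n)
  g <- expand.grid(x = s, y = s)
  trimesh(cbind(g$x, g$y, 0), grid_faces(n, n))
}

cylinder_patch <- function(radius = 1, height = 2, n_u = 48, n_v = 16) {
  u <- 2 * pi * (seq_len(n_u) - 1L) / n_u
  z <- seq(0, height, length.out = n_v)
  g <- expand.grid(u = u, z = z)
  trimesh(cbind(radius * cos(g$u), radius * sin(g$u), g$z),
          grid_faces(n_u, n_v, wrap_u = TRUE))
}

# saddle patch z = (x^2 - y^2)/2: negative Gaussian curvature fixture
saddle_patch <- function(half_width = 1, n = 24) {
  s <- seq(-half_width, half_width, length.out = n)
  g <- expand.grid(x = s, y = s)
  trimesh(cbind(g$x, g$y, (g$x^2 - g$y^2) / 2), grid_faces(n, n))
}

## ---- hooked cap -----------------------------------------------------------

# Flattened capsule swept along a circular arc: centerline on a circle of
# radius R_a in the xz-plane, elliptical cross-section (rho in-plane,
# flatten*rho out-of-plane) shrinking to rounded poles at both ends.
hooked_cap <- function(arc_radius = 2, arc_angle = 4, cap_radius = 1.3,
                       flatten = 0.7, n_u = 48, n_v = 24) {
  if (arc_angle <= 0 || arc_angle >= 2 * pi)
    stop("'arc_angle' must lie in (0, 2*pi)")
  tpar <- seq(0, 1, length.out = n_u + 1L)          # along the arc
  u <- arc_angle * tpar
  rho <- cap_radius * sqrt(pmax(4 * tpar * (1 - tpar), 0))  # rounded ends
  interior <- 2:n_u                                  # rho > 0 rings
  vang <- 2 * pi * (seq_len(n_v) - 1L) / n_v
  verts <- matrix(0, nrow = length(interior) * n_v + 2L, ncol = 3L)
  ring_id <- function(k, j) (k - 1L) * n_v + j      # k-th interior ring
  for (k in seq_along(interior)) {
    i <- interior[k]
    cu <- cos(u[i]); su <- sin(u[i])
    center <- arc_radius * c(cu, 0, su)
    nrm <- c(cu, 0, su)                              # in-plane normal
    bin <- c(0, 1, 0)                                # out-of-plane
    for (j in seq_len(n_v)) {
      verts[ring_id(k, j), ] <- center +
        rho[i] * cos(vang[j]) * nrm +
        flatten * rho[i] * sin(vang[j]) * bin
    }
  }
  p0 <- length(interior) * n_v + 1L                  # start pole
  p1 <- p0 + 1L                                      # end pole
  verts[p0, ] <- arc_radius * c(cos(u[1L]), 0, sin(u[1L]))
  verts[p1, ] <- arc_radius * c(cos(u[n_u + 1L]), 0, sin(u[n_u + 1L]))
  faces <- list()
  for (k in seq_len(length(interior) - 1L)) {
    j <- seq_len(n_v); jn <- j %% n_v + 1L
    a <- ring_id(k, j); b <- ring_id(k + 1L, j)
    cc <- ring_id(k + 1L, jn); d <- ring_id(k, jn)
    faces[[length(faces) + 1L]] <- cbind(a, b, cc)
    faces[[length(faces) + 1L]] <- cbind(a, cc, d)
  }
  j <- seq_len(n_v); jn <- j %% n_v + 1L
  faces[[length(faces) + 1L]] <- cbind(p0, ring_id(1L, j), ring_id(1L, jn))
  kl <- length(interior)
  faces[[length(faces) + 1L]] <- cbind(p1, ring_id(kl, jn), ring_id(kl, j))
  m <- trimesh(verts, do.call(rbind, faces))
  if (signed_volume(m) < 0) m$faces <- m$faces[, c(1L, 3L, 2L)]
  m
}

## ---- bump noise -----------------------------------------------------------

# real spherical harmonics up to degree 3 evaluated at unit directions
# (rows of `d`); returns a matrix with one column per harmonic
real_sph_harm <- function(d) {
  x <- d[, 1L]; y <- d[, 2L]; z <- d[, 3L]
  cbind(x, y, z,
        x * y, y * z, x * z, x^2 - y^2, 3 * z^2 - 1,
        (5 * z^2 - 1) * x, (5 * z^2 - 1) * y, z * (5 * z^2 - 3),
        x * y * z, z * (x^2 - y^2), x * (x^2 - 3 * y^2),
        y * (3 * x^2 - y^2))
}

# smooth radial displacement: v -> v * (1 + f(dir)), max|f| = amplitude
add_bump_noise <- function(mesh, amplitude, seed) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  rel <- sweep(v, 2L, ctr)
  r <- sqrt(rowSums(rel^2))
  d <- rel / pmax(r, .Machine$double.xmin)
  basis <- real_sph_harm(d)
  coef <- with_local_seed(as.integer(seed), stats::rnorm(ncol(basis)))
  f <- drop(basis %*% coef)
  fmax <- max(abs(f))
  if (fmax > 0) f <- f / fmax * amplitude
  mesh$vertices <- sweep(rel * (1 + f), 2L, ctr, `+`)
  mesh
}
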