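test_that("sphere curvature matches 1/R for both estimators", {
  for (meth in c("deficit", "quadric")) {
    s <- make_shape("icosphere", radius = 2, subdivisions = 4)
    fld <- curvature_field(s, method = meth)
    # node averages: a sphere has k1 = k2 = 1/R everywhere
    expect_equal(surface_average(fld$M), 0.5, tolerance = 0.02)
    expect_equal(surface_average(fld$G), 0.25, tolerance = 0.02)
    expect_lt(relative_fluctuation(fld$M), 0.05)
    expect_true(all(fld$k1 <= fld$k2 + 1e-12))
  }
  # quadric is pointwise accurate at every vertex
  fq <- curvature_field(make_shape("icosphere", radius = 2,
                                   subdivisions = 4),
                        method = "quadric")
  expect_true(all(abs(fq$k1 - 0.5) < 0.01))
  expect_true(all(abs(fq$k2 - 0.5) < 0.01))
})

test_that("flat patch interiors have zero curvature", {
  p <- make_shape("plane_patch", radius = 1, n_u = 20)
  expect_error(curvature_field(p), "not closed")
  fld <- curvature_field(p, allow_open = TRUE)
  ii <- fld$interior
  expect_true(any(ii))
  expect_lt(max(abs(fld$G[ii])), 1e-6)
  expect_lt(max(abs(fld$M[ii])), 1e-6)
  expect_true(all(is.na(fld$G[!ii])))
})

test_that("cylinder wall gives principal curvatures {0, 1/r}", {
  r <- 0.7
  cy <- make_shape("cylinder_patch", radius = r, height = 3,
                   n_u = 64, n_v = 24)
  fld <- curvature_field(cy, allow_open = TRUE)
  ii <- fld$interior
  expect_true(all(abs(fld$k1[ii]) < 0.03 / r))
  expect_equal(unname(fld$k2[ii]), rep(1 / r, sum(ii)),
               tolerance = 0.03)
  expect_equal(surface_average(fld$M[ii]), 1 / (2 * r), tolerance = 0.03)
})

test_that("saddle interiors have negative Gaussian curvature", {
  sad <- acroshape:::saddle_patch(1, 24)
  fld <- curvature_field(sad, allow_open = TRUE)
  expect_true(all(fld$G[fld$interior] < 0))
})

test_that("Gauss-Bonnet totals equal 2*pi*chi for the deficit estimator", {
  genus0 <- list(make_shape("icosphere", subdivisions = 3),
                 make_shape("ellipsoid", semi_axes = c(2, 1, 0.7)),
                 make_shape("hooked_cap"),
                 make_shape("icosphere", subdivisions = 3,
                            noise = 0.15, seed = 4))
  for (m in genus0)
    expect_equal(total_gaussian_curvature(curvature_field(m)), 4 * pi,
                 tolerance = 1e-8)
  tor <- make_shape("torus", n_u = 48, n_v = 24)
  expect_lt(abs(total_gaussian_curvature(curvature_field(tor))), 1e-8)
})

test_that("curvature accessors recombine the principal curvatures", {
  m <- make_shape("ellipsoid", semi_axes = c(1.5, 1, 0.8),
                  subdivisions = 3)
  fld <- curvature_field(m)
  expect_equal(mean_curvature(fld), (fld$k1 + fld$k2) / 2,
               tolerance = 1e-12)
  # G agrees with k1*k2 wherever the sqrt was not clamped
  free <- abs(fld$M^2 - fld$G) > 0 & fld$M^2 >= fld$G
  expect_equal(gaussian_curvature(fld)[free], fld$G[free],
               tolerance = 1e-9)
  # convex closed bodies: positive average curvatures, sign coherence
  expect_gt(surface_average(fld$M), 0)
  expect_gt(surface_average(fld$G), 0)
  expect_gt(surface_average(curvature_field(unit_cube())$M), 0)
})

test_that("node averages and fluctuations follow their definitions", {
  expect_equal(surface_average(c(1, 2, 3)), 2)
  expect_equal(surface_average(rep(3.7, 50)), 3.7)
  expect_equal(surface_average(c(1, 2, NA)), 1.5)   # boundary NAs dropped
  expect_equal(surface_average(c(1, 3), weights = c(3, 1)), 1.5)
  expect_error(surface_average(numeric()), "no values")

  expect_equal(relative_fluctuation(c(1, 3)), sqrt(2) / 2)
  expect_equal(relative_fluctuation(rep(2, 10)), 0)
  expect_error(relative_fluctuation(1), "two values")
  expect_error(relative_fluctuation(c(-1, 1)), "zero mean")
})

test_that("the 7-feature vector matches unit-sphere closed forms", {
  s <- make_shape("icosphere", radius = 1, subdivisions = 4)
  f <- extract_features(s)
  expect_named(f, c("V", "Sigma", "Psi", "Mbar", "Gbar", "dMrel", "dGrel"))
  expect_equal(unname(f["V"]), 4 * pi / 3, tolerance = 0.01)
  expect_equal(unname(f["Sigma"]), 4 * pi, tolerance = 0.005)
  expect_equal(unname(f["Psi"]), 1, tolerance = 1e-3)
  expect_equal(unname(f["Mbar"]), 1, tolerance = 0.02)
  expect_equal(unname(f["Gbar"]), 1, tolerance = 0.02)
  expect_lt(f["dMrel"], 0.05)
  expect_lt(f["dGrel"], 0.05)
})

test_that("features transform correctly under uniform scaling", {
  m <- make_shape("ellipsoid", semi_axes = c(1.6, 1, 1),
                  subdivisions = 3, noise = 0.05, seed = 2)
  f1 <- extract_features(m)
  f2 <- extract_features(transform_mesh(m, scale = 2))
  expect_equal(unname(f2["V"]), unname(8 * f1["V"]), tolerance = 1e-9)
  expect_equal(unname(f2["Sigma"]), unname(4 * f1["Sigma"]),
               tolerance = 1e-9)
  expect_equal(unname(f2["Psi"]), unname(f1["Psi"]), tolerance = 1e-9)
  expect_equal(unname(f2["Mbar"]), unname(f1["Mbar"] / 2),
               tolerance = 1e-9)
  expect_equal(unname(f2["Gbar"]), unname(f1["Gbar"] / 4),
               tolerance = 1e-9)
  expect_equal(unname(f2["dMrel"]), unname(f1["dMrel"]), tolerance = 1e-9)
  expect_equal(unname(f2["dGrel"]), unname(f1["dGrel"]), tolerance = 1e-9)
  # a prolate ellipsoid is less spherical than a sphere
  expect_lt(f1["Psi"], 1)
})
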