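# independent empirical-CDF oracle for the two-sample KS statistic
brute_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(vapply(pts, function(t) abs(mean(x <= t) - mean(y <= t)), 0))
}

make_table <- function(feats, labels, ids = NULL) {
  # assemble a feature_table directly from a numeric matrix
  tab <- data.frame(id = ids %||% sprintf("c%d", seq_len(nrow(feats))),
                    label = as.integer(labels), feats)
  names(tab)[-(1:2)] <- c("V", "Sigma", "Psi", "Mbar", "Gbar",
                          "dMrel", "dGrel")
  class(tab) <- c("feature_table", "data.frame")
  attr(tab, "space") <- "linear"
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("feature tables preserve input order and validate labels", {
  meshes <- lapply(c(0.8, 1, 1.3), function(r)
    make_shape("icosphere", radius = r, subdivisions = 1))
  tab <- build_feature_table(meshes, labels = c(-1, -1, 1))
  expect_s3_class(tab, "feature_table")
  expect_equal(nrow(tab), 3L)
  expect_equal(names(tab), c("id", "label", "V", "Sigma", "Psi",
                             "Mbar", "Gbar", "dMrel", "dGrel"))
  expect_true(all(diff(tab$V) > 0))        # row order follows input order
  expect_false(anyNA(tab))
  expect_error(build_feature_table(list(), integer()), "no meshes")
  expect_error(build_feature_table(meshes, c(0, 1, 2)), "coded")
  # an invalid mesh is reported with its cell id
  open <- meshes[[1L]]
  open$faces <- open$faces[-1L, , drop = FALSE]
  expect_error(build_feature_table(list(meshes[[2L]], open), c(-1, 1),
                                   ids = c("ok", "broken")), "broken")
})

test_that("class means follow their definition and concatenation identity", {
  f <- matrix(rep(c(1, 2), each = 2, times = 7), 4, 7)
  tab <- make_table(f, c(-1, -1, 1, 1))
  cm <- class_means(tab)
  expect_equal(unname(cm$means["class_A", ]), rep(1, 7))
  expect_equal(unname(cm$means["class_B", ]), rep(2, 7))
  expect_equal(unname(cm$n), c(2L, 2L))
  # concatenating a population with itself leaves the means unchanged
  tab2 <- rbind(tab, tab)
  class(tab2) <- class(tab); attr(tab2, "space") <- "linear"
  expect_equal(class_means(tab2)$means, cm$means)
  expect_error(class_means(make_table(f, rep(-1, 4))), "both classes")
})

test_that("KS statistic matches the brute-force empirical-CDF oracle", {
  set.seed(1)
  # worked example: {1,2,3,4} vs {3,4,5,6} has D = 0.5
  expect_equal(brute_ks_D(1:4, 3:6), 0.5)
  tab <- make_table(cbind(c(1:4, 3:6), matrix(rnorm(48), 8, 6)),
                    c(rep(-1, 4), rep(1, 4)))
  res <- ks_compare(tab, "V")
  expect_s3_class(res, "ks_result")
  expect_equal(res$D, 0.5)
  expect_equal(res$n_a, 4L)
  # identical samples: D = 0; disjoint supports: D = 1
  tab0 <- make_table(cbind(rep(1:3, 2), matrix(rnorm(36), 6, 6)),
                     c(rep(-1, 3), rep(1, 3)))
  expect_equal(ks_compare(tab0, "V")$D, 0)
  tabd <- make_table(cbind(c(0, 1, 10, 11), matrix(rnorm(24), 4, 6)),
                     c(-1, -1, 1, 1))
  expect_equal(ks_compare(tabd, "V")$D, 1)
  # random-sample property check against the oracle
  for (k in 1:5) {
    x <- rlnorm(20); y <- rlnorm(15, meanlog = 0.5)
    tabr <- make_table(cbind(c(x, y), matrix(rnorm(35 * 6), 35, 6)),
                       c(rep(-1, 20), rep(1, 15)))
    expect_equal(ks_compare(tabr, "V")$D, brute_ks_D(x, y),
                 tolerance = 1e-12)
  }
})

test_that("KS statistic is invariant under common monotone transforms", {
  set.seed(2)
  x <- rlnorm(30); y <- rlnorm(20, meanlog = 0.4)
  feats <- cbind(c(x, y), matrix(abs(rnorm(50 * 6)) + 0.1, 50, 6))
  tab <- make_table(feats, c(rep(-1, 30), rep(1, 20)))
  d_lin <- ks_compare(tab, "V")$D
  d_log <- ks_compare(log_transform(tab), "V")$D
  expect_equal(d_lin, d_log, tolerance = 1e-12)
})

test_that("log transform is column-wise, explicit about bad values", {
  f <- matrix(exp(1:28), 4, 7)
  tab <- make_table(f, c(-1, -1, 1, 1))
  lt <- log_transform(tab)
  expect_equal(unname(as.matrix(lt[, -(1:2)])), matrix(1:28, 4, 7))
  expect_identical(attr(lt, "space"), "log")
  expect_identical(lt$label, tab$label)
  expect_error(log_transform(lt), "already")
  # a negative value names the offending cell and feature
  f2 <- f; f2[2, 5] <- -0.1
  tab2 <- make_table(f2, c(-1, -1, 1, 1))
  expect_error(log_transform(tab2), "c2/Gbar")
  # the signed fallback must be requested explicitly and is asinh-based
  lt2 <- log_transform(tab2, signed_fallback = TRUE)
  expect_equal(lt2$Gbar[2], asinh(-0.05))
})

test_that("surface-volume scaling recovers the 2/3 law", {
  # spheres of radii 1, 2, 4
  spheres <- lapply(c(1, 2, 4), function(r)
    make_shape("icosphere", radius = r, subdivisions = 3))
  tab <- build_feature_table(spheres, labels = c(-1, -1, 1))
  fit <- fit_scaling_exponent(tab)
  expect_equal(fit$slope, 2 / 3, tolerance = 1e-3)
  # cubes of sides 1, 2, 3: exact similar-shape scaling
  cubes <- lapply(1:3, function(s) transform_mesh(unit_cube(), scale = s))
  fitc <- fit_scaling_exponent(build_feature_table(cubes,
                                                   labels = c(-1, -1, 1)))
  expect_equal(fitc$slope, 2 / 3, tolerance = 1e-9)
  # two-point slope is exactly log(4)/log(8)
  tab2 <- make_table(cbind(c(1, 8), c(6, 24), matrix(1, 2, 5)), c(-1, 1))
  expect_equal(fit_scaling_exponent(tab2)$slope, log(4) / log(8))
  # geometrically similar noisy-seeded shapes of varying scale: 2/3 +- 0.02
  base <- make_shape("hooked_cap", n_u = 24, n_v = 12)
  fam <- lapply(seq(0.5, 3, length.out = 8), function(s)
    transform_mesh(base, scale = s))
  fitf <- fit_scaling_exponent(
    build_feature_table(fam, labels = c(rep(-1, 4), rep(1, 4))))
  expect_equal(fitf$slope, 2 / 3, tolerance = 0.02)
  # degenerate input
  tabk <- make_table(cbind(rep(2, 3), 1:3, matrix(1, 3, 5)),
                     c(-1, 1, 1))
  expect_error(fit_scaling_exponent(tabk), "constant")
})
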