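#' Specify a synthetic two-class shape population
#'
#' Describes the generative model behind [simulate_population()]: two
#' subpopulations of closed shapes emulating the morphological contrast
#' between round spermatid acrosomes (class A, label -1) and hooked
#' spermatozoon acrosomes (class B, label +1).  Per-cell volumes are drawn
#' log-normally and each mesh is rescaled to its drawn volume, so the
#' class-B/class-A mean-volume ratio is controlled exactly by
#' `volume_factor` in expectation (default 1.5, i.e. class B ~50% larger).
#' Class A shapes are mildly elongated noisy ellipsoids; class B defaults to
#' hooked caps, which also have lower sphericity and lower, more
#' heterogeneous curvature.
#'
#' @param n_a,n_b class sizes (defaults 158 and 51).
#' @param volume_factor ratio of class-B to class-A mean volume.
#' @param mean_volume class-A mean volume (length^3; microns^3 for
#'   acrosome-scale data).
#' @param sdlog_volume log-scale SD of per-cell volumes (both classes).
#' @param kind_a,kind_b shape family per class (`"ellipsoid"` or
#'   `"hooked_cap"`).
#' @param elongation_a range of the class-A ellipsoid long-axis ratio,
#'   sampled uniformly.
#' @param arc_angle_b range of the class-B hooked-cap sweep angle
#'   (radians), sampled uniformly.
#' @param noise bump-noise amplitude passed to [make_shape()].
#' @param subdivisions,n_u,n_v mesh resolution.
#' @param seed master seed; per-mesh child seeds are spawned from it by
#'   counter, so any subset is reproducible.
#' @return a list of class `population_spec`.
#' @export
population_spec <- function(n_a = 158, n_b = 51, volume_factor = 1.5,
                            mean_volume = 60, sdlog_volume = 0.25,
                            kind_a = "ellipsoid", kind_b = "hooked_cap",
                            elongation_a = c(1, 1.4),
                            arc_angle_b = c(3.4, 4.6),
                            noise = 0.08, subdivisions = 3,
                            n_u = 40, n_v = 20, seed = 1L) {
  if (n_a < 2 || n_b < 2) stop("need at least 2 cells per class")
  if (volume_factor <= 0 || mean_volume <= 0 || sdlog_volume < 0)
    stop("volume parameters must be positive")
  structure(list(n_a = n_a, n_b = n_b, volume_factor = volume_factor,
                 mean_volume = mean_volume, sdlog_volume = sdlog_volume,
                 kind_a = kind_a, kind_b = kind_b,
                 elongation_a = elongation_a, arc_angle_b = arc_angle_b,
                 noise = noise, subdivisions = subdivisions,
                 n_u = n_u, n_v = n_v, seed = as.integer(seed)),
            class = "population_spec")
}

# one synthetic cell: build base shape, then rescale to the target volume
simulate_cell <- function(kind, target_volume, shape_par, noise,
                          subdivisions, n_u, n_v, seed) {
  m <- switch(kind,
    ellipsoid = make_shape("ellipsoid",
                           semi_axes = c(shape_par, 1, 1),
                           subdivisions = subdivisions,
                           noise = noise, seed = seed),
    hooked_cap = make_shape("hooked_cap", arc_angle = shape_par,
                            n_u = n_u, n_v = n_v,
                            noise = noise, seed = seed),
    stop("unsupported population shape kind: ", kind))
  s <- (target_volume / mesh_volume(m))^(1 / 3)
  m$vertices <- m$vertices * s
  m
}

#' Simulate a two-class population of shapes
#'
#' Draws the population described by a [population_spec()]: class A first
#' (rows 1..n_a, label -1), then class B (label +1).  Fully reproducible
#' from the master seed; the same spec and seed give bitwise-identical
#' vertex arrays.
#'
#' @param spec a [population_spec()].
#' @return a list of class `shape_population` with `meshes` (list of
#'   [trimesh()]), `labels` (-1/+1 integer vector) and `manifest`
#'   (data frame: id, label, kind, shape parameter, target volume, seed).
#' @examples
#' pop <- simulate_population(population_spec(n_a = 3, n_b = 2,
#'                                            subdivisions = 2))
#' table(pop$labels)
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_a + spec$n_b
  seeds <- child_seeds(spec$seed, 3L * n)
  labels <- c(rep(-1L, spec$n_a), rep(1L, spec$n_b))
  mu_a <- log(spec$mean_volume) - spec$sdlog_volume^2 / 2
  mu_b <- mu_a + log(spec$volume_factor)
  meshes <- vector("list", n)
  manifest <- data.frame(id = sprintf("cell_%03d", seq_len(n)),
                         label = labels, kind = "", shape_par = 0,
                         target_volume = 0, seed = 0L,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    is_b <- labels[i] > 0
    kind <- if (is_b) spec$kind_b else spec$kind_a
    vol <- with_local_seed(seeds[i],
                           stats::rlnorm(1, if (is_b) mu_b else mu_a,
                                         spec$sdlog_volume))
    par_rng <- if (kind == "hooked_cap") spec$arc_angle_b
               else spec$elongation_a
    shape_par <- with_local_seed(seeds[n + i],
                                 stats::runif(1, par_rng[1L], par_rng[2L]))
    meshes[[i]] <- simulate_cell(kind, vol, shape_par, spec$noise,
                                 spec$subdivisions, spec$n_u, spec$n_v,
                                 seeds[2L * n + i])
    manifest$kind[i] <- kind
    manifest$shape_par[i] <- shape_par
    manifest$target_volume[i] <- vol
    manifest$seed[i] <- seeds[2L * n + i]
  }
  structure(list(meshes = meshes, labels = labels, manifest = manifest),
            class = "shape_population")
}

#' @export
print.shape_population <- function(x, ...) {
  cat(sprintf("shape population: %d cells (%d / %d per class)\n",
              length(x$meshes), sum(x$labels < 0), sum(x$labels > 0)))
  invisible(x)
}

#' Assemble a labeled feature table from meshes
#'
#' Runs [extract_features()] over a list of meshes and binds the results
#' into a labeled table, the input of the statistical and classification
#' stages.  Row order preserves input order.  Column order is fixed and
#' documented: `V, Sigma, Psi, Mbar, Gbar, dMrel, dGrel`.
#'
#' @param meshes list of closed [trimesh()] objects, or a
#'   `shape_population` (in which case `labels` is taken from it).
#' @param labels vector of class labels coded -1 (class A, "spermatid")
#'   and +1 (class B, "spermatozoon").
#' @param ids optional cell identifiers (default `cell_001`, ...).
#' @param method curvature estimator for [extract_features()].
#' @return a data frame of class `feature_table` with columns `id`,
#'   `label` and the 7 features; attribute `space = "linear"`.
#' @export
build_feature_table <- function(meshes, labels = NULL, ids = NULL,
                                method = "deficit") {
  if (inherits(meshes, "shape_population")) {
    if (is.null(labels)) labels <- meshes$labels
    if (is.null(ids)) ids <- meshes$manifest$id
    meshes <- meshes$meshes
  }
  if (!length(meshes)) stop("no meshes supplied")
  if (length(labels) != length(meshes))
    stop("'labels' must match the number of meshes")
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be coded -1 (class A) / +1 (class B)")
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(meshes))
  feats <- matrix(NA_real_, length(meshes), 7L,
                  dimnames = list(NULL, feature_names()))
  for (i in seq_along(meshes)) {
    feats[i, ] <- tryCatch(extract_features(meshes[[i]], method = method),
                           error = function(e)
                             stop("feature extraction failed for cell '",
                                  ids[i], "': ", conditionMessage(e),
                                  call. = FALSE))
  }
  tab <- data.frame(id = ids, label = as.integer(labels), feats,
                    stringsAsFactors = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  attr(tab, "space") <- "linear"
  tab
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_names(), drop = FALSE])
}

#' Per-class feature means
#'
#' Arithmetic mean of each of the 7 features within each class, with class
#' sizes — the population-level summary contrasted between spermatids and
#' spermatozoa.
#'
#' @param table a [build_feature_table()] result with both classes present.
#' @return a list with `means` (2 x 7 matrix, rows `class_A`/`class_B`)
#'   and `n` (class sizes).
#' @export
class_means <- function(table) {
  check_two_classes(table)
  x <- feature_matrix(table)
  ia <- table$label < 0
  means <- rbind(class_A = colMeans(x[ia, , drop = FALSE]),
                 class_B = colMeans(x[!ia, , drop = FALSE]))
  list(means = means, n = c(class_A = sum(ia), class_B = sum(!ia)))
}

check_two_classes <- function(table) {
  if (!all(c(-1, 1) %in% table$label))
    stop("both classes must be present")
  invisible(table)
}

#' Two-sample Kolmogorov-Smirnov comparison of one feature
#'
#' Compares the two class distributions of a feature with the two-sided
#' two-sample KS statistic `D = sup |F_A - F_B|` and its asymptotic
#' p-value (ties are tolerated; the tie warning from [stats::ks.test()] is
#' suppressed).  An exact small-sample p-value is available behind
#' `exact = TRUE`.
#'
#' @param table a [build_feature_table()] result.
#' @param feature feature name (one of the 7 columns).
#' @param exact use the exact p-value instead of the asymptotic one.
#' @return a list of class `ks_result`: `feature`, `D`, `p_value`, `n_a`,
#'   `n_b`.
#' @export
ks_compare <- function(table, feature, exact = FALSE) {
  check_two_classes(table)
  if (!feature %in% feature_names())
    stop("unknown feature: ", feature)
  xa <- table[[feature]][table$label < 0]
  xb <- table[[feature]][table$label > 0]
  if (length(xa) < 2L || length(xb) < 2L)
    stop("need at least 2 values per class")
  kt <- suppressWarnings(stats::ks.test(xa, xb, exact = exact))
  structure(list(feature = feature, D = unname(kt$statistic),
                 p_value = kt$p.value,
                 n_a = length(xa), n_b = length(xb)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS %-6s D = %.4f  p = %.3g  (n = %d / %d)\n",
              x$feature, x$D, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' KS comparison of all 7 features
#'
#' @param table a [build_feature_table()] result.
#' @param exact passed to [ks_compare()].
#' @return a data frame with one row per feature: `feature`, `D`,
#'   `p_value`.  Raw p-values are reported (no multiplicity correction by
#'   default); Bonferroni-adjusted values are added as `p_bonferroni` when
#'   `bonferroni = TRUE`.
#' @param bonferroni also report Bonferroni-adjusted p-values.
#' @export
ks_compare_all <- function(table, exact = FALSE, bonferroni = FALSE) {
  res <- lapply(feature_names(), function(f) ks_compare(table, f, exact))
  out <- data.frame(feature = feature_names(),
                    D = vapply(res, `[[`, 0, "D"),
                    p_value = vapply(res, `[[`, 0, "p_value"))
  if (bonferroni)
    out$p_bonferroni <- stats::p.adjust(out$p_value, "bonferroni")
  out
}

#' Log-transform a feature table
#'
#' Applies the natural logarithm column-wise to all 7 features (labels and
#' ids untouched), the transformation under which the feature densities are
#' more uniform and in which the classifier operates by default.  Any
#' non-positive value is an explicit error naming the offending cells and
#' features, unless the signed fallback `asinh(x/2)` (which agrees with
#' `log(x)` for large positive x and is defined everywhere) is requested —
#' never silently.
#'
#' @param table a [build_feature_table()] result in linear space.
#' @param signed_fallback use `asinh(x/2)` instead of erroring on
#'   non-positive values.
#' @return the transformed `feature_table`, attribute `space = "log"`.
#' @export
log_transform <- function(table, signed_fallback = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  if (identical(attr(table, "space"), "log"))
    stop("table is already in log space")
  x <- feature_matrix(table)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L && !signed_fallback) {
    what <- paste(sprintf("%s/%s", table$id[bad[, 1L]],
                          colnames(x)[bad[, 2L]]), collapse = ", ")
    stop("non-positive feature values, cannot log-transform: ", what,
         " (set signed_fallback = TRUE for the asinh variant)")
  }
  x <- if (nrow(bad) > 0L) asinh(x / 2) else log(x)
  table[, feature_names()] <- x
  attr(table, "space") <- "log"
  table
}

#' Surface-volume scaling exponent
#'
#' Ordinary least-squares slope of `log(Sigma)` against `log(V)` over the
#' individual cells; geometrically similar shapes of varying scale follow
#' the dimensional law `Sigma ~ V^(2/3)`.
#'
#' @param table a [build_feature_table()] result with at least 3 cells (2
#'   are accepted for the exact two-point slope).
#' @return a list of class `scaling_fit`: `slope`, `se`, `intercept`, `n`.
#' @export
fit_scaling_exponent <- function(table) {
  V <- table$V
  Sigma <- table$Sigma
  keep <- V > 0 & Sigma > 0
  V <- V[keep]; Sigma <- Sigma[keep]
  if (length(V) < 2L) stop("need at least 2 cells with positive V, Sigma")
  if (diff(range(V)) == 0) stop("volume column is constant")
  fit <- stats::lm(log(Sigma) ~ log(V))
  # exactly similar shapes give a perfect fit; the warning is expected
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(slope = cf[2L, 1L],
                 se = if (length(V) > 2L) cf[2L, 2L] else NA_real_,
                 intercept = cf[1L, 1L], n = length(V)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("log-log surface-volume scaling: slope %.4f (se %.4f, n %d)\n",
              x$slope, x$se, x$n))
  invisible(x)
}
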