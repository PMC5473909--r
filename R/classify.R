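#' 2-component PCA projection of a feature table
#'
#' Projects the standardized 7-feature matrix onto its first two principal
#' components, in linear or log space — the low-dimensional view used to
#' check for obvious clustering before classification.  Component signs are
#' fixed by convention: the largest-magnitude loading of each component is
#' made positive, so the projection is fully deterministic.
#'
#' @param table a [build_feature_table()] result (linear space).
#' @param space `"linear"` or `"log"` (log-transforms internally).
#' @return a list of class `pca_projection`: `scores` (n x 2), `explained`
#'   (all explained-variance fractions, non-increasing), `loadings`
#'   (7 x 2), `space`.
#' @export
pca_project <- function(table, space = c("linear", "log")) {
  space <- match.arg(space)
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table) < 3L) stop("need at least 3 cells")
  if (space == "log" && !identical(attr(table, "space"), "log"))
    table <- log_transform(table)
  x <- feature_matrix(table)
  if (any(apply(x, 2L, stats::sd) == 0))
    stop("constant feature column; PCA on standardized features undefined")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (k in 1:2) {
    j <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[j, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x[, 1:2, drop = FALSE],
                 explained = ev / sum(ev),
                 loadings = pc$rotation[, 1:2, drop = FALSE],
                 space = space),
            class = "pca_projection")
}

## ---- repeated cross-validated classification ------------------------------

# balanced per-class weights: n / (n_classes * n_c), sklearn convention
balanced_weights <- function(y) {
  tab <- table(factor(y, levels = c(-1, 1)))
  w <- length(y) / (2 * as.numeric(tab))
  names(w) <- names(tab)
  w
}

# stratified (or plain) k-fold assignment; consumes the current RNG stream
make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  if (stratified) {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      if (length(idx) < k)
        stop("class with ", length(idx),
             " members cannot be split into ", k,
             " folds; reduce 'folds'")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(k), n))
  }
  fold
}

# one CV run of a learner; returns held-out predictions and scores for
# every cell (each predicted exactly once)
cv_run_once <- function(x, y, k, stratified, standardize, cost,
                        class_weights, learner, rf_mode, ntree) {
  n <- nrow(x)
  fold <- make_folds(y, k, stratified)
  pred <- integer(n)
  score <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    ytr <- y[tr]
    if (standardize) {
      mu <- colMeans(xtr)
      sdv <- apply(xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      xtr <- scale(xtr, mu, sdv)
      xte <- scale(xte, mu, sdv)
    }
    if (learner == "svm") {
      cw <- if (class_weights) balanced_weights(ytr) else NULL
      fit <- e1071::svm(x = xtr, y = factor(ytr, levels = c(-1, 1)),
                        kernel = "linear", cost = cost, scale = FALSE,
                        class.weights = cw)
      dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
                 "decision.values")
      # decision values are signed toward the first class of the colname
      first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
      s <- if (identical(first, "1")) dv[, 1L] else -dv[, 1L]
    } else {
      if (rf_mode == "downsample") {
        cls_n <- table(ytr)
        m <- min(cls_n)
        keep <- unlist(lapply(c(-1, 1), function(cl) {
          idx <- which(ytr == cl)
          if (length(idx) > m) sample(idx, m) else idx
        }))
        xtr <- xtr[keep, , drop = FALSE]
        ytr <- ytr[keep]
        cw <- NULL
      } else {
        cw <- balanced_weights(ytr)
      }
      fit <- randomForest::randomForest(
        x = xtr, y = factor(ytr, levels = c(-1, 1)), ntree = ntree,
        classwt = cw)
      votes <- stats::predict(fit, xte, type = "vote")
      s <- votes[, "1"] - 0.5
    }
    # decision rule: sign of the score, ties to the positive class
    pred[!tr] <- ifelse(s >= 0, 1L, -1L)
    score[!tr] <- s
  }
  list(pred = pred, score = score)
}

#' Repeated cross-validated shape classification
#'
#' The package's central fit: a repeated, stratified k-fold cross-validated
#' classifier for a labeled two-class feature table.  The default learner
#' is a soft-margin linear support vector machine — minimizing
#' `||w||^2 / 2 + C * sum(xi_i)` subject to `y_i (w . x_i + b) >= 1 - xi_i`
#' — with per-class penalty weights inversely proportional to the class
#' frequencies ("balanced"), so the minority class is not sacrificed; the
#' held-out prediction is `sign(w . x + b)` with ties assigned to the
#' positive class.  A random forest (with class weights or in-fold majority
#' downsampling) is available for imbalance comparisons under the identical
#' split protocol: with the same `seed`, SVM and RF fits see identical fold
#' assignments, so differences are learner-only.
#'
#' For each of `runs` repetitions the data are randomly split into `folds`
#' groups; each group is predicted once by a model trained on the others.
#' Correctness indicators form the binary outcome matrix `B` (cells x
#' runs), from which the per-cell accuracies `a_i`, class accuracies `A_C`,
#' threshold ratios `r_a` and the ROC AUC of the held-out decision scores
#' are derived (see [accuracy_report()]).  Features are standardized inside
#' each training fold by default (linear SVMs are scale-sensitive and the
#' 7 features span different units); classification is performed in log
#' space by default, where the feature densities are closer to uniform.
#'
#' @param table a [build_feature_table()] result with both classes.
#' @param runs number of repeated CV runs (the headline protocol uses
#'   1000; smaller values are adequate for testing).
#' @param folds number of CV folds (default 10).
#' @param cost misclassification penalty C of the SVM (default 1).
#' @param class_weights `"balanced"` or `"none"` (SVM only; the RF
#'   `"class_weights"` mode always uses balanced weights).
#' @param standardize standardize features within each training fold.
#' @param space `"log"` (default) or `"linear"` feature space.
#' @param stratified stratify folds by class (default; plain random folds
#'   behind `stratified = FALSE`).
#' @param learner `"svm"` (default) or `"rf"`.
#' @param rf_mode for the RF learner: `"class_weights"` or `"downsample"`
#'   (resample the majority class to minority size within each training
#'   fold).
#' @param ntree RF trees per fit.
#' @param thresholds accuracy thresholds for the `r_a` ratios.
#' @param seed master seed; run j uses the j-th child seed, so results are
#'   fully reproducible and extendable.
#' @return an object of class `acroclass`: the outcome matrix `B`, score
#'   matrix `scores`, `labels`, `ids`, the [accuracy_report()] in
#'   `report`, the final full-data model (`final_model`, SVM only) and the
#'   resolved configuration in `config`.  Methods: `print`, `summary`,
#'   `coef`, `predict`, `plot`.
#' @examples
#' pop <- simulate_population(population_spec(n_a = 20, n_b = 10,
#'                                            subdivisions = 2, seed = 3))
#' tab <- build_feature_table(pop)
#' fit <- classify_cv(tab, runs = 5, folds = 5, seed = 1)
#' summary(fit)
#' @export
classify_cv <- function(table, runs = 1000, folds = 10, cost = 1,
                        class_weights = c("balanced", "none"),
                        standardize = TRUE, space = c("log", "linear"),
                        stratified = TRUE,
                        learner = c("svm", "rf"),
                        rf_mode = c("class_weights", "downsample"),
                        ntree = 200, thresholds = c(0.85, 0.99),
                        seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  check_two_classes(table)
  class_weights <- match.arg(class_weights)
  space <- match.arg(space)
  learner <- match.arg(learner)
  rf_mode <- match.arg(rf_mode)
  if (folds < 2L) stop("'folds' must be at least 2")
  if (runs < 1L) stop("'runs' must be at least 1")
  if (cost <= 0) stop("'cost' must be positive")
  work <- if (space == "log" &&
              !identical(attr(table, "space"), "log"))
    log_transform(table) else table
  x <- feature_matrix(work)
  if (any(!is.finite(x))) stop("non-finite feature values")
  y <- work$label
  n <- nrow(x)
  B <- matrix(0L, n, runs)
  scores <- matrix(NA_real_, n, runs)
  seeds <- child_seeds(seed, runs)
  for (j in seq_len(runs)) {
    run <- with_local_seed(seeds[j],
      cv_run_once(x, y, folds, stratified, standardize, cost,
                  class_weights == "balanced", learner, rf_mode, ntree))
    B[, j] <- as.integer(run$pred == y)
    scores[, j] <- run$score
  }
  rownames(B) <- rownames(scores) <- table$id
  report <- accuracy_report(B, y, scores, thresholds)
  final <- NULL
  if (learner == "svm") {
    xf <- x
    ctr <- colMeans(xf); sdv <- apply(xf, 2L, stats::sd)
    sdv[sdv == 0] <- 1
    if (standardize) xf <- scale(xf, ctr, sdv)
    cw <- if (class_weights == "balanced") balanced_weights(y) else NULL
    final <- list(
      model = e1071::svm(x = xf, y = factor(y, levels = c(-1, 1)),
                         kernel = "linear", cost = cost, scale = FALSE,
                         class.weights = cw),
      center = if (standardize) ctr else rep(0, ncol(x)),
      scale = if (standardize) sdv else rep(1, ncol(x)))
  }
  structure(list(B = B, scores = scores, labels = y, ids = table$id,
                 report = report, final_model = final,
                 config = list(runs = runs, folds = folds, cost = cost,
                               class_weights = class_weights,
                               standardize = standardize, space = space,
                               stratified = stratified, learner = learner,
                               rf_mode = rf_mode, ntree = ntree,
                               thresholds = thresholds,
                               seed = as.integer(seed))),
            class = "acroclass")
}

## ---- accuracy framework ---------------------------------------------------

#' Per-cell classification accuracy
#'
#' `a_i`: the fraction of repeated-CV runs in which cell i was correctly
#' classified — the row means of the binary outcome matrix.
#'
#' @param B binary outcome matrix (cells x runs), entries 0/1.
#' @return numeric vector of per-cell accuracies in \[0, 1\].
#' @export
cell_accuracy <- function(B) {
  B <- as.matrix(B)
  if (ncol(B) < 1L) stop("need at least one run")
  if (!all(B %in% c(0L, 1L))) stop("B must be binary")
  rowMeans(B)
}

#' Class-level accuracy
#'
#' `A_C`: the mean of the per-cell accuracies over each class, plus the
#' mean over all cells.  Averaging over cells first or over runs first
#' commutes, so this equals the run-averaged per-run class accuracy
#' identically.
#'
#' @param a per-cell accuracies (from [cell_accuracy()]).
#' @param labels -1/+1 class labels aligned with `a`.
#' @return named numeric vector `c(class_A, class_B, all)`.
#' @export
class_accuracy <- function(a, labels) {
  if (length(a) != length(labels)) stop("'a' and 'labels' lengths differ")
  ia <- labels < 0
  if (!any(ia) || !any(!ia)) stop("both classes must be non-empty")
  c(class_A = mean(a[ia]), class_B = mean(a[!ia]), all = mean(a))
}

#' Ratio of cells at or above an accuracy threshold
#'
#' `r_a`: the fraction of a class's cells whose per-cell accuracy is at
#' least the threshold (inclusive comparison), per class and overall;
#' non-increasing in the threshold, with `r_0 = 1`.
#'
#' @param a per-cell accuracies.
#' @param labels -1/+1 class labels.
#' @param threshold accuracy threshold in \[0, 1\].
#' @return named numeric vector `c(class_A, class_B, all)`.
#' @export
ratio_above <- function(a, labels, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ia <- labels < 0
  c(class_A = mean(a[ia] >= threshold),
    class_B = mean(a[!ia] >= threshold),
    all = mean(a >= threshold))
}

#' ROC AUC of held-out decision scores
#'
#' The area under the receiver operating characteristic, computed as the
#' Mann-Whitney probability that a random positive-class score exceeds a
#' random negative-class score (ties counting one half).  For a score
#' matrix (cells x runs) the AUC of each run's pooled held-out scores is
#' computed and averaged over runs.
#'
#' @param scores numeric vector, or matrix with one column per run.
#' @param labels -1/+1 class labels aligned with the rows.
#' @return scalar AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- labels > 0
  if (!any(pos) || !any(!pos)) stop("both classes must be present")
  auc1 <- function(s) {
    r <- rank(s)                      # average ranks: ties count 1/2
    n1 <- sum(pos); n0 <- sum(!pos)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (is.matrix(scores)) mean(apply(scores, 2L, auc1)) else auc1(scores)
}

#' Accuracy report for a repeated-CV outcome matrix
#'
#' Bundles the full accuracy framework: per-cell accuracies `a_i`, class
#' accuracies `A_C`, threshold ratios `r_a` and the run-averaged ROC AUC.
#'
#' @param B binary outcome matrix (cells x runs).
#' @param labels -1/+1 class labels.
#' @param scores optional held-out decision score matrix for the AUC.
#' @param thresholds accuracy thresholds for the `r_a` rows.
#' @return an object of class `accuracy_report` with `a`, `A_C`, `r_a`
#'   (matrix thresholds x classes), `auc`, `n_runs`, `n` (class sizes).
#' @export
accuracy_report <- function(B, labels, scores = NULL,
                            thresholds = c(0.85, 0.99)) {
  a <- cell_accuracy(B)
  A_C <- class_accuracy(a, labels)
  r_a <- t(vapply(thresholds, function(th) ratio_above(a, labels, th),
                  numeric(3L)))
  rownames(r_a) <- sprintf("r_%g", thresholds)
  auc <- if (!is.null(scores)) roc_auc(scores, labels) else NA_real_
  structure(list(a = a, A_C = A_C, r_a = r_a, auc = auc,
                 n_runs = ncol(as.matrix(B)),
                 n = c(class_A = sum(labels < 0),
                       class_B = sum(labels > 0))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, digits = 2, ...) {
  tab <- cbind(A_C = x$A_C, t(x$r_a))
  rownames(tab) <- c(sprintf("class A (n=%d)", x$n[1L]),
                     sprintf("class B (n=%d)", x$n[2L]),
                     "all cells")
  cat(sprintf("accuracy over %d repeated-CV runs\n", x$n_runs))
  print(round(tab, digits))
  if (!is.na(x$auc)) cat(sprintf("ROC AUC: %.*f\n", digits, x$auc))
  invisible(x)
}

## ---- acroclass methods ----------------------------------------------------

#' @export
print.acroclass <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("repeated %d-fold CV %s (%s space, %s weights, %d runs)\n",
              cfg$folds, toupper(cfg$learner), cfg$space,
              cfg$class_weights, cfg$runs))
  print(x$report, ...)
  invisible(x)
}

#' @export
summary.acroclass <- function(object, ...) {
  print(object, ...)
  a <- object$report$a
  cat(sprintf("per-cell accuracy: min %.2f, median %.2f, max %.2f\n",
              min(a), stats::median(a), max(a)))
  invisible(object$report)
}

#' Separating-hyperplane coefficients
#'
#' Weight vector `w` and offset `b` of the linear SVM refit on the full
#' table (in the fit's working space: standardized log features by
#' default), oriented so that `w . x + b > 0` predicts the positive class.
#'
#' @param object an [classify_cv()] fit with the SVM learner.
#' @param ... unused.
#' @return named vector `c(b, w_V, ..., w_dGrel)`.
#' @export
coef.acroclass <- function(object, ...) {
  if (is.null(object$final_model))
    stop("coefficients are only available for the SVM learner")
  m <- object$final_model$model
  w <- drop(t(m$coefs) %*% m$SV)
  b <- -m$rho
  if (identical(m$levels[1L], "-1")) { w <- -w; b <- -b }
  c(b = b, stats::setNames(w, paste0("w_", feature_names())))
}

#' Predict class labels for new feature rows
#'
#' Applies the full-data SVM (same space and standardization as the fit)
#' to new cells.
#'
#' @param object an [classify_cv()] fit with the SVM learner.
#' @param newdata a `feature_table` or data frame with the 7 feature
#'   columns, in linear space unless already log-transformed.
#' @param ... unused.
#' @return integer -1/+1 predictions with the decision scores in
#'   attribute `"score"`.
#' @export
predict.acroclass <- function(object, newdata, ...) {
  if (is.null(object$final_model))
    stop("prediction is only available for the SVM learner")
  x <- as.matrix(newdata[, feature_names(), drop = FALSE])
  if (object$config$space == "log" &&
      !identical(attr(newdata, "space"), "log")) {
    if (any(x <= 0))
      stop("non-positive feature values cannot enter log space")
    x <- log(x)
  }
  fm <- object$final_model
  x <- scale(x, fm$center, fm$scale)
  dv <- attr(stats::predict(fm$model, x, decision.values = TRUE),
             "decision.values")
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  s <- if (identical(first, "1")) dv[, 1L] else -dv[, 1L]
  out <- ifelse(s >= 0, 1L, -1L)
  attr(out, "score") <- unname(s)
  out
}

#' Plot per-cell accuracies by class
#'
#' Two stacked histograms of the per-cell accuracies `a_i`, one per class —
#' the distribution whose thresholded tails give the `r_a` ratios.
#'
#' @param x an [classify_cv()] fit.
#' @param ... passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.acroclass <- function(x, ...) {
  a <- x$report$a
  lab <- x$labels
  old <- graphics::par(mfrow = c(2L, 1L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  br <- seq(0, 1, by = 0.05)
  graphics::hist(a[lab < 0], breaks = br, col = "darkseagreen3",
                 main = sprintf("class A (A_C = %.2f)",
                                x$report$A_C["class_A"]),
                 xlab = "per-cell accuracy a_i", ...)
  graphics::hist(a[lab > 0], breaks = br, col = "indianred2",
                 main = sprintf("class B (A_C = %.2f)",
                                x$report$A_C["class_B"]),
                 xlab = "per-cell accuracy a_i", ...)
  invisible(x)
}
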