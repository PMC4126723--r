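# ---------------------------------------------------------------------------
# Multivariate stage: linear SVM WS-vs-TD classification under leave-one-out
# cross-validation, recursive feature elimination by weight magnitude, and
# fold-wise case probabilities.
#
# The SVM fit itself is delegated to e1071 (libsvm) with a linear kernel and
# soft-margin cost C; everything around it — leakage-free per-fold
# standardization, the LOO protocol, RFE, the fold-ensemble case probability
# and the permutation null — is implemented here.
# ---------------------------------------------------------------------------

mvpa_levels <- c("WS", "TD")

#' Assemble a feature matrix for classification
#'
#' @param X subjects-by-voxels numeric matrix (typically from [vectorize] on
#'   4 mm down-sampled maps); no missing entries.
#' @param y group labels, coerced to factor with levels `WS`, `TD`; both
#'   classes must be present.
#' @param voxel_index optional feature-to-lattice map carried through from
#'   [vectorize].
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, y, voxel_index = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X))) stop("feature matrix has invalid entries")
  y <- factor(as.character(y), levels = mvpa_levels)
  if (anyNA(y)) stop("labels must be 'WS' or 'TD'")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present")
  structure(list(X = X, y = y, voxel_index = voxel_index),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d subjects (%s) x %d features\n",
              nrow(x$X), paste(sprintf("%d %s", table(x$y), mvpa_levels),
                               collapse = ", "), ncol(x$X)))
  invisible(x)
}

# Fit one linear soft-margin SVM; return weights in the (standardized)
# feature space, oriented so that the decision value w.x + b is positive on
# the WS side. Ties at the margin (w.x + b == 0) are assigned to TD.
fit_linear_svm <- function(X, y, C) {
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C,
                    scale = FALSE, type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # libsvm's positive decision side is the first label it encountered;
  # flip so positive always means WS
  if (fit$labels[1L] != which(mvpa_levels == "WS")) {
    w <- -w; b <- -b
  }
  list(w = w, b = b)
}

svm_side <- function(f) ifelse(f > 0, "WS", "TD")

# training-fold standardization statistics; zero-variance features get
# scale 1 so they pass through centered but unscaled
fold_standardizer <- function(Xtr) {
  ctr <- colMeans(Xtr)
  scl <- apply(Xtr, 2L, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2L, std$center, "-"), 2L, std$scale, "/")
}

#' Train a leave-one-out ensemble of linear SVMs
#'
#' One fold per reference subject: the fold's classifier is the
#' maximum-margin linear separator (soft-margin cost `C`) trained on the
#' remaining N-1 subjects, and the held-out subject is labeled by it.
#' `loo_accuracy` is the fraction of held-out subjects labeled correctly.
#' Feature standardization, when enabled, uses training-fold statistics only
#' so no information from the held-out subject (or any later case) leaks
#' into training.
#'
#' @param fm a [feature_matrix].
#' @param C soft-margin regularization parameter (default 1).
#' @param features optional integer subset of feature columns to use.
#' @param standardize center/scale features with training-fold statistics
#'   (default TRUE).
#' @return An object of class `classifier_ensemble`: `folds` (each with
#'   `w`, `b`, `center`, `scale`, `held_out`, `predicted`), `features`,
#'   `C`, `n`, `loo_accuracy`, `predictions`.
#' @export
train_loo <- function(fm, C = 1, features = NULL, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"), C > 0)
  if (is.null(features)) features <- seq_len(ncol(fm$X))
  X <- fm$X[, features, drop = FALSE]
  y <- fm$y
  n <- nrow(X)
  if (min(table(y)) < 2L)
    stop("leave-one-out needs at least 2 subjects per class")
  folds <- vector("list", n)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    ytr <- y[-i]
    std <- if (standardize) fold_standardizer(Xtr)
           else list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
    Xs <- apply_standardizer(Xtr, std)
    svm <- fit_linear_svm(Xs, ytr, C)
    xh <- apply_standardizer(X[i, , drop = FALSE], std)
    f <- drop(xh %*% svm$w) + svm$b
    pred[i] <- svm_side(f)
    folds[[i]] <- list(w = svm$w, b = svm$b,
                       center = std$center, scale = std$scale,
                       held_out = i, predicted = pred[i])
  }
  structure(list(folds = folds, features = features, C = C, n = n,
                 standardize = standardize,
                 loo_accuracy = mean(pred == as.character(y)),
                 predictions = pred, y = as.character(y)),
            class = "classifier_ensemble")
}

#' @export
print.classifier_ensemble <- function(x, ...) {
  cat(sprintf(
    "<classifier_ensemble> %d LOO folds, %d features, C = %g, accuracy %.3f\n",
    x$n, length(x$features), x$C, x$loo_accuracy))
  invisible(x)
}

#' Recursive feature elimination over the LOO ensemble
#'
#' At each level a fresh LOO ensemble is trained on the surviving features,
#' its accuracy recorded, features are ranked by the mean `|w|` across the
#' level's fold classifiers (in standardized space, so the ranking is
#' scale-free), and the bottom `floor(r * m)` (at least 1) are dropped.
#' Elimination stops before the feature count would fall below
#' `min_features`. The chosen level maximizes LOO accuracy; ties go to the
#' level with the fewest features. By construction the chosen level's
#' accuracy is at least the full-feature accuracy.
#'
#' @param fm a [feature_matrix].
#' @param C soft-margin cost (default 1).
#' @param r fraction of features eliminated per level, in (0, 1);
#'   default 0.30.
#' @param min_features elimination stops rather than descend below this
#'   count (default 10).
#' @param standardize see [train_loo].
#' @return An object of class `rfe_result`: `trace` (data.frame `level`,
#'   `n_features`, `loo_accuracy`), `chosen_level`, `features` (selected
#'   set, indices into `fm` columns), and `ensemble` (the chosen level's
#'   [train_loo] ensemble).
#' @export
rfe <- function(fm, C = 1, r = 0.30, min_features = 10, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!(r > 0 && r < 1)) stop("elimination fraction r must be in (0, 1)")
  active <- seq_len(ncol(fm$X))
  trace <- list()
  levels_kept <- list()
  lev <- 0L
  repeat {
    lev <- lev + 1L
    ens <- train_loo(fm, C = C, features = active, standardize = standardize)
    trace[[lev]] <- data.frame(level = lev, n_features = length(active),
                               loo_accuracy = ens$loo_accuracy)
    levels_kept[[lev]] <- list(features = active, ensemble = ens)
    m <- length(active)
    ndrop <- max(1L, floor(r * m))
    if (m - ndrop < min_features) break
    W <- do.call(rbind, lapply(ens$folds, `[[`, "w"))
    rank_score <- colMeans(abs(W))
    keep_local <- order(rank_score, decreasing = TRUE)[seq_len(m - ndrop)]
    active <- active[sort(keep_local)]
  }
  trace <- do.call(rbind, trace)
  best_acc <- max(trace$loo_accuracy)
  cand <- trace$level[trace$loo_accuracy == best_acc]
  chosen <- cand[which.min(trace$n_features[trace$level %in% cand])]
  structure(list(trace = trace, r = r, chosen_level = chosen,
                 features = levels_kept[[chosen]]$features,
                 ensemble = levels_kept[[chosen]]$ensemble),
            class = "rfe_result")
}

#' @export
print.rfe_result <- function(x, ...) {
  cat(sprintf("<rfe_result> %d levels (r = %.2f); chosen level %d: %d features, accuracy %.3f\n",
              nrow(x$trace), x$r, x$chosen_level, length(x$features),
              x$ensemble$loo_accuracy))
  invisible(x)
}

#' Fold-wise group probability for a single case
#'
#' Applies every fold classifier of a LOO ensemble to the case and reports
#' the fraction of folds assigning it to each group; `p_ws` and `p_td` are
#' exact multiples of 1/N and sum to 1. A case exactly on a fold's decision
#' boundary is assigned to TD (deterministic tie rule; affects only
#' measure-zero inputs).
#'
#' @param ens a `classifier_ensemble` (e.g. `rfe(...)$ensemble`).
#' @param case_vector numeric vector over the full original feature columns,
#'   or exactly over `ens$features`.
#' @param case_id identifier for reporting.
#' @return one-row data.frame: `case_id`, `p_ws`, `p_td`, `n_folds`.
#' @export
classify_case <- function(ens, case_vector, case_id = "case") {
  stopifnot(inherits(ens, "classifier_ensemble"))
  p <- length(ens$folds[[1L]]$w)
  if (length(case_vector) == p) {
    x <- as.numeric(case_vector)
  } else if (length(case_vector) >= max(ens$features)) {
    x <- as.numeric(case_vector)[ens$features]
  } else {
    stop("case vector length matches neither the selected features nor the full feature space")
  }
  sides <- vapply(ens$folds, function(fd) {
    xs <- (x - fd$center) / fd$scale
    svm_side(sum(xs * fd$w) + fd$b)
  }, character(1))
  p_ws <- mean(sides == "WS")
  data.frame(case_id = case_id, p_ws = p_ws, p_td = 1 - p_ws,
             n_folds = ens$n, stringsAsFactors = FALSE)
}

#' Permutation null for LOO accuracy
#'
#' Re-runs the full LOO protocol under `n_perm` random permutations of the
#' group labels and reports the achieved-significance p-value
#' `(1 + #{null >= observed}) / (n_perm + 1)`. With `n_perm = 199` the
#' smallest attainable p is 1/200.
#'
#' @param fm a [feature_matrix].
#' @param C soft-margin cost.
#' @param n_perm number of permutations (>= 1; >= 100 recommended for a
#'   usable p-value).
#' @param seed optional integer seed for the permutations.
#' @param features,standardize passed to [train_loo].
#' @return list: `observed` accuracy, `null` (numeric vector of length
#'   `n_perm`), `p`.
#' @export
permutation_accuracy_null <- function(fm, C = 1, n_perm = 199, seed = NULL,
                                      features = NULL, standardize = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.numeric(n_perm) || n_perm < 1)
    stop("n_perm must be a positive integer")
  n_perm <- as.integer(n_perm)
  if (!is.null(seed)) set.seed(seed)
  observed <- train_loo(fm, C = C, features = features,
                        standardize = standardize)$loo_accuracy
  null <- vapply(seq_len(n_perm), function(b) {
    fperm <- fm
    fperm$y <- sample(fm$y)
    # a permutation can leave a class with < 2 members only if the class had
    # < 2 to begin with, which train_loo already rejects
    train_loo(fperm, C = C, features = features,
              standardize = standardize)$loo_accuracy
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (n_perm + 1))
}
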