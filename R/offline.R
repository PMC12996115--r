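#' Offline post-hoc analyses
#'
#' Reproduces the post-hoc analysis chain on 30-s exposure epochs:
#' peak-to-peak epoch rejection, binary low/high fear labeling from
#' levels, leak-free nested cross-validated classification (SVM, random
#' forest, gradient boosting) over PSD / FAA / combined feature sets,
#' feature-importance ranking, grand-average band topographies, pairwise
#' level statistics with Benjamini-Hochberg correction, and masked
#' correlation matrices.
#'
#' @name offline
NULL

#' Reject epochs with excessive peak-to-peak voltage
#'
#' An epoch is kept iff its maximum per-channel peak-to-peak amplitude is
#' at most `threshold_uV`.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uV rejection threshold in microvolts; default 200.
#' @return the surviving `epoch_set`, with attribute `"kept"` (logical
#'   over the input epochs).
#' @export
reject_epochs <- function(epochs, threshold_uV = 200) {
  stopifnot(inherits(epochs, "epoch_set"))
  n <- n_epochs(epochs)
  if (!n) stop("no epochs supplied")
  ptp <- vapply(seq_len(n), function(k) {
    m <- epochs$epochs[, , k, drop = FALSE]
    max(apply(m[, , 1, drop = TRUE], 1L, function(x) diff(range(x))))
  }, 0)
  keep <- ptp <= threshold_uV
  if (!any(keep)) stop("no epochs survive rejection")
  out <- epochs
  out$epochs <- epochs$epochs[, , keep, drop = FALSE]
  out$onsets_s <- epochs$onsets_s[keep]
  attr(out, "kept") <- keep
  out
}

#' Binary low/high fear labels from stimulus levels
#'
#' Levels 1-2 map to `"low"`, levels 4-5 to `"high"`; level 3 is excluded
#' (`NA`) because it is too sparsely visited to label reliably.
#'
#' @param levels integer vector of per-epoch stimulus levels (1..5).
#' @return character vector (`"low"`, `"high"`, or `NA` for excluded),
#'   same length as `levels`.
#' @export
make_binary_labels <- function(levels) {
  if (!all(levels %in% 1:5)) stop("levels must be in 1..5")
  lab <- rep(NA_character_, length(levels))
  lab[levels %in% c(1, 2)] <- "low"
  lab[levels %in% c(4, 5)] <- "high"
  if (length(levels) && all(is.na(lab)))
    warning("all epochs at level 3: empty labeled set")
  lab
}

# Stratified fold assignment, deterministic under the current RNG state.
.stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

.macro_f1 <- function(truth, pred) {
  mean(vapply(unique(truth), function(cls) {
    tp <- sum(pred == cls & truth == cls)
    fp <- sum(pred == cls & truth != cls)
    fn <- sum(pred != cls & truth == cls)
    if (tp == 0) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0))
}

.default_grids <- list(
  svm = expand.grid(cost = c(0.1, 1, 10)),
  rf  = expand.grid(mtry_frac = c(0.1, 0.33), num.trees = 300),
  xgb = expand.grid(max_depth = c(2, 4), nrounds = 50, eta = 0.3))

.fit_predict <- function(algorithm, par, Xtr, ytr, Xte) {
  ytr <- factor(ytr, levels = c("low", "high"))
  if (algorithm == "svm") {
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = par$cost,
                      scale = FALSE)
    list(fit = fit, pred = as.character(predict(fit, Xte)))
  } else if (algorithm == "rf") {
    mtry <- max(1L, floor(par$mtry_frac * ncol(Xtr)))
    fit <- ranger::ranger(x = Xtr, y = ytr, mtry = mtry,
                          num.trees = par$num.trees,
                          importance = "impurity",
                          num.threads = 1L, seed = 1L)
    list(fit = fit,
         pred = as.character(stats::predict(fit, Xte,
                                            num.threads = 1L)$predictions))
  } else {
    dtr <- xgboost::xgb.DMatrix(Xtr, label = as.integer(ytr == "high"))
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = par$max_depth,
                    eta = par$eta, nthread = 1L),
      data = dtr, nrounds = par$nrounds, verbose = 0)
    pr <- stats::predict(fit, xgboost::xgb.DMatrix(Xte))
    list(fit = fit, pred = ifelse(pr > 0.5, "high", "low"))
  }
}

#' Nested cross-validated fear-level classification
#'
#' Outer stratified 5-fold cross-validation reports accuracy and macro-F1
#' (mean +/- sd, in percent); inside each outer training fold the features
#' are z-scored (statistics fitted on that fold only) and hyperparameters
#' are selected by stratified 3-fold grid search, so no information leaks
#' from any test fold. A final model with the most frequently selected
#' parameters is fitted on all (standardized) data to provide the feature
#' importance ranking.
#'
#' @param X numeric feature matrix (epochs x features), named columns.
#' @param y labels `"low"` / `"high"` (`NA` rows are dropped).
#' @param algorithm `"svm"` (linear), `"rf"` (random forest) or `"xgb"`
#'   (gradient boosting).
#' @param feature_set `"psd+faa"` (all columns), `"psd"` (band-power
#'   columns only) or `"faa"` (FAA columns only), selected by column name.
#' @param outer_folds,inner_folds fold counts; defaults 5 and 3.
#' @param grid hyperparameter data.frame; `NULL` uses a compact default.
#' @param seed RNG seed for fold assignment; default 1.
#' @return a `classification_report`: list with `algorithm`,
#'   `feature_set`, `accuracy_mean`, `accuracy_sd`, `f1_mean`, `f1_sd`
#'   (percent), `fold_accuracy`, `fold_f1`, `chosen_params`, `importance`
#'   (named, sorted descending).
#' @export
nested_cv_classify <- function(X, y, algorithm = c("svm", "rf", "xgb"),
                               feature_set = c("psd+faa", "psd", "faa"),
                               outer_folds = 5, inner_folds = 3,
                               grid = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm)
  feature_set <- match.arg(feature_set)
  keep <- !is.na(y)
  X <- as.matrix(X[keep, , drop = FALSE])
  y <- y[keep]
  faa_cols <- grepl("^FAA_", colnames(X))
  X <- switch(feature_set,
              "psd+faa" = X,
              "psd" = X[, !faa_cols, drop = FALSE],
              "faa" = X[, faa_cols, drop = FALSE])
  if (!ncol(X)) stop("feature set selects no columns")
  if (any(table(y) < 10L)) stop("need at least 10 samples per class")
  grid <- grid %||% .default_grids[[algorithm]]
  set.seed(seed)
  outer <- .stratified_folds(y, outer_folds)
  fold_acc <- fold_f1 <- numeric(outer_folds)
  chosen_idx <- integer(outer_folds)
  for (f in seq_len(outer_folds)) {
    tr <- outer != f
    ctr <- colMeans(X[tr, , drop = FALSE])
    scl <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    std <- function(m) sweep(sweep(m, 2L, ctr), 2L, scl, `/`)
    Xtr <- std(X[tr, , drop = FALSE]); ytr <- y[tr]
    Xte <- std(X[!tr, , drop = FALSE]); yte <- y[!tr]
    best <- 1L
    if (nrow(grid) > 1L) {
      inner <- .stratified_folds(ytr, inner_folds)
      score <- vapply(seq_len(nrow(grid)), function(g) {
        mean(vapply(seq_len(inner_folds), function(j) {
          fp <- .fit_predict(algorithm, grid[g, , drop = FALSE],
                             Xtr[inner != j, , drop = FALSE], ytr[inner != j],
                             Xtr[inner == j, , drop = FALSE])
          mean(fp$pred == ytr[inner == j])
        }, 0))
      }, 0)
      best <- which.max(score)
    }
    fp <- .fit_predict(algorithm, grid[best, , drop = FALSE], Xtr, ytr, Xte)
    fold_acc[f] <- mean(fp$pred == yte)
    fold_f1[f] <- .macro_f1(yte, fp$pred)
    chosen_idx[f] <- best
  }
  modal <- as.integer(names(sort(table(chosen_idx), decreasing = TRUE))[1L])
  ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)
  final <- .fit_predict(algorithm, grid[modal, , drop = FALSE], Xs, y, Xs)
  structure(list(
    algorithm = algorithm, feature_set = feature_set,
    accuracy_mean = 100 * mean(fold_acc),
    accuracy_sd = 100 * stats::sd(fold_acc),
    f1_mean = 100 * mean(fold_f1), f1_sd = 100 * stats::sd(fold_f1),
    fold_accuracy = 100 * fold_acc, fold_f1 = 100 * fold_f1,
    chosen_params = grid[chosen_idx, , drop = FALSE],
    importance = rank_feature_importance(final$fit, colnames(X))),
    class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s / %s: accuracy %.2f +/- %.2f%%, F1 %.2f +/- %.2f%%\n",
              x$algorithm, x$feature_set, x$accuracy_mean, x$accuracy_sd,
              x$f1_mean, x$f1_sd))
  cat("top features:", paste(utils::head(names(x$importance), 5L),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Rank features by importance
#'
#' Random forests use impurity importance, gradient boosting uses gain
#' (absent features get 0), and linear margin classifiers -- which expose
#' no native importance -- use the absolute hyperplane weight on the
#' standardized features.
#'
#' @param model a fitted `ranger`, `xgb.Booster` or `svm` model.
#' @param feature_names feature names in training column order.
#' @return named numeric vector sorted decreasing.
#' @export
rank_feature_importance <- function(model, feature_names) {
  imp <- if (inherits(model, "ranger")) {
    ranger::importance(model)[feature_names]
  } else if (inherits(model, "xgb.Booster")) {
    tab <- xgboost::xgb.importance(model = model)
    v <- stats::setNames(rep(0, length(feature_names)), feature_names)
    v[tab$Feature] <- tab$Gain
    v
  } else if (inherits(model, "svm")) {
    w <- as.vector(crossprod(model$SV, model$coefs))
    stats::setNames(abs(w), feature_names)
  } else stop("model exposes no importances")
  sort(imp, decreasing = TRUE)
}

#' Grand-average band-power topography matrix
#'
#' Mean Welch band power per channel, per band, per stimulus level.
#'
#' @param epochs an `epoch_set` of exposure epochs.
#' @param levels per-epoch stimulus level (1..5).
#' @param bands band set; default [default_bands()].
#' @return numeric array `level x band x channel` (5 x 5 x n_channels);
#'   levels without epochs give `NA` rows with a warning.
#' @export
grand_average_topomap <- function(epochs, levels, bands = default_bands()) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(levels) != n_epochs(epochs))
    stop("one level per epoch required")
  labels <- epochs$channel_labels
  out <- array(NA_real_, dim = c(5, length(bands), length(labels)),
               dimnames = list(paste0("level", 1:5),
                               vapply(bands, `[[`, "", "name"), labels))
  bp <- vapply(seq_len(n_epochs(epochs)), function(k) {
    spec <- welch_psd(epochs$epochs[, , k], epochs$fs_hz)
    vapply(bands, function(b) bandpower(spec, b), numeric(length(labels)))
  }, matrix(0, length(labels), length(bands)))  # channels x bands x epochs
  for (lv in 1:5) {
    idx <- which(levels == lv)
    if (!length(idx)) {
      warning("no epochs at level ", lv, "; NA row")
      next
    }
    m <- apply(bp[, , idx, drop = FALSE], c(1, 2), mean)
    out[lv, , ] <- t(m)
  }
  out
}

#' Pairwise level statistics with Benjamini-Hochberg correction
#'
#' All pairwise Welch (unequal-variance) t-tests between level groups,
#' with BH adjustment over the whole comparison family. Level groups may
#' have unequal sizes (online control visits levels unevenly). Degenerate
#' pairs (zero variance in both groups) are flagged with `NA` statistics.
#'
#' @param values numeric observations (e.g. FAA per epoch, or the 10
#'   per-iteration 30-s HR means).
#' @param levels group label per observation.
#' @param alpha significance level for the flags; default 0.05.
#' @return a `stat_table` data.frame: `group_a`, `group_b`, `statistic`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
level_stats <- function(values, levels, alpha = 0.05) {
  if (length(values) != length(levels)) stop("values/levels length mismatch")
  groups <- sort(unique(levels))
  if (length(groups) < 2L) stop("need at least 2 levels")
  pairs <- utils::combn(groups, 2L)
  res <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- values[levels == pairs[1, i]]
    b <- values[levels == pairs[2, i]]
    if (length(a) < 2L || length(b) < 2L ||
        (stats::sd(a) == 0 && stats::sd(b) == 0)) next
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res$statistic[i] <- unname(tt$statistic)
    res$p_raw[i] <- tt$p.value
  }
  ok <- !is.na(res$p_raw)
  res$p_adj <- NA_real_
  res$significant <- NA
  if (any(ok)) {
    bh <- benjamini_hochberg(res$p_raw[ok], alpha)
    res$p_adj[ok] <- bh$p_adjusted
    res$significant[ok] <- bh$rejected
  }
  class(res) <- c("stat_table", "data.frame")
  res
}

#' Per-iteration 30-s heart-rate means for a main session
#'
#' Averages the HR series over consecutive `exposure_s` windows -- one
#' mean per loop iteration, i.e. 10 values per participant for the
#' default protocol.
#'
#' @param session a main-protocol `session_recording` (or an
#'   `hr_series`).
#' @param n_iter number of iterations; default 10.
#' @param exposure_s window length; default 30 s.
#' @return numeric vector of length `n_iter`.
#' @export
hr_window_means <- function(session, n_iter = 10, exposure_s = 30) {
  hr <- if (inherits(session, "session_recording")) session$hr else session
  stopifnot(inherits(hr, "hr_series"))
  vapply(seq_len(n_iter), function(i) {
    lo <- (i - 1) * exposure_s; hi <- i * exposure_s
    v <- hr$values[hr$times >= lo & hr$times < hi]
    if (!length(v)) return(NA_real_)
    mean(v)
  }, 0)
}

#' Masked Pearson correlation matrix with BH correction
#'
#' Pairwise Pearson correlations with two-tailed p-values, BH-adjusted
#' over the upper triangle; non-significant entries are masked (`NA`) in
#' `r_masked`. A rank-based variant is available via `method =
#' "spearman"`.
#'
#' @param data numeric data.frame or matrix (observations x variables),
#'   e.g. questionnaire scores, per-level FAA means, HR.
#' @param alpha significance level; default 0.05.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `correlation_matrix` list: `r`, `p`, `p_adj`, `significant`,
#'   `r_masked`. Zero-variance variables yield `NA` rows/columns with a
#'   warning.
#' @export
correlation_matrix <- function(data, alpha = 0.05, method = "pearson") {
  X <- as.matrix(data)
  if (nrow(X) < 3L) stop("need at least 3 observations per variable")
  p <- ncol(X)
  vars <- colnames(X) %||% paste0("V", seq_len(p))
  degenerate <- apply(X, 2L, stats::sd) == 0
  if (any(degenerate))
    warning("zero-variance variable(s): ",
            paste(vars[degenerate], collapse = ", "))
  r <- pv <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (degenerate[i] || degenerate[j]) next
    ct <- stats::cor.test(X[, i], X[, j], method = method, exact = FALSE)
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  ut <- upper.tri(pv)
  ok <- ut & !is.na(pv)
  p_adj <- sig <- matrix(NA, p, p, dimnames = list(vars, vars))
  if (any(ok)) {
    bh <- benjamini_hochberg(pv[ok], alpha)
    p_adj[ok] <- bh$p_adjusted
    sig[ok] <- bh$rejected
    p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
    sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  }
  r_masked <- r
  r_masked[!is.na(sig) & !sig] <- NA_real_
  structure(list(r = r, p = pv, p_adj = p_adj, significant = sig,
                 r_masked = r_masked, alpha = alpha, method = method),
            class = "correlation_matrix")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: with ordered p-values `p(1) <= ... <= p(m)`, find
#' the largest `k` with `p(k) <= k/m * alpha` and reject hypotheses
#' `1..k`. Adjusted p-values are `min_{j >= i} (m/j) p(j)`, capped at 1.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param alpha FDR level for the rejection flags; default 0.05.
#' @return list with `p_adjusted` and logical `rejected`, in input order.
#' @export
benjamini_hochberg <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj_sorted <- pmin(1, rev(cummin(rev(ranked))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  k <- which(p[o] <= seq_len(m) / m * alpha)
  rejected <- logical(m)
  if (length(k)) rejected[o[seq_len(max(k))]] <- TRUE
  list(p_adjusted = adj, rejected = rejected)
}
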