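#' Individualized fear-state calibration
#'
#' The pretest protocol records ~90 s in a relaxed neutral scene and ~90 s
#' under the maximal spider stimulus. Both phases are cut into
#' non-overlapping 500-ms windows (each window one trial), the 5-value
#' calibration features (4 FAA + mean HR) are extracted, and a margin
#' classifier is trained whose signed distance to the decision boundary
#' drives the online controller: positive distances mean "fear side".
#'
#' @name calibration
NULL

#' Build the calibration dataset from a pretest session
#'
#' The relax phase is the `relax_span` seconds ending at the
#' `Spider_Scene` marker; the fear phase is the `fear_span` seconds
#' starting at the `Spider_Stimulus` marker. The session is preprocessed
#' (filter, CAR, baseline from the pre-marker window), each phase is
#' segmented into non-overlapping `window_s` windows, and a per-feature
#' standardization (mean/sd) is fitted on the pooled matrix.
#'
#' @param session a pretest `session_recording` containing both phase
#'   markers.
#' @param relax_span,fear_span phase lengths in seconds; default 90.
#' @param window_s trial window length; default 0.5 s.
#' @param pairs FAA pair table.
#' @param preprocess apply the standard cleaning chain first (default TRUE).
#' @return a `calibration_dataset`: list with `X` (trials x 5), `y`
#'   (0 = relax, 1 = fear), `scaler` (`center`, `scale`), `feature_names`.
#' @export
build_calibration_dataset <- function(session, relax_span = 90,
                                      fear_span = 90, window_s = 0.5,
                                      pairs = default_faa_pairs(),
                                      preprocess = TRUE) {
  stopifnot(inherits(session, "session_recording"))
  t_scene <- marker_time(session$markers, "Spider_Scene")
  t_stim <- marker_time(session$markers, "Spider_Stimulus")
  if (is.na(t_scene)) stop("missing relax phase: no Spider_Scene marker")
  if (is.na(t_stim)) stop("missing fear phase: no Spider_Stimulus marker")
  if (preprocess) session <- preprocess_session(session)
  dur <- session_duration(session)
  relax <- slice_session(session, max(0, t_scene - relax_span), t_scene)
  fear <- slice_session(session, t_stim, min(dur, t_stim + fear_span))
  if (session_duration(relax) < window_s || session_duration(fear) < window_s)
    stop("phase shorter than one window")
  feats <- function(phase) {
    ep <- segment_windows(phase$eeg, window_s, overlap_fraction = 0)
    calibration_features(ep, phase$hr, pairs = pairs)
  }
  Xr <- feats(relax)
  Xf <- feats(fear)
  if (abs(nrow(Xr) - nrow(Xf)) / max(nrow(Xr), nrow(Xf)) > 0.05)
    warning("class imbalance exceeds 5%: ", nrow(Xr), " relax vs ",
            nrow(Xf), " fear trials")
  X <- rbind(Xr, Xf)
  y <- c(rep(0L, nrow(Xr)), rep(1L, nrow(Xf)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  structure(list(X = X, y = y,
                 scaler = list(center = ctr, scale = scl),
                 feature_names = colnames(X)),
            class = "calibration_dataset")
}

#' @export
print.calibration_dataset <- function(x, ...) {
  cat(sprintf("<calibration_dataset> %d trials (%d relax / %d fear), %d features\n",
              nrow(x$X), sum(x$y == 0), sum(x$y == 1), ncol(x$X)))
  invisible(x)
}

.scale_features <- function(X, scaler) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, `/`)
}

#' Train the individualized fear classifier
#'
#' Fits a support-vector machine on the standardized calibration features.
#' The linear kernel is the default: its decision values are expressed in
#' margin units, which is what the controller's fixed +/-0.5 thresholds
#' assume. The decision sign is calibrated after fitting so that the
#' fear-class mean distance is positive regardless of label encoding.
#'
#' @param data a `calibration_dataset` with both classes (>= 10 trials
#'   each).
#' @param kernel `"linear"` (default) or `"radial"`.
#' @param cost SVM regularization constant C; default 1.
#' @return a `fear_classifier`: stores kernel parameters (weights or
#'   support vectors), the scaler, the feature-order tag, and training
#'   accuracy.
#' @export
train_fear_classifier <- function(data, kernel = "linear", cost = 1) {
  stopifnot(inherits(data, "calibration_dataset"))
  kernel <- match.arg(kernel, c("linear", "radial"))
  tab <- table(data$y)
  if (length(tab) < 2L) stop("single-class data: both classes required")
  if (any(tab < 10L)) stop("need at least 10 trials per class")
  key <- function(m) apply(round(m, 12L), 1L, paste, collapse = ",")
  if (identical(sort(key(data$X[data$y == 0, , drop = FALSE])),
                sort(key(data$X[data$y == 1, , drop = FALSE]))))
    stop("degenerate classes: identical feature sets under both labels")
  Xs <- .scale_features(data$X, data$scaler)
  fit <- e1071::svm(Xs, factor(data$y, levels = c(0, 1)),
                    kernel = kernel, cost = cost, scale = FALSE)
  gamma <- if (kernel == "radial") fit$gamma else NA_real_
  sv <- fit$SV
  coefs <- as.vector(fit$coefs)
  rho <- fit$rho
  model <- structure(list(
    kernel = kernel, cost = cost, gamma = gamma,
    sv = sv, coefs = coefs, rho = rho, sign = 1,
    weights = if (kernel == "linear") as.vector(crossprod(sv, coefs)) else NULL,
    scaler = data$scaler, feature_names = data$feature_names,
    training_accuracy = NA_real_), class = "fear_classifier")
  d <- signed_distance(model, data$X)
  if (mean(d[data$y == 1]) < mean(d[data$y == 0])) model$sign <- -1
  d <- d * model$sign
  model$training_accuracy <- mean((d > 0) == (data$y == 1))
  model
}

#' @export
print.fear_classifier <- function(x, ...) {
  cat(sprintf("<fear_classifier> %s kernel (C = %g), %d features, training accuracy %.1f%%\n",
              x$kernel, x$cost, length(x$feature_names),
              100 * x$training_accuracy))
  invisible(x)
}

#' Signed distance to the decision boundary
#'
#' Standardizes the features with the scaler stored at calibration and
#' returns the classifier decision value; positive values lie on the fear
#' side, negative on the relaxed side. For the linear kernel the value is
#' affine in the standardized features and expressed in margin units. The
#' computation uses the stored weight/support vectors directly (not the
#' fitting library), so saved-and-reloaded models reproduce distances
#' bit for bit.
#'
#' @param model a `fear_classifier`.
#' @param features numeric vector of length 5 or matrix (trials x 5);
#'   column names, if present, must match the model's feature order.
#' @return numeric vector of signed distances.
#' @export
signed_distance <- function(model, features) {
  stopifnot(inherits(model, "fear_classifier"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (ncol(features) != length(model$feature_names))
    stop("feature order mismatch: expected ", length(model$feature_names),
         " features")
  if (!is.null(colnames(features)) &&
      !identical(colnames(features), model$feature_names))
    stop("feature order mismatch: column names disagree with the model tag")
  Xs <- .scale_features(features, model$scaler)
  dv <- if (model$kernel == "linear") {
    as.vector(Xs %*% model$weights) - model$rho
  } else {
    d2 <- outer(rowSums(Xs^2), rowSums(model$sv^2), `+`) -
      2 * tcrossprod(Xs, model$sv)
    as.vector(exp(-model$gamma * d2) %*% model$coefs) - model$rho
  }
  model$sign * dv
}

#' Save a fear classifier (JSON metadata + binary sidecar)
#'
#' Writes `<path>.json` with kernel, scaler, feature order and training
#' metadata, and `<path>.bin` with all numeric arrays as little-endian
#' doubles, so reloaded models reproduce distances exactly.
#'
#' @param model a `fear_classifier`.
#' @param path file stem.
#' @return `path`, invisibly.
#' @export
save_fear_classifier <- function(model, path) {
  stopifnot(inherits(model, "fear_classifier"))
  arrays <- list(sv = as.vector(model$sv), coefs = model$coefs,
                 rho = model$rho,
                 weights = model$weights %||% numeric(),
                 center = model$scaler$center, scale = model$scaler$scale)
  lens <- vapply(arrays, length, 0L)
  meta <- list(format = "faaloop-model/1", kernel = model$kernel,
               cost = model$cost,
               gamma = if (is.na(model$gamma)) NULL else model$gamma,
               sign = model$sign, sv_rows = nrow(model$sv),
               feature_names = model$feature_names,
               training_accuracy = model$training_accuracy,
               array_lengths = as.list(lens))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(unlist(arrays, use.names = FALSE), con, size = 8L,
           endian = "little")
  invisible(path)
}

#' Load a fear classifier saved by [save_fear_classifier()]
#'
#' @param path file stem.
#' @return a `fear_classifier`.
#' @export
load_fear_classifier <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lens <- unlist(meta$array_lengths)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = sum(lens), size = 8L, endian = "little")
  ends <- cumsum(lens)
  splits <- Map(function(a, b) if (b < a) numeric() else raw[a:b],
                ends - lens + 1L, ends)
  names(splits) <- names(lens)
  p <- length(meta$feature_names)
  sv <- matrix(splits$sv %||% numeric(), ncol = p)
  structure(list(
    kernel = meta$kernel, cost = meta$cost,
    gamma = meta$gamma %||% NA_real_,
    sv = sv, coefs = splits$coefs, rho = splits$rho, sign = meta$sign,
    weights = if (meta$kernel == "linear") splits$weights else NULL,
    scaler = list(center = stats::setNames(splits$center, meta$feature_names),
                  scale = stats::setNames(splits$scale, meta$feature_names)),
    feature_names = meta$feature_names,
    training_accuracy = meta$training_accuracy),
    class = "fear_classifier")
}
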