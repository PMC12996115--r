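#' Closed-loop stimulus controller
#'
#' The exposure loop runs 10 iterations. Each iteration pulls the last
#' 30 s of EEG/HR, averages the classifier's signed decision distance over
#' 500-ms sub-windows, and maps that mean through fixed margins: below
#' -0.5 (relaxed side) the five-level spider stimulus is intensified,
#' above +0.5 (fear side) it is reduced, and values within the margin
#' leave the level unchanged. Levels saturate at 1 and 5.
#'
#' @name controller
NULL

# Per-level spider counts; level 5 equals the pretest maximum
# (100 floor, 100 wall, 5 web-net spiders).
.level_counts <- data.frame(
  level = 1:5,
  n_floor = c(10L, 25L, 50L, 75L, 100L),
  n_wall  = c(10L, 25L, 50L, 75L, 100L),
  n_web   = c(1L, 2L, 3L, 4L, 5L))

#' Spider stimulus template for a level
#'
#' Counts and size scale are non-decreasing in level; level 1 shows ten
#' floor spiders, ten wall spiders and one web-net spider at unit size;
#' each level increment multiplies the size by 1.10, so the template is a
#' pure function of the level (level 5: 1.1^4 ~ 1.4641).
#'
#' @param level integer in 1..5.
#' @param size_step multiplicative size increment per level; default 1.10.
#' @return a `stimulus_template`: list with `level`, `n_floor`, `n_wall`,
#'   `n_web`, `size_scale`.
#' @export
template_for_level <- function(level, size_step = 1.10) {
  if (!(level %in% 1:5)) stop("level must be in 1..5")
  row <- .level_counts[level, ]
  structure(list(level = level, n_floor = row$n_floor, n_wall = row$n_wall,
                 n_web = row$n_web, size_scale = size_step^(level - 1)),
            class = "stimulus_template")
}

#' Initialize controller state
#'
#' @param level starting stimulus level; default 1.
#' @param margins decision margins (lower, upper); default c(-0.5, 0.5).
#' @return a `controller_state` with empty history.
#' @export
controller_state <- function(level = 1L, margins = c(-0.5, 0.5)) {
  structure(list(level = as.integer(level), iteration = 0L,
                 margins = margins,
                 template = template_for_level(level),
                 history = data.frame(iteration = integer(),
                                      mean_distance = numeric(),
                                      action = character(),
                                      level = integer(),
                                      rating = integer(),
                                      stringsAsFactors = FALSE)),
            class = "controller_state")
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf("<controller_state> level %d after %d iteration(s)\n",
              x$level, x$iteration))
  if (nrow(x$history)) print(utils::tail(x$history, 3L))
  invisible(x)
}

#' Map a mean decision distance to a stimulus action
#'
#' Strictly below the lower margin (default -0.5, relaxed side) the
#' stimulus is increased; strictly above the upper margin (fear side) it
#' is decreased; anything in between -- including values exactly on a
#' margin -- keeps the level.
#'
#' @param mean_distance mean signed distance over the control window.
#' @param margins numeric length-2, `(lower, upper)`.
#' @return `"increase"`, `"decrease"`, or `"keep"`.
#' @export
decide_action <- function(mean_distance, margins = c(-0.5, 0.5)) {
  if (!is.finite(mean_distance)) stop("mean distance must be finite")
  if (mean_distance < margins[1]) "increase"
  else if (mean_distance > margins[2]) "decrease"
  else "keep"
}

#' Apply an action to the controller state
#'
#' Increase moves the level up one (clamped at 5, introducing a new spider
#' wave with 10% larger spiders); decrease moves it down one (clamped at
#' 1, removing the last wave); keep leaves it unchanged. The decision is
#' appended to the history and the iteration counter advanced.
#'
#' @param state a `controller_state`.
#' @param action `"increase"`, `"decrease"` or `"keep"`.
#' @param mean_distance distance that produced the action (for the log).
#' @param rating subjective rating 1-4, or `NA` if not collected.
#' @return updated `controller_state`.
#' @export
apply_action <- function(state, action, mean_distance = NA_real_,
                         rating = NA_integer_) {
  stopifnot(inherits(state, "controller_state"))
  action <- match.arg(action, c("increase", "decrease", "keep"))
  delta <- switch(action, increase = 1L, decrease = -1L, keep = 0L)
  state$level <- min(5L, max(1L, state$level + delta))
  state$template <- template_for_level(state$level)
  state$iteration <- state$iteration + 1L
  state$history <- rbind(state$history, data.frame(
    iteration = state$iteration, mean_distance = mean_distance,
    action = action, level = state$level,
    rating = as.integer(rating), stringsAsFactors = FALSE))
  state
}

#' Mean signed decision distance over a control window
#'
#' Runs the online chain on one 30-s window: filter + common average
#' reference (the marker-free excerpt has no baseline interval; the 1 Hz
#' high-pass removes DC), segmentation into 500-ms sub-windows,
#' calibration features per sub-window, and the mean of their signed
#' distances.
#'
#' @param model a `fear_classifier`.
#' @param window a `session_recording` slice (>= `sub_window_s` long).
#' @param sub_window_s sub-window length; default 0.5 s.
#' @param preprocess run the filtering chain first; default TRUE.
#' @return mean signed distance (positive = fear side).
#' @export
mean_window_distance <- function(model, window, sub_window_s = 0.5,
                                 preprocess = TRUE) {
  stopifnot(inherits(model, "fear_classifier"),
            inherits(window, "session_recording"))
  if (session_duration(window) < sub_window_s)
    stop("window shorter than one sub-window")
  if (preprocess) window <- preprocess_session(window, baseline_s = NULL)
  ep <- segment_windows(window$eeg, sub_window_s, overlap_fraction = 0)
  feats <- tryCatch(calibration_features(ep, window$hr),
                    error = function(e) stop("no usable data: ",
                                             conditionMessage(e)))
  ok <- stats::complete.cases(feats)
  if (!any(ok)) stop("no usable data: all sub-windows rejected")
  mean(signed_distance(model, feats[ok, , drop = FALSE]))
}

#' Agreement between a controller action and a subjective rating
#'
#' Ratings use the 4-point finger scale (1 no fear, 2 little fear,
#' 3 moderate fear, 4 high fear). An increase is correct for ratings 1-2,
#' a decrease for ratings 3-4, and a keep for ratings 2-3.
#'
#' @param action `"increase"`, `"decrease"` or `"keep"`.
#' @param rating integer 1-4.
#' @return logical.
#' @export
rating_agreement <- function(action, rating) {
  action <- match.arg(action, c("increase", "decrease", "keep"))
  if (!(is.numeric(rating) && rating %in% 1:4))
    stop("rating must be an integer in 1..4")
  switch(action,
         increase = rating %in% c(1, 2),
         decrease = rating %in% c(3, 4),
         keep     = rating %in% c(2, 3))
}

#' Run the adaptive exposure loop
#'
#' Per iteration: pull a 30-s window from the source, average the signed
#' decision distance, decide, apply, and -- when the source is a virtual
#' participant -- feed the new level back into the participant model.
#' Deterministic given the participant's seed.
#'
#' @param source either a `session_recording` (replayed in consecutive
#'   `exposure_s` slices) or a `virtual_participant` (closed loop).
#' @param model a trained `fear_classifier`.
#' @param n_iter number of loop iterations; default 10.
#' @param exposure_s window length per iteration; default 30 s.
#' @param initial_level starting level; default 1.
#' @return final `controller_state`; the decision log is in `$history`.
#'   For a virtual participant the per-iteration ground truth (fear,
#'   rating) is attached as attribute `"ground_truth"`. If a replayed
#'   session is exhausted early, the partial log carries attribute
#'   `"terminated" = TRUE`.
#' @export
run_adaptive_loop <- function(source, model, n_iter = 10, exposure_s = 30,
                              initial_level = 1L) {
  stopifnot(inherits(model, "fear_classifier"))
  state <- controller_state(initial_level)
  is_vp <- inherits(source, "virtual_participant")
  if (!is_vp && !inherits(source, "session_recording"))
    stop("source must be a session_recording or virtual_participant")
  truth <- data.frame(iteration = integer(), level = integer(),
                      fear = numeric(), rating = integer())
  for (i in seq_len(n_iter)) {
    if (is_vp) {
      step <- participant_window(source, state$level, exposure_s)
      source <- step$participant
      win <- step$window
      rating <- step$rating
      truth <- rbind(truth, data.frame(iteration = i, level = state$level,
                                       fear = step$fear, rating = rating))
    } else {
      t0 <- (i - 1) * exposure_s
      if (t0 + exposure_s > session_duration(source) + 1e-9) {
        attr(state, "terminated") <- TRUE
        break
      }
      win <- slice_session(source, t0, t0 + exposure_s)
      rating <- NA_integer_
    }
    d <- mean_window_distance(model, win)
    state <- apply_action(state, decide_action(d, state$margins), d, rating)
  }
  if (is_vp) attr(state, "ground_truth") <- truth
  state
}
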