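# Simulated level-labeled epochs shared across the offline tests.
fx_offline <- function() {
  if (is.null(.fx$offline)) {
    pp <- fx_params()
    lv <- rep(c(1L, 2L, 4L, 5L), each = 8L)
    set.seed(111)
    mats <- lapply(lv, function(l) {
      f <- plogis(pp$sensitivity * (l - pp$level_midpoint))
      simulate_eeg(f, pp, 4)$samples
    })
    arr <- array(unlist(mats), dim = c(32, 2000, length(lv)),
                 dimnames = list(montage_labels(), NULL, NULL))
    ep <- structure(list(epochs = arr, onsets_s = 4 * (seq_along(lv) - 1),
                         fs_hz = 500, channel_labels = montage_labels(),
                         window_s = 4),
                    class = "epoch_set")
    .fx$offline <- list(epochs = ep, levels = lv,
                        X = offline_features(ep),
                        y = make_binary_labels(lv))
  }
  .fx$offline
}

test_that("epoch rejection drops only epochs exceeding the voltage threshold", {
  fx <- fx_offline()
  clean <- reject_epochs(fx$epochs)
  expect_equal(n_epochs(clean), n_epochs(fx$epochs))

  spiked <- fx$epochs
  spiked$epochs[5, 300, 7] <- 500
  kept <- reject_epochs(spiked, 200)
  expect_identical(which(!attr(kept, "kept")), 7L)

  expect_equal(n_epochs(reject_epochs(spiked, Inf)), n_epochs(spiked))
  tiny <- fx$epochs
  expect_error(reject_epochs(tiny, 0), "no epochs survive")
})

test_that("binary labels pool levels 1-2 and 4-5 and exclude level 3", {
  expect_identical(make_binary_labels(c(1, 2, 3, 4, 5)),
                   c("low", "low", NA, "high", "high"))
  expect_warning(lab <- make_binary_labels(rep(3, 4)), "empty labeled set")
  expect_true(all(is.na(lab)))
  lv <- c(1, 1, 2, 4, 5, 5, 3)
  lab2 <- make_binary_labels(lv)
  expect_equal(sum(lab2 == "low", na.rm = TRUE), sum(lv %in% 1:2))
  expect_equal(sum(lab2 == "high", na.rm = TRUE), sum(lv %in% 4:5))
  expect_error(make_binary_labels(c(0, 1)), "levels must be")
})

test_that("nested CV is perfect on separable data and at chance under permutation", {
  fx <- fx_offline()
  rep_svm <- nested_cv_classify(fx$X, fx$y, "svm", "psd+faa", seed = 1)
  expect_equal(rep_svm$accuracy_mean, 100)
  expect_equal(rep_svm$accuracy_sd, 0)

  # permutation null on FAA-only features (small and fast)
  accs <- vapply(1:6, function(s) {
    set.seed(1000 + s)
    yperm <- sample(fx$y)
    nested_cv_classify(fx$X, yperm, "svm", "faa", seed = s)$accuracy_mean
  }, 0)
  expect_lt(abs(mean(accs) - 50), 15)
})

test_that("simulated data keep the band-power features at least as informative as FAA", {
  fx <- fx_offline()
  wins <- vapply(1:3, function(s) {
    psd <- nested_cv_classify(fx$X, fx$y, "svm", "psd", seed = s)
    faa <- nested_cv_classify(fx$X, fx$y, "svm", "faa", seed = s)
    psd$accuracy_mean >= faa$accuracy_mean
  }, TRUE)
  expect_gte(sum(wins), 2L)
})

test_that("cross-validation does not leak scaling or label information", {
  # pure-noise features with random labels must stay near chance for
  # every algorithm; leakage of fold statistics would inflate this
  set.seed(121)
  X <- matrix(rnorm(60 * 10), 60, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- rep(c("low", "high"), each = 30)
  for (alg in c("svm", "rf", "xgb")) {
    acc <- nested_cv_classify(X, y, alg, "psd+faa", seed = 4)$accuracy_mean
    expect_lt(acc, 75)
    expect_gt(acc, 25)
  }
})

test_that("feature importance surfaces planted signals", {
  set.seed(131)
  n <- 80
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- rep(c("low", "high"), each = n / 2)
  X[y == "high", 3] <- X[y == "high", 3] + 3
  rf <- nested_cv_classify(X, y, "rf", "psd+faa", seed = 5)
  expect_identical(names(rf$importance)[1], "f3")

  # duplicated informative feature: both copies rank in the top 3
  X2 <- cbind(X, f3dup = X[, 3])
  rf2 <- nested_cv_classify(X2, y, "rf", "psd+faa", seed = 5)
  expect_true(all(c("f3", "f3dup") %in% names(rf2$importance)[1:3]))

  # unstable ranks on pure noise: top feature varies across seeds
  set.seed(141)
  Xn <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("g", 1:8)))
  tops <- vapply(1:4, function(s)
    names(nested_cv_classify(Xn, sample(y), "rf", "psd+faa",
                             seed = s)$importance)[1], "")
  expect_gt(length(unique(tops)), 1L)
})

test_that("grand-average topographies reflect level-dependent band shifts", {
  fx <- fx_offline()
  suppressWarnings(tm <- grand_average_topomap(fx$epochs, fx$levels))
  expect_equal(dim(tm), c(5L, 5L, 32L))
  expect_true(all(is.na(tm["level3", , ])))  # unvisited level

  frontal <- grepl("^F", montage_labels())
  theta_by_level <- rowMeans(tm[c(1, 2, 4, 5), "theta", frontal])
  alpha_by_level <- rowMeans(tm[c(1, 2, 4, 5), "alpha", ])
  expect_true(all(diff(theta_by_level) > 0))  # frontal theta rises with fear
  expect_true(all(diff(alpha_by_level) < 0))  # alpha suppressed with fear

  same <- fx$epochs
  for (k in seq_len(n_epochs(same))) same$epochs[, , k] <- same$epochs[, , 1]
  suppressWarnings(tm2 <- grand_average_topomap(same, fx$levels))
  expect_equal(tm2["level1", , ], tm2["level5", , ])
})

test_that("pairwise level statistics control type I error and detect shifts", {
  # identical distributions: significant pairs rare across seeded runs
  set.seed(151)
  any_sig <- vapply(1:200, function(i) {
    st <- level_stats(rnorm(50, 72, 1), rep(1:5, each = 10))
    any(st$significant, na.rm = TRUE)
  }, TRUE)
  expect_gte(mean(!any_sig), 0.95)

  # planted 2-bpm shift at one level, n = 40 per level: power >= 0.8
  set.seed(152)
  hits <- vapply(1:50, function(i) {
    v <- c(rnorm(40, 72, 1), rnorm(40, 72, 1), rnorm(40, 74, 1))
    st <- level_stats(v, rep(1:3, each = 40))
    all(st$significant[st$group_a == 1 & st$group_b == 3],
        st$significant[st$group_a == 2 & st$group_b == 3])
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  # degenerate variance pair is flagged undefined
  st <- level_stats(c(rep(1, 5), rep(1, 5), rnorm(5)), rep(1:3, each = 5))
  expect_true(is.na(st$statistic[st$group_a == 1 & st$group_b == 2]))
})

test_that("the 30-s HR averaging yields one value per loop iteration", {
  ses <- simulate_session(fx_params(), "main", seed = 16)
  means <- hr_window_means(ses)
  expect_length(means, 10L)
  expect_false(anyNA(means))
  expect_true(all(means > 40 & means < 120))
})

test_that("correlation matrices mask non-significant pairs after BH", {
  set.seed(161)
  n <- 21
  x <- rnorm(n)
  df <- data.frame(a = x, b = 2 * x + rnorm(n, 0, 1e-6), c = rnorm(n))
  cm <- correlation_matrix(df)
  expect_equal(cm$r["a", "a"], 1)
  expect_gt(cm$r["a", "b"], 0.999)
  expect_true(cm$significant["a", "b"])
  expect_false(is.na(cm$r_masked["a", "b"]))

  # independent Gaussian pair: masked in at least 90% of seeded runs
  set.seed(162)
  masked <- vapply(1:40, function(i) {
    d <- data.frame(u = rnorm(n), v = rnorm(n))
    is.na(correlation_matrix(d)$r_masked["u", "v"])
  }, TRUE)
  expect_gte(mean(masked), 0.9)

  expect_warning(correlation_matrix(data.frame(a = rnorm(5), z = rep(1, 5))),
                 "zero-variance")
})

test_that("BH step-up matches stats::p.adjust and flags by the classic rule", {
  bh <- benjamini_hochberg(c(0.01, 0.02, 0.03))
  expect_true(all(bh$rejected))
  expect_false(any(benjamini_hochberg(rep(1, 6))$rejected))
  expect_true(benjamini_hochberg(0.04)$rejected)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")

  set.seed(171)
  for (i in 1:200) {
    m <- sample(1:12, 1)
    p <- round(runif(m), 3)
    got <- benjamini_hochberg(p)
    expect_identical(got$rejected, bf_benjamini_hochberg(p))
    expect_equal(got$p_adjusted, p.adjust(p, method = "BH"))
  }
})
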