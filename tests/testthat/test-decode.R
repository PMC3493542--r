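# independent oracle for the binomial tail: exact coefficient sums
tail_sum_oracle <- function(t, n, k) {
  if (k > n) return(0)
  sum(choose(n, k:n) * (1 / t)^(k:n) * (1 - 1 / t)^(n - (k:n)))
}

test_that("cross-validated DA is exact on deterministic toy data", {
  # perfectly separable features
  set.seed(1)
  x <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 10, 0.1), 10))
  y <- rep(c("a", "b"), each = 10)
  cv <- cross_validated_da(x, y, folds = 5, repeats = 3, lambda = 0.1,
                           seed = 2)
  expect_equal(cv$da, 100)

  # {0,0,1,1} with 2-fold stratified CV: every split trains on one point
  # per class and tests the other, always correctly (exhaustive check)
  x2 <- matrix(c(0, 0, 1, 1), 4, 1)
  y2 <- c("A", "A", "B", "B")
  cv2 <- cross_validated_da(x2, y2, folds = 2, repeats = 5, lambda = 1,
                            seed = 3)
  expect_equal(cv2$da, 100)
  expect_equal(cv2$per_repeat, rep(100, 5))

  expect_error(cross_validated_da(x2, y2, folds = 5), "folds")
})

test_that("shuffled labels decode at chance within the binomial band", {
  set.seed(7)
  for (t_cls in c(2, 4)) {
    n <- 60
    x <- matrix(rnorm(n * 6), n)
    y <- sample(rep(letters[1:t_cls], n / t_cls))
    cv <- cross_validated_da(x, y, folds = 10, repeats = 10, lambda = 0.25,
                             seed = 11 + t_cls)
    # 99% band of the guessing distribution, on the accuracy scale
    band <- 100 * qbinom(c(0.005, 0.995), n, 1 / t_cls) / n
    expect_gte(cv$da, band[1])
    expect_lte(cv$da, band[2])
  }
})

test_that("binomial tail probabilities match exact sums and simulation", {
  expect_equal(binomial_p(2, 10, 0), 1)
  expect_equal(binomial_p(2, 10, 8), 56 / 1024)       # 45 + 10 + 1 coefficients
  expect_equal(binomial_p(4, 4, 4), (1 / 4)^4)        # 0.00390625

  for (t_cls in c(2, 4)) for (n in c(10, 60, 240)) {
    ks <- unique(round(seq(0, n, length.out = 7)))
    for (k in ks) {
      expect_equal(binomial_p(t_cls, n, k), tail_sum_oracle(t_cls, n, k),
                   tolerance = 1e-12)
    }
    # monotone non-increasing in k
    p <- binomial_p(t_cls, n, 0:n)
    expect_true(all(diff(p) <= 1e-15))
  }

  # Monte-Carlo guessing agreement within 3 standard errors
  set.seed(8)
  draws <- 1e5
  for (case in list(c(2, 30, 20), c(4, 40, 15))) {
    t_cls <- case[1]; n <- case[2]; k <- case[3]
    sim <- mean(rbinom(draws, n, 1 / t_cls) >= k)
    p <- binomial_p(t_cls, n, k)
    se <- sqrt(p * (1 - p) / draws)
    expect_lt(abs(sim - p), 3 * se + 1e-12)
  }

  # large n remains finite and ordered
  p_big <- binomial_p(2, 10000, c(0, 5000, 5200, 10000))
  expect_true(all(is.finite(p_big)) && all(p_big >= 0) && all(p_big <= 1))
  expect_true(all(diff(p_big) < 0))

  expect_error(binomial_p(1, 10, 2), "invalid")
  expect_error(binomial_p(2, 10, 11), "invalid")
})

test_that("significance level is the smallest significant accuracy", {
  # alpha = 1: every count is 'significant', so the level is 0
  expect_equal(significance_level(2, 60, alpha = 1), 0)

  # exhaustive scan oracle at t=2, n=60, alpha=0.05
  p <- sapply(0:60, function(k) tail_sum_oracle(2, 60, k))
  k_star <- which(p <= 0.05)[1] - 1
  expect_equal(significance_level(2, 60, 0.05), 100 * k_star / 60)

  # non-increasing in n at fixed alpha
  ls <- sapply(c(20, 40, 60, 120, 240, 600), function(n)
    significance_level(2, n, 0.05))
  expect_true(all(diff(ls) <= 1e-12))

  # tiny n where nothing reaches significance
  expect_equal(significance_level(2, 2, 0.05), 100)
})

test_that("peak extraction smooths, windows and tests the DA curve", {
  fs <- 7.94
  tt <- seq(-6, 35, by = 1 / fs)
  flat <- da_curve(tt, rep(50, length(tt)), n_trials = 60, t_classes = 2,
                   alpha = 0.001)
  res <- max_da(flat, fs)
  expect_equal(res$da, 50, tolerance = 1e-6)
  expect_equal(res$time, tt[tt >= 5][1])          # first window sample
  expect_equal(res$p, binomial_p(2, 60, 30), tolerance = 1e-6)
  expect_false(res$significant)

  # a one-sample spike is attenuated by the smoothing
  spiky <- rep(50, length(tt)); spiky[160] <- 100
  sp <- max_da(da_curve(tt, spiky, n_trials = 60), fs)
  expect_lt(sp$da, 100)
  expect_gt(sp$da, 50)

  # monotone curve: the smoothed max sits at the window's right edge
  mono <- da_curve(tt, seq(40, 90, length.out = length(tt)), n_trials = 60)
  mm <- max_da(mono, fs)
  expect_equal(mm$time, max(tt[tt <= 20]))

  expect_error(max_da(flat, fs, window = c(100, 120)), "window")
})

test_that("Benjamini-Hochberg flags match the step-up procedure by hand", {
  expect_equal(fdr_correct(rep(1, 5)), rep(FALSE, 5))
  # p = {0.001, 0.002, 0.9}: adjusted {0.003, 0.003, 0.9} -> two rejections
  expect_equal(fdr_correct(c(0.001, 0.002, 0.9), q = 0.05),
               c(TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(0.03, q = 0.05), TRUE)
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
})

test_that("peak-DA table applies FDR across subjects", {
  fs <- 7.94
  tt <- seq(-6, 35, by = 1 / fs)
  good <- da_curve(tt, ifelse(tt > 5 & tt < 20, 95, 50), n_trials = 60)
  flat <- da_curve(tt, rep(50, length(tt)), n_trials = 60)
  tab <- max_da_table(list(good, good, flat), fs = fs)
  expect_equal(tab$fdr_significant, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(tab), 3)
})

test_that("subset analysis grows toward the full-set accuracy", {
  set.seed(9)
  # one informative channel among noise
  ntr <- 40
  hbo <- array(rnorm(ntr * 6 * 5), c(ntr, 6, 5))
  labels <- rep(c("left", "down"), each = ntr / 2)
  hbo[labels == "left", 3, ] <- hbo[labels == "left", 3, ] + 2.5
  co <- structure(list(hbo = hbo, hbr = -0.3 * hbo,
                       valid_channel = rep(TRUE, 6), time = 0:4,
                       labels = labels, fs = 1, baseline = c(-1, 0)),
                  class = "conc_epochs")
  full <- cross_validated_da(hbo[, , 3], labels, folds = 5, repeats = 5,
                             lambda = 0.25, seed = 1)
  rnd <- subset_analysis(co, pool = 1:6, time_point = 2, sizes = c(1, 6),
                         mode = "random", reps = 8, folds = 5, repeats = 2,
                         seed = 2)
  bst <- subset_analysis(co, pool = 1:6, time_point = 2, sizes = c(1, 6),
                         mode = "best_first", folds = 5, repeats = 2,
                         rank_repeats = 4, seed = 3)
  # at full size both modes match the full-set DA (up to CV resampling)
  expect_lt(abs(rnd$da[2] - full$da), 8)
  expect_lt(abs(bst$da[2] - full$da), 8)
  # best-first finds the informative channel immediately
  expect_equal(attr(bst, "ranking")[1], 3)
  expect_gt(bst$da[1], rnd$da[1] + 5)

  expect_warning(subset_analysis(co, 1:6, 2, sizes = c(2, 10), mode = "random",
                                 reps = 2, folds = 5, repeats = 1, seed = 1),
                 "clipped")
})

test_that("distance profile normalises counts by recorded channels", {
  channels <- data.frame(distance = c(rep(1.2, 10), rep(3.2, 10)))
  pool <- 1:20
  # top 10 all in the 3-4.5 bin
  das <- c(rep(50, 10), rep(90, 10))
  prof <- distance_profile(das, pool, channels, top_k = 10,
                           breaks = c(0, 2, 4, 6))
  expect_equal(prof$count, c(0, 10, 0))
  expect_equal(prof$total, c(10, 10, 0))
  expect_equal(prof$likelihood, c(0, 1, NA))
  # all channels in one bin: likelihood top_k / total
  prof2 <- distance_profile(das[1:10], 1:10, channels[1:10, , drop = FALSE],
                            top_k = 4, breaks = c(0, 2))
  expect_equal(prof2$likelihood, 0.4)
  expect_warning(distance_profile(das[1:5], 1:5,
                                  channels[1:5, , drop = FALSE], top_k = 10,
                                  breaks = c(0, 2)),
                 "top_k")
})
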