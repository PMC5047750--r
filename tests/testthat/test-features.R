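test_that("channel scaling is the ratio of averaged-trace maxima", {
  shape <- c(0, 20, 60, 100, 80, 40)
  A <- rbind(shape * 0.9, shape * 1.1)           # averaged max 100
  B <- A * 1.52                                  # averaged max 152
  sc <- compute_scaling_factor(A, B)
  expect_equal(sc$factor, 1.52, tolerance = 1e-12)
  expect_equal(compute_scaling_factor(A, A)$factor, 1)
  expect_equal(compute_scaling_factor(A, 2 * A)$factor, 2)
  # round trip is exact
  v <- c(1.3, 7.7, 42)
  expect_identical(apply_scaling(sc, apply_scaling(sc, v), inverse = TRUE), v)
  expect_error(compute_scaling_factor(A, -A), "positive")
  expect_error(compute_scaling_factor(A, B[, -1]), "grid")
})

test_that("peak_level takes the in-window maximum only", {
  tm <- seq(0, 8, by = 2)
  expect_equal(peak_level(c(0, 5, 10, 7, 3), tm, c(0, 8)), 10)
  expect_equal(peak_level(rep(4.2, 5), tm, c(0, 8)), 4.2)
  tm2 <- seq(0, 60, by = 2)
  tr <- dnorm(tm2, mean = 40, sd = 5)            # global max at 40 min
  inwin <- max(tr[tm2 <= 30])                    # brute-force oracle
  expect_equal(peak_level(tr, tm2, c(0, 30)), inwin)
  expect_lt(peak_level(tr, tm2, c(0, 30)), max(tr))
  expect_error(peak_level(tr, tm2, c(100, 120)), "window")
})

test_that("auc is the plain sample sum and is window-additive", {
  tm <- seq(0, 30, by = 2)
  expect_equal(auc(rep(1, 16), tm, c(0, 30)), 16)
  expect_equal(auc(rep(0, 16), tm, c(0, 30)), 0)
  set.seed(42)
  for (i in 1:20) {
    tr <- runif(91)
    full <- auc(tr, std_times, c(0, 180))
    split <- auc(tr, std_times, c(0, 58)) + auc(tr, std_times, c(60, 180))
    expect_equal(full, split, tolerance = 1e-12)
  }
  # the 30-min stress window sums exactly the first-30-min samples
  tr <- seq_len(91)
  expect_equal(auc(tr, std_times, c(0, 30)), sum(tr[1:16]))
})

test_that("half-max times interpolate crossings correctly", {
  tm <- seq(0, 40, by = 2)
  ramp <- pmin(tm / 10, 1) * 8                   # linear 0 -> max over 10 min
  expect_equal(half_max_times(ramp, tm, 0)$t_half_import_min, 5)
  tf_ <- seq(0, 40, by = 0.01)                   # ideal step at t0 = 10,
  step <- ifelse(tf_ >= 10, 3, 0)                # densely sampled
  expect_equal(half_max_times(step, tf_, 0)$t_half_import_min, 10,
               tolerance = 0.01)
  tau <- 6
  expo <- 1 - exp(-tm / tau)                     # closed form: tau*ln 2
  expect_equal(half_max_times(expo, tm, 0)$t_half_import_min, tau * log(2),
               tolerance = 0.05)
  # export: decay after offset crosses half-max going down
  tr <- c(rep(10, 11), 10 * exp(-(tm[12:21] - 20) / 4))
  hm <- half_max_times(tr, tm, 0, offset_min = 20)
  expect_equal(hm$t_half_export_min, 20 + 4 * log(2), tolerance = 0.2)
  expect_lt(hm$t_half_import_min, hm$t_half_export_min)
  # sustained input: export flagged as NA
  expect_true(is.na(half_max_times(rep(5, 21), tm, 0)$t_half_export_min))
  expect_error(half_max_times(rep(0, 21), tm, 0), "positive maximum")
})

test_that("ensemble stats match hand computation and scale correctly", {
  tm <- c(0, 2, 4)
  traces <- rbind(c(0, 8, 1), c(0, 10, 2), c(0, 12, 3))
  es <- ensemble_stats(traces, tm)
  expect_equal(es$peak_time_of_mean, 2)
  expect_equal(es$mean_trace[2], 10)
  expect_equal(es$sd_at_peak, 2)                 # n-1 denominator
  expect_equal(es$cv_at_peak, 0.2)

  expect_equal(ensemble_stats(rbind(c(1, 5), c(1, 5)), c(0, 2))$cv_at_peak, 0)

  es7 <- ensemble_stats(7 * traces, tm)
  expect_equal(es7$cv_at_peak, es$cv_at_peak)
  expect_equal(es7$sd_at_peak, 7 * es$sd_at_peak)

  esp <- ensemble_stats(traces, tm, scale_mode = "percent_of_mean_peak")
  expect_equal(max(esp$mean_trace), 100)
  expect_equal(esp$cv_at_peak, es$cv_at_peak)
  expect_error(ensemble_stats(traces[1, , drop = FALSE], tm), "2 traces")
})

test_that("expression endpoint and maximum behave as stated", {
  expect_equal(expression_endpoint(c(0, 1, 4, 9)), 9)
  expect_equal(expression_endpoint(rep(0, 5)), 0)
  mono <- cumsum(runif(30))
  expect_equal(expression_endpoint(mono),
               expression_endpoint(mono, stat = "max"))
  expect_error(expression_endpoint(numeric()), "empty")
})

test_that("compute_features assembles per-cell summaries coherently", {
  ex <- pulse_exp("slow", 30, "WT", n = 40, seed = 4)
  ft <- compute_features(ex)
  expect_equal(nrow(ft), 40)
  expect_true(all(ft$peak_msn2 > ft$peak_msn4 - 5))
  expect_true(all(ft$auc_msn2 >= 0))
  ok <- !is.na(ft$t_half_export_msn2)
  expect_true(all(ft$t_half_import_msn2[ok] < ft$t_half_export_msn2[ok]))
  # endpoint vs max agree within 3x measurement noise (on average) for a
  # plateaued stable reporter
  expect_true(all(ft$expr_max >= ft$expr_endpoint))
  expect_lt(mean(ft$expr_max - ft$expr_endpoint),
            3 * default_tf$meas_noise_sd)

  exd <- pulse_exp("slow", 30, "msn2d", n = 10, seed = 4)
  ftd <- compute_features(exd)
  expect_true(all(ftd$peak_msn2 == 0))
  expect_true(all(is.na(ftd$t_half_import_msn2)))
})
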