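test_that("zero-phase low-pass preserves DC and attenuates high frequencies", {
  fc <- fit_config(lowpass_cutoff = 0.2, lowpass_order = 4)

  const <- bf_trace(rep(3.5, 32 * 60), fs = 32, t_release = 10)
  out <- lowpass(const, fc)
  expect_equal(out$flux, const$flux, tolerance = 1e-9)
  expect_equal(length(out$flux), length(const$flux))

  # 1 Hz sinusoid (5x cutoff) attenuated more than 10-fold
  t <- (0:(32 * 60 - 1)) / 32
  sine <- bf_trace(5 + sin(2 * pi * 1 * t), fs = 32, t_release = 10)
  filt <- lowpass(sine, fc)
  mid <- filt$flux[t > 10 & t < 50] - 5
  expect_lt(max(abs(mid)), 1 / 10)

  # filtering brings a noisy synthetic trace closer to its clean curve
  cfg <- synth_config("CTRL", fs = 32, baseline_duration = 60,
                      occlusion_duration = 60, post_duration = 240,
                      noise_sd = 0.1,
                      flowmotion = list(c(1, 0.2)))
  tr <- synth_trace(cfg, seed = 4)
  truth <- attr(tr, "truth")
  sm <- lowpass(tr, fc)
  post_raw <- crop_post_release(tr, 200)
  post_sm <- crop_post_release(sm, 200)
  clean <- predict(truth$step_response, post_raw$t)
  expect_lt(sqrt(mean((post_sm$flux - clean)^2)),
            sqrt(mean((post_raw$flux - clean)^2)))

  expect_error(lowpass(const, fit_config(lowpass_cutoff = 20)), "Nyquist")
})

test_that("post-release cropping re-times the window", {
  x <- bf_trace(seq_len(100) / 10, fs = 1, t_release = 40)
  cr <- crop_post_release(x, 30)
  expect_equal(cr$t[1], 0)
  expect_equal(max(cr$t), 30)
  expect_equal(cr$flux[1], x$flux[41])
  expect_equal(cr$t_release, 0)

  # full remaining record is the identity on that segment
  full <- crop_post_release(x, 59)
  expect_equal(full$flux, x$flux[41:100])

  # release at the last sample leaves nothing to crop
  y <- bf_trace(1:10, fs = 1, t_release = 9)
  expect_error(crop_post_release(y, 5), "insufficient")
})

test_that("group averaging is idempotent, symmetric and group-safe", {
  base <- bf_trace(sin(seq(0, 5, by = 0.05)) + 2, fs = 20, t_release = 0)
  six <- replicate(6, base, simplify = FALSE)
  avg <- average_group(six, resample_fs = 20)
  expect_equal(avg$flux, base$flux, tolerance = 1e-9)

  delta <- 0.3 * cos(seq(0, 5, by = 0.05))
  up <- bf_trace(base$flux + delta, fs = 20, t_release = 0)
  dn <- bf_trace(base$flux - delta, fs = 20, t_release = 0)
  avg2 <- average_group(list(up, dn), resample_fs = 20)
  expect_equal(avg2$flux, base$flux, tolerance = 1e-9)

  sci <- bf_trace(base$flux, fs = 20, group = "SCI", t_release = 0)
  expect_error(average_group(list(base, sci)), "one group")
  expect_error(average_group(list()), "empty")
})

test_that("the SSE objective behaves algebraically", {
  p <- control_circuit()
  sr <- step_response(p)
  t <- seq(0, 240, by = 0.25)
  target <- bf_trace(predict(sr, t), fs = 4, t_release = 0)
  expect_equal(sse_error(p, target), 0, tolerance = 1e-18)

  shifted <- bf_trace(predict(sr, t) + 0.5, fs = 4, t_release = 0)
  expect_equal(sse_error(p, shifted), length(t) * 0.25, tolerance = 1e-8)

  # invalid parameters give the +Inf sentinel
  bad <- unclass(p); bad$c1 <- -3
  expect_identical(sse_error(bad, target), Inf)
})

test_that("the fitted circuit beats random in-bound parameter draws", {
  p <- control_circuit()
  cfg <- clean_synth_config(cv = 0.1)
  coh <- synth_cohort(cfg, n_subjects = 6, seed = 21)
  crops <- lapply(coh$traces, crop_post_release, window = 240)
  target <- average_group(crops, resample_fs = 4)

  e_ctrl <- sse_error(p, target)
  fc <- fit_config()
  set.seed(99)
  e_rand <- replicate(200, {
    draw <- fc$lower + stats::runif(6) * (fc$upper - fc$lower)
    pr <- suppressWarnings(circuit_params(draw[1], draw[2], draw[3],
                                          draw[4], draw[5], draw[6], 85))
    sse_error(pr, target)
  })
  expect_gt(mean(e_ctrl < e_rand), 0.95)
})

test_that("multistart fitting recovers the generating curve and is seeded", {
  cfg <- clean_synth_config(cv = 0)
  coh <- synth_cohort(cfg, n_subjects = 3, seed = 8)
  fc <- fit_config(n_starts = 30, seed = 2, fit_window = 240,
                   resample_fs = 4, lowpass_cutoff = NA)
  fit <- fit_group(coh$traces, fc)

  # curve recovery on noiseless data: relative L2 below 1e-3
  sr_true <- step_response(cfg$base_params)
  sr_fit <- step_response(fit$params)
  t <- seq(0, 240, by = 0.25)
  rel_l2 <- sqrt(sum((predict(sr_fit, t) - predict(sr_true, t))^2) /
                 sum(predict(sr_true, t)^2))
  expect_lt(rel_l2, 1e-3)

  # bounds respected
  pv <- unlist(fit$params)[c("r1", "r2", "r3", "r4", "c1", "c2")]
  expect_true(all(pv >= fc$lower & pv <= fc$upper))

  # best error beats random in-bound draws (monotone improvement)
  set.seed(31)
  target <- average_group(lapply(coh$traces, crop_post_release,
                                 window = 240),
                          resample_fs = 4)
  for (i in 1:20) {
    draw <- fc$lower + stats::runif(6) * (fc$upper - fc$lower)
    pr <- suppressWarnings(circuit_params(draw[1], draw[2], draw[3],
                                          draw[4], draw[5], draw[6], 85))
    expect_lte(fit$error, sse_error(pr, target) + 1e-12)
  }

  # determinism under the seed
  fit2 <- fit_group(coh$traces, fc)
  expect_identical(unlist(fit$params), unlist(fit2$params))
  expect_identical(fit$error, fit2$error)
})

test_that("subject fits are optimal against the generator and survive zeros", {
  cfg <- synth_config("CTRL", fs = 8, baseline_duration = 60,
                      occlusion_duration = 60, post_duration = 300,
                      noise_sd = 0.05, flowmotion = list(c(0.1, 0.03)))
  tr <- synth_trace(cfg, seed = 14)
  fc <- fit_config(n_starts = 20, seed = 3)
  fit <- fit_subject(tr, fc)

  # the fit can only improve on the generator's own parameters
  target <- average_group(list(crop_post_release(lowpass(tr, fc), 240)),
                          resample_fs = 4)
  expect_lte(fit$error, sse_error(cfg$base_params, target))

  # degenerate all-zero trace: finite result with a warning
  zero <- bf_trace(rep(0, 8 * 400), fs = 8, t_release = 100)
  expect_warning(fz <- fit_subject(zero, fit_config(n_starts = 4, seed = 1)),
                 "degenerate")
  expect_true(is.finite(fz$error))
  expect_lt(steady_state(fz$params), steady_state(control_circuit()))
})

test_that("the SCI configuration inherits control compliance caps", {
  ctrl_fit <- structure(list(params = control_circuit()),
                        class = "fit_result")
  sci_cfg <- sci_bounds_from_control(ctrl_fit, fit_config())
  expect_equal(unname(sci_cfg$upper["c1"]), 69.28)
  expect_equal(unname(sci_cfg$upper["c2"]), 14.45)
  expect_equal(sci_cfg$v0_fixed, 75)

  at_bound <- structure(list(params = suppressWarnings(
    circuit_params(1, 1, 1, 200, 200, 200, 85))), class = "fit_result")
  cfg2 <- sci_bounds_from_control(at_bound, fit_config())
  expect_equal(unname(cfg2$upper[c("c1", "c2")]), c(200, 200))
})

test_that("fit results round-trip through JSON", {
  cfg <- clean_synth_config()
  fit <- fit_group(list(synth_trace(cfg, seed = 1)),
                   fit_config(n_starts = 4, seed = 9))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_result(fit, path)
  back <- read_fit_result(path)
  expect_equal(unlist(back$params), unlist(fit$params))
  expect_equal(back$error, fit$error)
  expect_equal(back$seed, 9)
})
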