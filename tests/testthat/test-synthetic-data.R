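test_that("motion model validates its parameters", {
  expect_error(motion_model_params(0), class = "iconqa_parameter_error")
  expect_error(motion_model_params(10, sample_interval_ms = -1),
               class = "iconqa_parameter_error")
  expect_error(motion_model_params(10, walk_sigma_mm = c(-0.1, 0, 0)),
               class = "iconqa_parameter_error")
  expect_error(gating_config(threshold_mm = 0.1, record_trigger_mm = 0.2),
               class = "iconqa_parameter_error")
})

test_that("zero motion gives an identically zero trace and zero statistics", {
  p <- motion_model_params(60, 100)
  tr <- simulate_motion_trace(p)
  expect_true(all(tr$x_mm == 0 & tr$y_mm == 0 & tr$z_mm == 0))
  expect_true(!is.unsorted(tr$t_s, strictly = TRUE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_hdmm_log(tr, gating_config(), f)
  s <- parse_hdmm_log(f)
  a <- session_auc(s)
  expect_identical(a$mean_radial_mm, 0)
  expect_identical(c(a$mean_x_mm, a$mean_y_mm, a$mean_z_mm), c(0, 0, 0))
  expect_identical(post_cbct_residuals(list(s))$vec_mean, 0)
})

test_that("linear drift accumulates as rate times time", {
  p <- motion_model_params(600, 100, drift_mm_per_min = c(0, 0, 0.5))
  tr <- simulate_motion_trace(p)
  expect_equal(tr$z_mm[nrow(tr)], 5.0, tolerance = 1e-12)
  expect_equal(tr$z_mm[tr$t_s == 60], 0.5, tolerance = 1e-12)
  expect_true(all(tr$x_mm == 0))
})

test_that("random walk displacement SD matches the closed form", {
  n_steps <- 1000L
  sig <- 0.05
  finals <- vapply(1:150, function(i) {
    p <- motion_model_params(n_steps * 0.1, 100,
                             walk_sigma_mm = rep(sig, 3), seed = 1000L + i)
    tr <- simulate_motion_trace(p)
    unlist(tr[nrow(tr), c("x_mm", "y_mm", "z_mm")])
  }, numeric(3))
  sd_true <- sig * sqrt(n_steps)           # Var(sum of n iid steps) = n sigma^2
  se_sd <- sd_true / sqrt(2 * (ncol(finals) - 1))
  for (ax in 1:3)
    expect_lt(abs(sd(finals[ax, ]) - sd_true), 3 * se_sd)
})

test_that("seeded generation is bit-reproducible", {
  p <- motion_model_params(30, 100, walk_sigma_mm = rep(0.05, 3),
                           drift_mm_per_min = c(0.1, 0, 0.2), seed = 99L)
  expect_identical(simulate_motion_trace(p), simulate_motion_trace(p))
  t1 <- make_component_table("random_small", seed = 5)
  t2 <- make_component_table("random_small", seed = 5)
  expect_identical(t1, t2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(d1, n_sessions = 2,
                        duration_range_min = c(1, 2), seed = 3)
  s2 <- simulate_cohort(d2, n_sessions = 2,
                        duration_range_min = c(1, 2), seed = 3)
  expect_identical(s1$truth, s2$truth)
  expect_identical(readLines(s1$files[1]), readLines(s2$files[1]))
})

test_that("constant zero trace logs only baseline and end rows", {
  tr <- simulate_motion_trace(motion_model_params(10, 100))
  f <- withr::local_tempfile(fileext = ".csv")
  recs <- write_hdmm_log(tr, gating_config(), f)
  expect_identical(recs$event, c("baseline", "end"))
  expect_true(all(recs$radial_mm == 0))
})

test_that("a 0.3 mm radial step emits exactly one record once the window catches up", {
  # hand-simulated: 100 ms sampling, 500 ms window (k = 5); x steps 0 -> 0.3
  # at sample 6, so the windowed radial ramps 0.06, 0.12, 0.18, 0.24, 0.30;
  # the 0.2 mm trigger (change from last emitted record) first fires at the
  # 0.24 sample (t = 0.8 s) and never again
  n <- 15
  tr <- data.frame(t_s = (0:(n - 1)) * 0.1,
                   x_mm = c(rep(0, 5), rep(0.3, n - 5)),
                   y_mm = 0, z_mm = 0)
  class(tr) <- c("motion_trace", "data.frame")
  f <- withr::local_tempfile(fileext = ".csv")
  recs <- write_hdmm_log(tr, gating_config(), f)
  expect_identical(recs$event, c("baseline", "record", "end"))
  body <- recs[recs$event == "record", ]
  expect_equal(body$t_s, 0.8)
  expect_equal(body$radial_mm, 0.24)
  expect_equal(body$x_mm, 0.3)
})

test_that("sustained excursions beyond the threshold are flagged paused", {
  p <- motion_model_params(300, 100, drift_mm_per_min = c(0, 0, 1))
  tr <- simulate_motion_trace(p)  # crosses 1.5 mm at 90 s, stays out
  f <- withr::local_tempfile(fileext = ".csv")
  recs <- write_hdmm_log(tr, gating_config(), f)
  expect_true(any(recs$state == "paused"))
  expect_true(all(recs$state[recs$radial_mm > 1.5] == "paused"))
  # the state change itself is recorded so gating timing is recoverable
  flips <- which(recs$state[-1] != recs$state[-nrow(recs)])
  expect_true(length(flips) >= 1)
})

test_that("paper_table2 preset carries the printed component rows", {
  tab <- make_component_table("paper_table2", quiet = TRUE)
  expect_identical(nrow(tab), 11L)
  mri <- tab[tab$name == "MRI Distortion", ]
  expect_equal(mri$vec_mean, 0.63)
  expect_equal(mri$vec_sd, 0.18)
  expect_identical(mri$error_type, "systematic")
  expect_identical(mri$class, "B")
  mot <- tab[tab$name == "Motion During Treatment", ]
  expect_equal(mot$vec_mean, 0.72)
  expect_equal(mot$vec_sd, 0.24)
  expect_identical(mot$error_type, "random")
  # CBCT stability reads out radially only: axis cells absent, not zero
  expect_true(all(is.na(tab[tab$name == "CBCT Stability",
                            c("x_mean", "y_mean", "z_mean")])))
  expect_message(make_component_table("paper_table2"), "0.13")
  expect_error(make_component_table("no_such_preset"))
})

test_that("offset fixture returns the exact displacement and ground truth", {
  fx <- make_offset_fixture(c(60, 60, 0))
  expect_equal(fiducial_coords(fx$displaced) - fiducial_coords(fx$reference),
               matrix(rep(c(60, 60, 0), each = 7), ncol = 3),
               ignore_attr = TRUE)
  expect_equal(fx$transform$translation, c(60, 60, 0))
  fx0 <- make_offset_fixture(c(0, 0, 0))
  expect_equal(fx0$transform$rotation, diag(3))
  expect_equal(fx0$transform$translation, c(0, 0, 0))
  expect_identical(fiducial_coords(fx0$displaced),
                   fiducial_coords(fx0$reference))
  # noisy displacement stays within 5 x noise of the exact offset per axis
  fxn <- make_offset_fixture(c(10, -5, 2), noise_mm = 0.1, seed = 11)
  dev <- fiducial_coords(fxn$displaced) - fiducial_coords(fxn$reference) -
    matrix(rep(c(10, -5, 2), each = 7), ncol = 3)
  expect_true(all(abs(dev) <= 0.5))
  expect_error(make_offset_fixture(c(0, 0, 0), noise_mm = -1),
               class = "iconqa_parameter_error")
})
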