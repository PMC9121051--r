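test_that("write -> parse round-trips every record field exactly", {
  p <- motion_model_params(120, 100, drift_mm_per_min = c(0.05, -0.1, 0.4),
                           walk_sigma_mm = rep(0.01, 3),
                           baseline_offset_mm = c(-0.09, 0.06, 0.06),
                           seed = 21L)
  tr <- simulate_motion_trace(p)
  f <- withr::local_tempfile(fileext = ".csv")
  recs <- write_hdmm_log(tr, gating_config(), f, session_id = "rt")
  s <- parse_hdmm_log(f)
  expect_identical(s$id, "rt")
  expect_identical(length(s$segments), 1L)
  expect_identical(s$segments[[1]]$trace, recs)
  expect_equal(s$segments[[1]]$residual, c(-0.09, 0.06, 0.06))
  expect_equal(s$gating$threshold_mm, 1.5)
  # rewrite of the parsed records is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  con <- file(f2, "w")
  writeLines(readLines(f)[1:5], con)
  utils::write.csv(s$segments[[1]]$trace, con, row.names = FALSE,
                   quote = FALSE)
  close(con)
  expect_identical(readLines(f2), readLines(f))
})

test_that("the phantom fixture baseline keeps the documented radial/xyz asymmetry", {
  s <- parse_hdmm_log(extdata("iroc_phantom_synthetic.csv"))
  expect_equal(s$segments[[1]]$residual, c(-0.09, 0.06, 0.06))
  expect_equal(s$segments[[1]]$trace$radial_mm[1], 0.09)
  # the windowed radial is NOT the quadrature of the instantaneous axes and
  # the parser must not repair it
  expect_equal(radial_displacement(c(-0.09, 0.06, 0.06)), sqrt(0.0153))
  expect_false(isTRUE(all.equal(radial_displacement(c(-0.09, 0.06, 0.06)),
                                0.09)))
})

test_that("rebaseline events split a session into segments", {
  lines <- c("# iconqa hdmm log v1",
             "# session_id: twoseg",
             "# threshold_mm: 1.5",
             "# record_trigger_mm: 0.2",
             "# window_ms: 500",
             "t_s,x_mm,y_mm,z_mm,radial_mm,state,event",
             "0,0.1,0,0,0.1,treating,baseline",
             "10,0.4,0,0,0.4,treating,record",
             "20,-0.02,0.05,0.01,0.05,treating,rebaseline",
             "30,0.2,0,0,0.2,treating,record",
             "40,0.2,0,0,0.2,treating,end")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f)
  s <- parse_hdmm_log(f)
  expect_identical(length(s$segments), 2L)
  expect_equal(s$segments[[2]]$residual, c(-0.02, 0.05, 0.01))
  expect_identical(nrow(s$segments[[1]]$trace), 2L)
  expect_identical(nrow(s$segments[[2]]$trace), 3L)
})

test_that("malformed rows and non-monotone times are rejected with location", {
  base <- c("# threshold_mm: 1.5",
            "t_s,x_mm,y_mm,z_mm,radial_mm,state,event",
            "0,0,0,0,0,treating,baseline")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(base, "1,0,0,0,0,flying,record"), f)
  expect_error(parse_hdmm_log(f), "line", class = "iconqa_parse_error")
  writeLines(c(base, "1,0,0,0,0,treating,record",
               "0.5,0,0,0,0,treating,end"), f)
  expect_error(parse_hdmm_log(f), class = "iconqa_validation_error")
})

test_that("AUC of constant and ramp traces matches the closed forms", {
  g <- gating_config()
  const <- make_segment(seq(0, 600, by = 60), radial = 0.5)
  expect_equal(auc_mean(const, g)$mean_radial_mm, 0.5)
  expect_equal(auc_mean(const, g)$treating_duration_s, 600)
  ramp <- make_segment(c(0, 300), radial = c(0, 1))
  expect_equal(auc_mean(ramp, g)$mean_radial_mm, 0.5)
  over <- make_segment(c(0, 100), radial = 2.0)
  expect_equal(auc_mean(over, g)$mean_radial_mm, 1.5)  # clipped at threshold
})

test_that("AUC matches an adaptive-quadrature oracle to 1e-9 and obeys clipping", {
  set.seed(42)
  g <- gating_config()
  for (i in 1:100) {
    seg <- random_segment()
    got <- auc_mean(seg, g)
    expect_false(got$empty)
    expect_equal(got$mean_radial_mm,
                 oracle_clipped_radial_mean(seg, g$threshold_mm),
                 tolerance = 1e-9)
    expect_lte(got$mean_radial_mm, g$threshold_mm)
    expect_gte(got$mean_radial_mm, 0)
  }
})

test_that("AUC is invariant under resampling and unchanged when sub-threshold", {
  set.seed(7)
  g <- gating_config()
  for (i in 1:20) {
    seg <- random_segment(n = 8)
    seg$state <- "treating"
    # resample the same piecewise-linear trace 10x finer
    tfine <- sort(unique(c(seg$t_s, seq(min(seg$t_s), max(seg$t_s),
                                        length.out = 200))))
    fine <- make_segment(
      tfine,
      radial = approx(seg$t_s, seg$radial_mm, tfine)$y,
      x = approx(seg$t_s, seg$x_mm, tfine)$y,
      y = approx(seg$t_s, seg$y_mm, tfine)$y,
      z = approx(seg$t_s, seg$z_mm, tfine)$y)
    a1 <- auc_mean(seg, g); a2 <- auc_mean(fine, g)
    expect_equal(a1$mean_radial_mm, a2$mean_radial_mm, tolerance = 1e-10)
    expect_equal(a1$mean_x_mm, a2$mean_x_mm, tolerance = 1e-10)
    # wholly sub-threshold: clipped and unclipped agree
    sub <- seg; sub$radial_mm <- pmin(sub$radial_mm, 1.0)
    wide <- gating_config(threshold_mm = 100)
    expect_equal(auc_mean(sub, g)$mean_radial_mm,
                 auc_mean(sub, wide)$mean_radial_mm)
  }
})

test_that("paused intervals are excluded and an all-paused segment signals empty", {
  g <- gating_config()
  seg <- make_segment(c(0, 10, 20, 30), radial = c(0.4, 0.4, 1.0, 1.0),
                      state = c("treating", "paused", "treating", "paused"))
  a <- auc_mean(seg, g)
  expect_equal(a$treating_duration_s, 20)
  expect_equal(a$mean_radial_mm, (0.4 + 1.0) / 2)
  allp <- make_segment(c(0, 10), radial = 2, state = "paused")
  e <- auc_mean(allp, g)
  expect_true(e$empty)
  expect_true(is.na(e$mean_radial_mm))
  expect_identical(e$treating_duration_s, 0)
  expect_error(auc_mean(make_segment(numeric(0), numeric(0)), g),
               class = "iconqa_validation_error")
})

test_that("post-CBCT residual statistics follow the summary conventions", {
  g <- gating_config()
  mk <- function(res) treatment_session("s", g, list(list(
    residual = res,
    trace = make_segment(c(0, 1), radial = radial_displacement(res)))))
  one <- post_cbct_residuals(list(mk(c(-0.02, -0.02, 0.11))))
  expect_equal(c(one$x_mean, one$y_mean, one$z_mean), c(-0.02, -0.02, 0.11))
  expect_equal(one$vec_mean, radial_displacement(c(-0.02, -0.02, 0.11)))
  zeros <- post_cbct_residuals(list(mk(c(0, 0, 0)), mk(c(0, 0, 0))))
  expect_identical(zeros$vec_mean, 0)
  expect_error(post_cbct_residuals(list()), class = "iconqa_validation_error")
  # simulation recovery: known residual distribution, n = 30
  set.seed(123)
  mu <- c(-0.02, -0.02, 0.11); sig <- c(0.17, 0.21, 0.37)
  sessions <- lapply(1:30, function(i) mk(rnorm(3, mu, sig)))
  got <- post_cbct_residuals(sessions)
  se <- sig / sqrt(30)
  expect_true(all(abs(c(got$x_mean, got$y_mean, got$z_mean) - mu) <= 3 * se))
})

test_that("cohort summary is the sample mean/SD over session AUC results", {
  a <- structure(list(mean_x_mm = 0.1, mean_y_mm = -0.1, mean_z_mm = 0.2,
                      mean_radial_mm = 0.4, treating_duration_s = 100,
                      empty = FALSE), class = "auc_result")
  b <- a; b$mean_radial_mm <- 0.8
  cs <- cohort_summary(list(a, b))
  expect_equal(cs$vec_mean, 0.6)
  expect_equal(cs$vec_sd, sd(c(0.4, 0.8)))
  same <- cohort_summary(list(a, a, a))
  expect_equal(same$vec_sd, 0)
  expect_equal(c(same$x_sd, same$y_sd, same$z_sd), c(0, 0, 0))
  expect_error(cohort_summary(list()), class = "iconqa_validation_error")
})
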