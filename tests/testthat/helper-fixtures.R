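# shared fixture builders for the suite

# marker-sample data.frame in the analyzer's segment layout
make_segment <- function(t_s, radial, x = 0, y = 0, z = 0,
                         state = "treating") {
  n <- length(t_s)
  data.frame(t_s = t_s,
             x_mm = rep_len(x, n), y_mm = rep_len(y, n),
             z_mm = rep_len(z, n),
             radial_mm = rep_len(radial, n),
             state = rep_len(state, n),
             stringsAsFactors = FALSE)
}

# random piecewise-linear segment with mixed treating/paused states
random_segment <- function(n = NULL) {
  if (is.null(n)) n <- sample(5:30, 1)
  t_s <- cumsum(runif(n, 0.1, 30))
  st <- sample(c("treating", "paused"), n, replace = TRUE,
               prob = c(0.8, 0.2))
  st[sample(n - 1, 1)] <- "treating"  # guarantee treating time
  make_segment(t_s, radial = runif(n, 0, 2.5),
               x = rnorm(n, 0, 0.5), y = rnorm(n, 0, 0.5),
               z = rnorm(n, 0, 0.5), state = st)
}

# independent brute-force oracle for the clipped treating-time radial mean:
# dense trapezoid (2e4 points per interval) of min(linear interpolant,
# threshold); worst-case error ~1e-9 of the mean at threshold crossings
oracle_clipped_radial_mean <- function(segment, threshold) {
  n <- nrow(segment)
  total <- 0
  tt <- 0
  for (i in seq_len(n - 1)) {
    if (segment$state[i] != "treating") next
    t1 <- segment$t_s[i]; t2 <- segment$t_s[i + 1]
    r1 <- segment$radial_mm[i]; r2 <- segment$radial_mm[i + 1]
    ts <- seq(t1, t2, length.out = 20001L)
    vals <- pmin(r1 + (r2 - r1) * (ts - t1) / (t2 - t1), threshold)
    h <- (t2 - t1) / 20000
    total <- total + h * (sum(vals) - (vals[1] + vals[20001L]) / 2)
    tt <- tt + (t2 - t1)
  }
  total / tt
}

# absolute-difference expectation (testthat tolerances are relative)
expect_within <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "iconqa")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}

fiducial_coords <- function(fs) as.matrix(fs[, c("x_mm", "y_mm", "z_mm")])

random_rotation <- function() {
  rigid_transform_euler(runif(3, -180, 180))$rotation
}
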