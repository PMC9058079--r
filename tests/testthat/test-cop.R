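test_that("frame CoP is the pressure-weighted centroid", {
  lay <- insole_layout()
  expect_equal(nrow(lay), 16)
  # uniform pressure on the symmetric layout -> CoP at the origin
  u <- sample_cop(rep(1, 16))
  expect_equal(c(u$cop_x, u$cop_y), c(0, 0), tolerance = 1e-12)
  # single active sensor -> CoP at that sensor
  p <- numeric(16); p[7] <- 3.2
  s <- sample_cop(p)
  expect_equal(c(s$cop_x, s$cop_y), c(lay$x[7], lay$y[7]))
  # two sensors, weighted mean
  lay2 <- data.frame(sensor = c("a", "b"), x = c(0, 0), y = c(0.3, 0))
  w <- sample_cop(c(2, 1), lay2)
  expect_equal(w$cop_y, 0.2)
  expect_equal(w$total_force, 3)
  # all-zero frame: undefined CoP, zero force
  z <- sample_cop(numeric(16))
  expect_true(is.na(z$cop_x) && z$total_force == 0)
  expect_error(sample_cop(c(-1, rep(1, 15))), "negative")
})

test_that("CoP lies inside the hull of active sensors", {
  set.seed(5)
  lay <- insole_layout()
  for (i in 1:50) {
    p <- runif(16) * rbinom(16, 1, 0.4)
    if (sum(p) == 0) next
    s <- sample_cop(p)
    act <- p > 0
    expect_gte(s$cop_x, min(lay$x[act]) - 1e-12)
    expect_lte(s$cop_x, max(lay$x[act]) + 1e-12)
    expect_gte(s$cop_y, min(lay$y[act]) - 1e-12)
    expect_lte(s$cop_y, max(lay$y[act]) + 1e-12)
  }
})

# build a small insole trace with prescribed CoP path during one stance
mk_insole <- function(cop_x, cop_y, force, fs = 100) {
  n <- length(cop_x)
  press <- gaitdrift:::.bilinear_pressures(cop_x, cop_y, force)
  ch <- as.data.frame(press)
  names(ch) <- sprintf("p%02d", 1:16)
  ch$gyro_y <- 0; ch$accel_y <- 0
  sensor_trace((seq_len(n) - 1) / fs, ch,
               c(stats::setNames(rep("norm", 16), sprintf("p%02d", 1:16)),
                 gyro_y = "deg/s", accel_y = "m/s2"))
}

test_that("step CoP averages the stance trajectory force-weighted", {
  # constant CoP through stance
  tr <- mk_insole(rep(0.1, 50), rep(0, 50), rep(1, 50))
  sc <- step_cop(tr, c(0L, 50L), foot = "left", contact_threshold = 0.1)
  expect_equal(c(sc$cop_pa, sc$cop_lm), c(0.1, 0), tolerance = 1e-10)
  # linear heel-to-toe ramp with constant force -> midpoint
  ramp <- seq(-0.3, 0.3, length.out = 101)
  tr2 <- mk_insole(ramp, rep(0.05, 101), rep(2, 101))
  sc2 <- step_cop(tr2, c(0L, 101L), foot = "left", contact_threshold = 0.1)
  expect_equal(sc2$cop_pa, 0, tolerance = 1e-10)
  expect_equal(sc2$cop_lm, 0.05, tolerance = 1e-10)
  # right foot's lateral axis is mirrored into the anatomical frame
  sc3 <- step_cop(tr2, c(0L, 101L), foot = "right", contact_threshold = 0.1)
  expect_equal(sc3$cop_lm, -0.05, tolerance = 1e-10)
  # unloaded window -> step skipped
  tr3 <- mk_insole(rep(0, 20), rep(0, 20), rep(0, 20))
  expect_equal(step_cop(tr3, c(0L, 20L), foot = "left",
                        contact_threshold = 0.1)$n_samples, 0L)
})

test_that("segment averaging uses plain means and sd across steps", {
  vals <- c(0.1, 0.2, 0.3)
  expect_equal(mean(vals), 0.2)
  expect_equal(stats::sd(vals), 0.1)
  # via ws_cop on a trace whose three stance windows carry those values:
  # loaded spans [10,40), [50,80), [90,120), swing in between
  cop_y <- rep(0, 130); force <- rep(0, 130)
  loads <- list(11:40, 51:80, 91:120)
  for (k in 1:3) { cop_y[loads[[k]]] <- vals[k]; force[loads[[k]]] <- 1 }
  tr <- mk_insole(rep(0, 130), cop_y, force)
  # four strides: step k = heel-strike k -> toe-off k+1
  ev <- data.frame(toeoff = c(2L, 40L, 80L, 120L),
                   midswing = c(5L, 45L, 85L, 125L),
                   heelstrike = c(10L, 50L, 90L, 128L))
  seg <- list(ws = 1L, start_idx = 0L, end_idx = 130L)
  w <- ws_cop(tr, ev, seg, foot = "left", contact_threshold = 0.1)
  expect_equal(w$n_steps, 3L)
  expect_equal(w$cop_lm, 0.2, tolerance = 1e-9)
  expect_equal(w$sd_lm, 0.1, tolerance = 1e-6)
  # a single step yields sd 0 by convention
  one <- ws_cop(tr, ev[1:2, ], seg, foot = "left", contact_threshold = 0.1)
  expect_equal(one$n_steps, 1L)
  expect_equal(one$sd_lm, 0)
  # zero usable steps -> missing values
  none <- ws_cop(tr, ev[1, , drop = FALSE], seg, foot = "left",
                 contact_threshold = 0.1)
  expect_true(is.na(none$cop_lm))
})

test_that("symmetry is left minus right with the documented sign", {
  expect_equal(cop_sym(-0.10, -0.04), -0.06)
  expect_equal(cop_sym(0.3, 0.3), 0)
  expect_true(is.na(cop_sym(NA, 0.1)))
  # leftward weight shift (left foot more lateral = less medial) -> negative
  left_shifted <- cop_sym(-0.05, 0.0)
  expect_lt(left_shifted, 0)
})

test_that("injected lateral offsets are recovered from full trials", {
  for (off in c(-0.08, 0.08)) {
    tr <- simulate_trial(quick_cfg(21, cop_offset = off), "baseline")
    est <- trial_cop_sym(tr)
    expect_true(all(abs(est - off) < 0.02))
  }
  # mirroring left<->right negates the symmetry (antisymmetry)
  plus <- trial_cop_sym(simulate_trial(quick_cfg(22, cop_offset = 0.06),
                                       "baseline"))
  minus <- trial_cop_sym(simulate_trial(quick_cfg(22, cop_offset = -0.06),
                                        "baseline"))
  expect_true(all(abs(plus + minus) < 0.02))
})
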