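# Bilevel waveform analysis: state levels, crossing geometry on analytic
# fixtures, and full-feature agreement with the brute-force oracle.

trapezoid_trace <- function(frame_rate = 100, total_s = 25,
                            t_up = 10, ramp = 1, hold = 4) {
  tt <- (seq_len(total_s * frame_rate) - 1) / frame_rate
  up_end <- t_up + ramp
  down_start <- up_end + hold
  down_end <- down_start + ramp
  ifelse(tt < t_up, 0,
    ifelse(tt < up_end, (tt - t_up) / ramp,
      ifelse(tt < down_start, 1,
        ifelse(tt < down_end, 1 - (tt - down_start) / ramp, 0))))
}

test_that("state levels recover a clean two-level signal", {
  tr <- rep(c(0, 0, 0, 1, 1, 1), 4)
  sl <- estimate_state_levels(tr, n_bins = 100)
  expect_lt(abs(sl$low - 0), sl$bin_width)
  expect_lt(abs(sl$high - 1), sl$bin_width)
  # affine equivariance: scaling the trace scales both levels
  sl2 <- estimate_state_levels(2 * tr, 100)
  expect_equal(sl2$low, 2 * sl$low)
  expect_equal(sl2$high, 2 * sl$high)
  expect_error(estimate_state_levels(rep(1, 10)), "constant")
  expect_error(estimate_state_levels(c(0, 1)), "4 samples")
})

test_that("state levels match the histogram oracle on a bimodal draw", {
  set.seed(101)
  tr <- c(rnorm(350, 0.05, 0.02), rnorm(150, 0.85, 0.03))
  sl <- estimate_state_levels(tr, 100)
  or <- oracle_state_levels(tr, 100)
  expect_equal(sl$low, or$low)
  expect_equal(sl$high, or$high)
  expect_lt(abs(sl$low - 0.05), 2 * sl$bin_width)
  expect_lt(abs(sl$high - 0.85), 2 * sl$bin_width)
})

test_that("trapezoid pulse geometry is recovered exactly", {
  fr <- 100
  tr <- trapezoid_trace(frame_rate = fr)   # ramp 10->11, hold to 15, down to 16
  sl <- estimate_state_levels(tr, 100)
  pulses <- find_pulses(tr, fr, sl)
  expect_equal(nrow(pulses), 1)
  # analytic values for state levels (0, 1): mid crossings 10.5 / 15.5,
  # 10-90% rise time = 0.8 x ramp duration, slew = 0.8 span / 0.8 s = 1
  tol <- 1.5 / fr + 0.02  # one sample + state-level bin offset
  expect_lt(abs(pulses$width - 5.0), tol)
  expect_lt(abs(pulses$rise_time - 0.8), tol)
  expect_lt(abs(pulses$fall_time - 0.8), tol)
  expect_lt(abs(pulses$slew_pos - 1.0), 0.05)
  expect_lt(abs(pulses$slew_neg + 1.0), 0.05)
  expect_equal(pulses$t_rise_mid, 10.5, tolerance = 0.02)
  expect_equal(pulses$t_fall_mid, 15.5, tolerance = 0.02)
})

test_that("monotone traces contain no complete pulse", {
  tr <- seq(0, 1, length.out = 50)
  sl <- estimate_state_levels(tr, 100)
  expect_equal(nrow(find_pulses(tr, 5, sl)), 0)
  ft <- extract_features(tr, 5)
  expect_false(ft$valid)
  expect_true(is.na(ft$amplitude))
})

test_that("square wave features are exact at the analytic values", {
  # period 20 s, 5 s high, amplitude 1, sampled at 5 Hz
  fr <- 5
  one_period <- c(rep(1, 5 * fr), rep(0, 15 * fr))
  tr <- rep(one_period, 5)
  tr <- c(rep(0, 10), tr)    # lead-in so the first rise is a real crossing
  ft <- extract_features(tr, fr)
  expect_true(ft$valid)
  # state levels sit at bin centers: one half-bin offset at each end
  expect_lte(abs(ft$amplitude - 1), 0.01 + 1e-12)
  expect_equal(ft$pulse_width_s, 5, tolerance = 1 / fr)
  expect_equal(ft$frequency_hz, 0.05, tolerance = 0.001)
  expect_equal(ft$duty_cycle, 0.25, tolerance = 0.01)
})

test_that("single pulse defines width but not frequency", {
  fr <- 10
  tr <- c(rep(0, 30), rep(1, 20), rep(0, 30))
  ft <- extract_features(tr, fr)
  expect_true(ft$valid)
  expect_equal(ft$n_pulses, 1)
  expect_false(is.na(ft$pulse_width_s))
  expect_true(is.na(ft$frequency_hz))
  expect_true(is.na(ft$duty_cycle))
})

test_that("features agree with the brute-force oracle on simulated trains", {
  set.seed(202)
  worst <- 0
  checked <- 0
  for (i in 1:40) {
    tr <- random_burst_trace(n_frames = 300 + 20 * (i %% 5),
                             frame_rate = 5, n_events = 2 + i %% 7)
    got <- extract_features(tr, 5)
    exp_ <- oracle_features(tr, 5)
    expect_equal(got$n_pulses, exp_$n_pulses)
    for (f in c("amplitude", "pulse_width_s", "frequency_hz", "rise_time_s",
                "fall_time_s", "slew_pos", "slew_neg", "duty_cycle")) {
      g <- got[[f]]; e <- exp_[[f]]
      expect_equal(is.na(g), is.na(e), info = f)
      if (!is.na(g)) {
        rel <- abs(g - e) / max(abs(e), 1e-12)
        worst <- max(worst, rel)
        checked <- checked + 1
        expect_lt(rel, 1e-9)
      }
    }
  }
  expect_gt(checked, 100)
})

test_that("amplitude equivariance: scaling dF scales amplitude and slew", {
  set.seed(303)
  tr <- random_burst_trace()
  a <- extract_features(tr, 5)
  b <- extract_features(3 * tr, 5)
  expect_equal(b$amplitude, 3 * a$amplitude, tolerance = 1e-9)
  expect_equal(b$slew_pos, 3 * a$slew_pos, tolerance = 1e-9)
  expect_equal(b$slew_neg, 3 * a$slew_neg, tolerance = 1e-9)
  expect_equal(b$pulse_width_s, a$pulse_width_s, tolerance = 1e-9)
  expect_equal(b$frequency_hz, a$frequency_hz, tolerance = 1e-9)
  expect_equal(b$rise_time_s, a$rise_time_s, tolerance = 1e-9)
})

test_that("trapezoid features converge to analytic values with sampling", {
  errs <- vapply(c(20, 50, 200), function(fr) {
    ft <- extract_features(trapezoid_trace(frame_rate = fr), fr)
    abs(ft$pulse_width_s - 5.0)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))   # error shrinks (or stays) as fr grows
  ft <- extract_features(trapezoid_trace(frame_rate = 500), 500)
  expect_equal(ft$pulse_width_s, 5.0, tolerance = 0.01)
  expect_equal(ft$rise_time_s, 0.8, tolerance = 0.01)
})

test_that("fall time and width grow with the decay time constant", {
  # rise_tau is kept at 3 samples per rise so the sampled peak (and with it
  # the high state level) is stable across the sweep
  fr <- 10
  taus <- c(0.8, 1.2, 1.6, 2.2, 3.0, 4.0)
  events <- list(c(5, 25, 45, 65, 85))
  falls <- widths <- numeric(length(taus))
  for (i in seq_along(taus)) {
    kin <- transient_kinetics(rise_tau = 0.3, decay_tau = taus[i],
                              amplitude_mean = 1, amplitude_cv = 0)
    tr <- render_traces(events, kin, fr, 1000)
    ft <- extract_features(tr[1, ], fr)
    falls[i] <- ft$fall_time_s
    widths[i] <- ft$pulse_width_s
  }
  expect_gt(cor(taus, falls, method = "spearman"), 0.9)
  expect_gt(cor(taus, widths, method = "spearman"), 0.9)
})

test_that("features_table aggregates valid ROIs into field means", {
  flat <- matrix(0.2, 3, 60)
  ft <- features_table(flat, frame_rate = 5)
  expect_equal(sum(ft$valid), 0)
  expect_true(all(is.na(attr(ft, "field_means"))))

  set.seed(7)
  tr1 <- random_burst_trace(); tr2 <- random_burst_trace()
  m <- rbind(tr1, tr2, rep(0.1, length(tr1)))
  tab <- features_table(m, frame_rate = 5)
  expect_equal(nrow(tab), 3)
  fm <- attr(tab, "field_means")
  manual <- mean(tab$amplitude[tab$valid], na.rm = TRUE)
  expect_equal(unname(fm["amplitude"]), manual)
  # homogeneous field: mean equals the single-ROI value
  hom <- features_table(rbind(tr1, tr1), frame_rate = 5)
  expect_equal(unname(attr(hom, "field_means")["amplitude"]),
               hom$amplitude[1])
})
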