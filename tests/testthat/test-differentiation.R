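# The Nanog-gated differentiation machinery: ramps, the two-step
# NH -> NL -> Oct4-Sox2-loss sequence, and the Y dependence.

test_that("ramp construction validates and samples deterministically", {
  expect_error(ramp_spec(t_mid_median = 0), "t_mid_median")
  expect_error(ramp_spec(p_max = -1), "p_max")
  expect_error(ramp_spec(slope = 0), "slope")
  sp <- ramp_spec(p_max = 40, t_mid_median = 600, t_mid_logsd = 0.4)
  r1 <- sample_ramps(sp, 50, master_seed = 8)
  r2 <- sample_ramps(sp, 50, master_seed = 8)
  expect_identical(r1$t_mid, r2$t_mid)
  # log-sd 0: every cell shares the single ramp (synchronous population)
  r0 <- sample_ramps(ramp_spec(t_mid_logsd = 0), 20, master_seed = 1)
  expect_true(all(r0$t_mid == r0$t_mid[1]))
  # the logistic passes p_max/2 at the midpoint and approaches a step for
  # steep slopes
  expect_equal(r1$p_of_t(r1$t_mid[3], 3), sp$p_max / 2)
  steep <- sample_ramps(ramp_spec(slope = 5, t_mid_logsd = 0), 1, 1)
  expect_lt(steep$p_of_t(steep$t_mid[1] - 10, 1), 1e-8)
  expect_equal(steep$p_of_t(steep$t_mid[1] + 10, 1), 40, tolerance = 1e-8)
})

test_that("the population-average ramp at the median time is p_max/2 within 2%", {
  sp <- ramp_spec(p_max = 40, t_mid_median = 720, t_mid_logsd = 0.5,
                  slope = 0.015)
  r <- sample_ramps(sp, 10000, master_seed = 21)
  p_at_median <- sp$p_max / (1 + exp(-sp$slope * (sp$t_mid_median - r$t_mid)))
  expect_lt(abs(mean(p_at_median) - sp$p_max / 2), 0.02 * sp$p_max)
})

test_that("withdrawal requires the 2i starting state", {
  expect_error(simulate_differentiation(ref_params()), "p = 0")
})

test_that("without signal Y Nanog switches but no cell differentiates", {
  dr <- simulate_differentiation(two_i_params(), Y_level = 0, n_cells = 40,
                                 duration = 2880, dt = 0.2, master_seed = 5)
  expect_equal(sum(!is.na(dr$outcomes$t_diff_min)), 0)
  tc <- dr$timecourse
  expect_lt(tc$mean_N[nrow(tc)], 0.05) # NH -> NL switch happened
  expect_gt(tc$mean_OS[nrow(tc)], 0.5) # Oct4-Sox2 stays high
})

test_that("with signal Y the two-step sequence and its timing hold", {
  dr <- cached("diffrun_default",
               simulate_differentiation(two_i_params(), n_cells = 120,
                                        duration = 2880, dt = 0.2,
                                        master_seed = 3))
  tc <- dr$timecourse
  half_time <- function(v) tc$t_min[which(v <= 0.5)[1]]
  # Nanog declines before Rex1, both population means
  expect_lt(half_time(tc$mean_N), half_time(tc$mean_R))
  # across-cell dispersion of Nanog peaks before that of Rex1
  expect_lt(tc$t_min[which.max(tc$sd_N)], tc$t_min[which.max(tc$sd_R)])
  # differentiation engages essentially the whole population under strong Y
  expect_gt(mean(!is.na(dr$outcomes$t_diff_min)), 0.9)
  expect_true(all(diff(tc$frac_differentiated) >= 0))
})

test_that("differentiation classification is absorbing under extension", {
  short <- simulate_differentiation(two_i_params(), n_cells = 30,
                                    duration = 1800, dt = 0.2, master_seed = 12)
  long <- simulate_differentiation(two_i_params(), n_cells = 30,
                                   duration = 2400, dt = 0.2, master_seed = 12)
  sh <- short$outcomes$t_diff_min
  lo <- long$outcomes$t_diff_min
  committed <- !is.na(sh)
  expect_identical(sh[committed], lo[committed]) # same cells, same times
  expect_true(all(is.na(sh[!committed]) | lo[!committed] >= 1800))
})

test_that("Nanog pinned at NH keeps the gate shut for any tested Y", {
  pinned <- ng_params(sigma_N = 0, base = lif_serum_params())
  for (y in c(1, 5)) {
    fr <- differentiated_fraction_vs_Y(pinned, Y_grid = y, n_cells = 25,
                                       duration = 1440, dt = 0.2,
                                       master_seed = 7)
    expect_equal(fr$frac_differentiated, 0)
  }
})

test_that("synchronous ramps collapse the heterogeneous Rex1-decay period", {
  async <- simulate_differentiation(two_i_params(),
                                    ramp = ramp_spec(t_mid_logsd = 0.5),
                                    n_cells = 80, duration = 2160, dt = 0.2,
                                    master_seed = 9)
  sync <- simulate_differentiation(two_i_params(),
                                   ramp = ramp_spec(t_mid_logsd = 0),
                                   n_cells = 80, duration = 2160, dt = 0.2,
                                   master_seed = 9)
  at24 <- function(dr) {
    tc <- dr$timecourse
    tc$sd_R[which.min(abs(tc$t_min - 1440))]
  }
  expect_lt(at24(sync), at24(async))
})

test_that("the differentiated fraction is zero without Y and non-decreasing in Y", {
  fr <- cached("frac_vs_y",
               differentiated_fraction_vs_Y(ref_params(),
                                            Y_grid = c(0, 0.5, 2, 5),
                                            n_cells = 100, duration = 2880,
                                            dt = 0.2, master_seed = 5))
  expect_equal(fr$frac_differentiated[fr$Y == 0], 0)
  expect_true(all(diff(fr$frac_differentiated) >= -0.03)) # paired seeds
  expect_equal(fr$frac_NH + fr$frac_NL + fr$frac_differentiated,
               rep(1, nrow(fr)))
  # intermediate Y: both fates coexist (re-expression and differentiation)
  mid <- fr[fr$Y == 0.5, ]
  expect_gt(mid$frac_differentiated, 0)
  expect_gt(mid$frac_NH, 0.5)
})
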