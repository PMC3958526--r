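# Basin classification, the transition validity rule, rates, residence
# statistics and the noise sweeps.

test_that("the validity rule accepts 2 h excursions and rejects 0.5 h ones", {
  b <- 50
  # NH 10 h | NL 0.5 h | NH 10 h: the dip never validates
  tr <- square_wave(c(100, 10, 100), c(600, 30, 600))
  expect_equal(nrow(detect_transitions(tr, b)), 0)
  # NH 10 h | NL 2 h | NH 10 h: two valid events, hand-traced residences
  tr2 <- square_wave(c(100, 10, 100), c(600, 120, 600))
  ev <- detect_transitions(tr2, b)
  expect_equal(nrow(ev), 2)
  expect_identical(ev$direction, c("NH->NL", "NL->NH"))
  expect_equal(ev$t_min, c(600, 720))
  expect_equal(ev$residence_in_destination[1], 120)
  expect_gte(ev$residence_in_destination[2], 600)
  expect_identical(ev$censored, c(FALSE, TRUE))
  # a constant trajectory has no events; short ones warn
  expect_equal(nrow(detect_transitions(square_wave(100, 600), b)), 0)
  expect_warning(out <- detect_transitions(square_wave(100, 30), b),
                 "shorter")
  expect_equal(nrow(out), 0)
})

test_that("sub-threshold excursions do not reset the current basin", {
  b <- 50
  # NH | brief NL dips | then a real NL period: only one event, at the
  # start of the validated run
  tr <- square_wave(c(100, 10, 100, 10, 100, 10), c(300, 20, 60, 30, 300, 400))
  ev <- detect_transitions(tr, b)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_min, 300 + 20 + 60 + 30 + 300)
})

test_that("transition parity and residence additivity hold on stochastic runs", {
  run <- simulate_population(ref_params(), 150, init = "at_NH",
                             duration = 4320, dt = 0.1, master_seed = 17,
                             record_every = 1, species = "N")
  ev <- population_transitions(run, ref_boundary())
  counts <- table(factor(ev$direction, levels = c("NH->NL", "NL->NH")),
                  factor(ev$cell_id, levels = 1:150))
  expect_true(all(abs(counts[1, ] - counts[2, ]) <= 1))
  rec <- residence_records(run, ref_boundary())
  per_cell <- tapply(rec$end - rec$start, rec$cell_id, sum)
  expect_true(all(abs(per_cell - 4320) < 1e-9))
  # uncensored records are bounded by two valid transitions
  unc <- rec[!rec$censored, ]
  if (nrow(unc) > 0) {
    expect_true(all(unc$start %in% ev$t_min & unc$end %in% ev$t_min))
  }
})

test_that("transition rates are plain arithmetic with a seeded bootstrap CI", {
  expect_equal(transition_rate(detect_transitions(square_wave(100, 600), 50),
                               10, 1440)$rate_per_day, 0)
  ev <- tibble::tibble(cell_id = rep(1:15, 1), t_min = 1:15,
                       direction = "NH->NL",
                       residence_in_destination = 100, censored = FALSE)
  r <- transition_rate(ev, n_cells = 100, duration = 3 * 1440)
  expect_equal(r$rate_per_day, 15 / 300) # 0.05 per cell per 24 h
  expect_equal(r$rate_per_hour * 24, r$rate_per_day)
  expect_true(r$ci_lo <= r$rate_per_day && r$rate_per_day <= r$ci_hi)
  r2 <- transition_rate(ev, n_cells = 100, duration = 3 * 1440)
  expect_identical(r, r2) # bootstrap is seeded
})

test_that("residence statistics recover the sojourn means of a known process", {
  # alternating two-state process with exponential sojourns, sampled every
  # 5 minutes like a thinned Nanog series; the window spans every sojourn
  # so only the leading/trailing intervals are censored
  mean_NL <- 9 * 1440
  mean_NH <- 11 * 1440
  b <- 50
  rec <- withr::with_seed(99, {
    purrr::map_dfr(1:10, function(i) {
      d <- rep(c(mean_NH, mean_NL), 40)
      lens <- pmax(round(stats::rexp(80, 1 / d) / 5), 1)
      vals <- rep(c(100, 1), 40)
      N <- rep(vals, times = lens)
      run <- structure(list(times = (seq_along(N) - 1) * 5,
                            N = matrix(N, ncol = 1), n_cells = 1,
                            species = "N"),
                       class = "ng_population")
      out <- residence_records(run, b)
      out$cell_id <- i
      out
    })
  })
  st <- residence_statistics(rec)
  expect_gt(min(st$n_uncensored), 200)
  expect_lt(abs(st$mean_days[st$basin == "NL"] - 9) / 9, 0.15)
  expect_lt(abs(st$mean_days[st$basin == "NH"] - 11) / 11, 0.15)
  expect_lt(max(st$ks_distance), 0.1) # close to exponential
  # and an event-free population is flagged insufficient
  quiet <- residence_records(structure(list(times = seq(0, 1440, 5),
                                            N = matrix(100, 289, 3),
                                            n_cells = 3, species = "N"),
                                       class = "ng_population"), b)
  st0 <- residence_statistics(quiet)
  expect_true(all(st0$insufficient))
})

test_that("every boundary crossing is valid in the min_residence -> 0 limit", {
  tr <- square_wave(rep(c(100, 10), 10), rep(c(45, 50), 10))
  b <- 50
  ev0 <- detect_transitions(tr, b, min_residence = 0)
  expect_equal(nrow(ev0), 19) # every crossing counts
  ev <- detect_transitions(tr, b, min_residence = 60)
  expect_lte(nrow(ev), nrow(ev0)) # the rule can only remove events
})

test_that("NL-fraction sweep honours its analytic corners", {
  pr <- ref_params()
  # no noise, started in NH: no escape
  sw0 <- nl_fraction_sweep(ng_params(sigma_OS = 0, sigma_R = 0, base = pr),
                           s4_grid = 35, sigma_grid = 0, n_cells = 20,
                           duration = 1440, master_seed = 1)
  expect_equal(sw0$nl_fraction, 0)
  # s4 below the lower fold: the low state is the only attractor
  sw1 <- nl_fraction_sweep(pr, s4_grid = 5, sigma_grid = c(0.05, 0.1),
                           n_cells = 20, duration = 1440, master_seed = 1)
  expect_equal(sw1$nl_fraction, c(1, 1))
  expect_error(nl_fraction_sweep(pr, numeric(0), 0.1, 10), "nonempty")
})

test_that("transitions_vs_noise rejects s4 outside the bistable window", {
  expect_error(transitions_vs_noise(ref_params(), s4_values = 5,
                                    sigma_grid = 0.1, n_cells = 5,
                                    duration = 1440),
               "bistable")
})
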