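# Shared fixtures, built in code. Expensive simulation products are cached
# per session so several test files can reuse them.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

ref_params <- function() cached("ref_params", lif_serum_params())

ref_boundary <- function() cached("ref_boundary", basin_boundary(ref_params()))

# the 1000-cell, 3-day LIF/serum population used by several checks
run_3day <- function() {
  cached("run_3day", simulate_population(
    ref_params(), n_cells = 1000, init = "at_NH", duration = 4320, dt = 0.1,
    master_seed = 20, record_every = 1, species = "N"))
}

# a synthetic square-wave Nanog trajectory: values per segment, segment
# lengths in minutes, sampled every minute
square_wave <- function(levels, lengths_min) {
  n <- rep(levels, times = lengths_min + c(rep(0, length(lengths_min) - 1), 1))
  tibble::tibble(cell_id = 1L, t_min = seq_along(n) - 1, N = n)
}

# random-but-seeded structural variations of the reference set that keep the
# Oct4-Sox2 subsystem intact
random_param_sets <- function(n, seed = 42) {
  base <- ref_params()
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      ng_params(s3 = runif(1, 0.3, 0.6),
                s4 = runif(1, 15, 60),
                s6 = runif(1, 8, 24),
                p = sample(c(0, 5, 15, 25), 1),
                d_N = runif(1, 0.02, 0.06),
                base = base)
    })
  })
}

# ramp-recovery experiment shared between the calibration tests and the
# acceptance suite: data generated from a known ramp, fitted from a
# perturbed start
ramp_recovery <- function() {
  cached("ramp_recovery", {
    p2i <- two_i_params()
    truth <- ramp_spec(p_max = 40, t_mid_median = 720, t_mid_logsd = 0.5,
                       slope = 0.015)
    gen <- simulate_differentiation(p2i, ramp = truth, Y_level = 0,
                                    rex1_turnover_scale = 0.06, n_cells = 300,
                                    duration = 2880, dt = 0.5,
                                    master_seed = 77, record_every = 30)
    tc <- gen$timecourse
    obs <- tibble::tibble(t_h = seq(0, 48, by = 3))
    obs$nanog_rel <- stats::approx(tc$t_min / 60, tc$mean_N, obs$t_h)$y
    obs$rex1_rel <- stats::approx(tc$t_min / 60, tc$mean_R, obs$t_h)$y
    fit <- fit_ramp(obs, p2i,
                    spec_template = ramp_spec(p_max = 30, t_mid_median = 540,
                                              t_mid_logsd = 0.3, slope = 0.015),
                    Y_level = 0, n_cells = 120, dt = 0.5, fit_seed = 5,
                    maxit = 120)
    list(truth = truth, true_scale = 0.06, obs = obs, fit = fit, p2i = p2i)
  })
}
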