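# The Euler-Maruyama stepper: determinism, the deterministic limit,
# non-negativity, thinning, and step-size robustness.

test_that("identical seeds give bit-identical trajectories and populations", {
  pr <- ref_params()
  t1 <- simulate_cell(pr, duration = 100, dt = 0.1, seed = 11)
  t2 <- simulate_cell(pr, duration = 100, dt = 0.1, seed = 11)
  expect_identical(t1$N, t2$N)
  expect_identical(t1$OS, t2$OS)
  r1 <- simulate_population(pr, 20, duration = 200, dt = 0.1, master_seed = 4,
                            record_every = 10)
  r2 <- simulate_population(pr, 20, duration = 200, dt = 0.1, master_seed = 4,
                            record_every = 10)
  expect_identical(r1$N, r2$N)
  expect_identical(r1$R, r2$R)
  # a different seed actually changes the noise
  r3 <- simulate_population(pr, 20, duration = 200, dt = 0.1, master_seed = 5,
                            record_every = 10)
  expect_false(identical(r1$N, r3$N))
})

test_that("cell streams depend only on (master_seed, cell_id), not on the cohort", {
  pr <- ref_params()
  big <- simulate_population(pr, 8, duration = 100, dt = 0.1, master_seed = 9,
                             record_every = 10)
  small <- simulate_population(pr, 3, duration = 100, dt = 0.1, master_seed = 9,
                               record_every = 10)
  expect_identical(big$N[, 1:3], small$N)
})

test_that("without noise a stable fixed point is stationary and basins attract", {
  pr0 <- ng_params(sigma_OS = 0, sigma_N = 0, sigma_R = 0, base = ref_params())
  fp <- find_fixed_points(pr0)
  nh <- as.numeric(fp[fp$branch == "NH", c("OS", "N", "R", "E")])
  traj <- simulate_cell(pr0, init = nh, duration = 2000, dt = 0.1, seed = 1,
                        record_every = 100)
  expect_true(all(abs(t(traj[, c("OS", "N", "R", "E")]) - nh) < 1e-6 * (nh + 1)))
  # a perturbed state inside the NH basin relaxes back to the fixed point
  init <- nh * c(1.2, 3, 0.5, 0.9)
  term <- simulate_cell(pr0, init = init, duration = 3000, dt = 0.1, seed = 1)
  expect_equal(as.numeric(term[nrow(term), c("OS", "N", "R", "E")]), nh,
               tolerance = 1e-3)
})

test_that("the compiled stepper reproduces the R drift over one step", {
  pr0 <- ng_params(sigma_OS = 0, sigma_N = 0, sigma_R = 0, Y = 2,
                   base = ref_params())
  init <- c(60, 5, 10, 25) # Y_in active at this low Nanog
  dt <- 0.05
  step <- simulate_cell(pr0, init = init, duration = dt, dt = dt, seed = 1)
  expected <- pmax(init + deterministic_drift(init, pr0) * dt, 0)
  expect_equal(as.numeric(step[2, c("OS", "N", "R", "E")]), unname(expected),
               tolerance = 1e-12)
})

test_that("concentrations never go negative, even under extreme noise", {
  pr <- ng_params(sigma_N = 0.6, sigma_OS = 0.4, sigma_R = 0.6,
                  base = ref_params())
  run <- simulate_population(pr, 30, duration = 1440, dt = 0.1,
                             master_seed = 3, record_every = 1)
  for (s in c("OS", "N", "R", "E")) expect_true(all(run[[s]] >= 0))
})

test_that("snapshot thinning and terminal states are consistent", {
  pr <- ref_params()
  run <- simulate_population(pr, 5, duration = 100, dt = 0.1, master_seed = 2,
                             record_every = 20)
  expect_equal(run$times, seq(0, 100, by = 20))
  tb <- tibble::as_tibble(run)
  expect_identical(names(tb), c("cell_id", "t_min", "OS", "N", "R", "E"))
  expect_equal(nrow(tb), 5 * 6)
  ts <- terminal_states(run)
  expect_equal(ts$N, run$N[6, ])
  # N-only recording for long runs
  runN <- simulate_population(pr, 5, duration = 100, dt = 0.1, master_seed = 2,
                              record_every = 20, species = "N")
  expect_identical(runN$N, run$N)
  expect_null(runN$OS)
  expect_error(species_matrix(runN, "R"), "not recorded")
})

test_that("an oversized step triggers the stability warning", {
  expect_warning(simulate_population(ng_params(Y = 20, base = ref_params()),
                                     2, duration = 100, dt = 1,
                                     master_seed = 1),
                 "unstable")
})

test_that("summary statistics are robust to halving the step size", {
  pr <- ref_params()
  b <- ref_boundary()
  nl_frac <- sapply(c(0.1, 0.05), function(dt) {
    run <- simulate_population(pr, 1500, init = "at_NH", duration = 4320,
                               dt = dt, master_seed = 31)
    mean(terminal_states(run)$N < b)
  })
  expect_lt(abs(nl_frac[1] - nl_frac[2]), 0.02)
})
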