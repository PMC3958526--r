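# Network primitives: the Nanog gate Y_in, the deterministic drift, and the
# parameter-set plumbing.

test_that("Y_in gate matches its closed form and boundary behaviour", {
  # full transmission without Nanog; exact hand evaluations
  expect_equal(compute_Yin(N = 0, Y = 5, k_Y = 100, h = 2), 5)
  expect_equal(compute_Yin(N = 300, Y = 2, k_Y = 100, h = 2), 0.2)
  # half-saturation symmetry for several gate shapes
  for (kY in c(4, 12, 100)) for (h in c(1, 2, 4)) {
    expect_equal(compute_Yin(N = kY, Y = 3.7, k_Y = kY, h = h), 3.7 / 2)
  }
  # strictly decreasing in N, bounded in [0, Y], vanishing at huge N
  N <- seq(0, 500, length.out = 200)
  y <- compute_Yin(N, Y = 2, k_Y = 12, h = 2)
  expect_true(all(diff(y) < 0))
  expect_true(all(y >= 0 & y <= 2))
  expect_lt(compute_Yin(1e6 * 12, Y = 2, k_Y = 12, h = 2), 1e-9)
  expect_equal(compute_Yin(0, Y = 2, k_Y = 12, h = 3), 2)
})

test_that("k_Y moves the slope of the gate but not its range", {
  N <- seq(0, 2000, length.out = 4001)
  rng <- sapply(c(2, 8, 32, 128), function(kY) {
    y <- compute_Yin(N, Y = 3, k_Y = kY, h = 2)
    c(min(y), max(y))
  })
  expect_true(all(abs(rng[2, ] - 3) < 1e-3)) # max is Y for every k_Y
  expect_true(all(rng[1, ] < 0.05)) # min approaches 0 for every k_Y
  # slopes at N = k_Y do differ
  sl <- sapply(c(2, 128), function(kY) {
    eps <- 1e-3
    (compute_Yin(kY + eps, 3, kY) - compute_Yin(kY - eps, 3, kY)) / (2 * eps)
  })
  expect_gt(abs(sl[1]), 10 * abs(sl[2]))
})

test_that("Y_in rejects invalid arguments", {
  expect_error(compute_Yin(-1, 1, 10), "N and Y")
  expect_error(compute_Yin(1, -1, 10), "N and Y")
  expect_error(compute_Yin(NaN, 1, 10), "finite")
  expect_error(compute_Yin(1, 1, 0), "k_Y")
  expect_error(compute_Yin(1, 1, 10, h = 0.5), "h")
})

test_that("deterministic drift reproduces hand-computed rates", {
  pr <- ng_params(s12 = 12, s3 = 4, s4 = 40, s5 = 6, s6 = 10, s7 = 2,
                  k = 50, n = 2, p = 0, d_OS = 0.1, d_N = 0.1, d_R = 0.1,
                  d_E = 0.1, i_OS = 0, i_N = 0, i_R = 0, Y = 0,
                  base = lif_serum_params())
  # H(100) = 100^2/(50^2+100^2) = 0.8
  f <- deterministic_drift(c(100, 100, 0, 0), pr)
  expect_equal(unname(f), c(12 * 0.8 - 10, (4 + 40) * 0.8 - 10,
                            6 * 0.8 + 10 * 0.8, 2 * 0.8),
               tolerance = 1e-12)
  # the origin is a fixed point: every production term has a zero numerator
  expect_equal(unname(deterministic_drift(c(0, 0, 0, 0), pr)), rep(0, 4))
  # pure first-order decay when all transcription is off
  pr0 <- ng_params(s12 = 0, s3 = 0, s4 = 0, s5 = 0, s6 = 0, s7 = 0, base = pr)
  expect_equal(unname(deterministic_drift(c(10, 10, 10, 10), pr0)),
               rep(-1, 4))
})

test_that("with p = 0 the Nanog drift is independent of Erk", {
  pr <- ng_params(p = 0, Y = 0, base = lif_serum_params())
  fN <- sapply(c(0, 10, 100, 1000), function(E) {
    deterministic_drift(c(60, 20, 5, E), pr)[["N"]]
  })
  expect_true(all(abs(fN - fN[1]) < 1e-12))
  # and with p > 0 it is not
  pr15 <- ng_params(p = 15, base = pr)
  fN15 <- sapply(c(0, 100), function(E) {
    deterministic_drift(c(60, 20, 5, E), pr15)[["N"]]
  })
  expect_gt(abs(diff(fN15)), 1e-6)
})

test_that("drift is finite and bounded on a compact box and rejects negatives", {
  pr <- lif_serum_params()
  grid <- expand.grid(OS = c(0, 1, 62.5, 200), N = c(0, 1.2, 8, 101, 900),
                      R = c(0, 400), E = c(0, 29))
  vals <- apply(grid, 1, function(s) deterministic_drift(as.numeric(s), pr))
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(vals)), 100) # production rates bound the drift
  expect_error(deterministic_drift(c(-1, 0, 0, 0), pr), "integrator")
})

test_that("parameter sets validate their invariants", {
  expect_error(ng_params(bogus = 1), "unknown parameter")
  expect_error(ng_params(s4 = -3), "negative")
  expect_error(ng_params(k = 0), "k must be")
  expect_error(ng_params(h = 0.2), "h must be")
  expect_s3_class(ng_params(), "ng_params")
  expect_identical(ng_params()$n, 2) # Hill coefficient fixed to 2 by default
})

test_that("scenarios encode the culture conditions", {
  expect_identical(scenario("TwoI")$p_override, 0)
  expect_error(scenario("TwoI", p_override = 12), "forces")
  expect_error(scenario("LIF_serum", rex1_turnover_scale = 0.5), "outside")
  expect_error(scenario("N2B27_withdrawal", rex1_turnover_scale = 0), "0, 1")
  pr <- apply_scenario(lif_serum_params(), scenario("TwoI"))
  expect_identical(pr$p, 0)
  wd <- apply_scenario(lif_serum_params(),
                       scenario("N2B27_withdrawal", Y_level = 5,
                                rex1_turnover_scale = 0.25))
  expect_equal(wd$d_R, lif_serum_params()$d_R * 0.25)
  expect_equal(wd$s6 / wd$d_R, lif_serum_params()$s6 / lif_serum_params()$d_R)
  expect_equal(wd$Y, 5)
})

test_that("config files round-trip and report unknown/missing keys", {
  pr <- ng_params(sigma_N = 0.107)
  f1 <- withr::local_tempfile(fileext = ".cfg")
  f2 <- withr::local_tempfile(fileext = ".cfg")
  write_params_config(pr, f1)
  back <- read_params_config(f1)
  expect_equal(unclass(back), unclass(pr))
  write_params_config(back, f2)
  expect_identical(readLines(f1), readLines(f2)) # byte-identical round trip
  writeLines(c(readLines(f1), "mystery_rate = 3"), f2)
  expect_warning(read_params_config(f2), "mystery_rate")
  writeLines(readLines(f1)[-c(3, 18)], f2) # drop s4 and sigma_N
  expect_error(read_params_config(f2), "s4.*sigma_N|sigma_N.*s4")
})
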