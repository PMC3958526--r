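# Fixed points, stability, bifurcation structure, and the 1-D reduction
# that serves as the independent oracle for the 4-D root finder.

test_that("reduced Nanog map has the expected sign structure", {
  pr <- ref_params()
  OS_top <- max(find_fixed_points(pr)$OS)
  expect_gt(reduced_nanog_rhs(0, pr, OS_top), 0) # production beats decay at N = 0
  expect_lt(reduced_nanog_rhs(1e5, pr, OS_top), 0) # decay wins for large N
  expect_error(reduced_nanog_rhs(1, ng_params(Y = 2, base = pr), OS_top),
               "Y = 0")
})

test_that("4-D fixed points agree with the brute-force 1-D oracle on random sets", {
  sets <- random_param_sets(20)
  for (pr in sets) {
    fp <- find_fixed_points(pr)
    os_top <- max(fp$OS)
    skip_if(os_top <= 0) # degenerate draw without an OS-positive branch
    on_branch <- sort(fp$N[abs(fp$OS - os_top) < 1e-3 * os_top])
    oracle <- sort(nanogate:::reduced_nanog_roots(pr, os_top))
    expect_equal(length(on_branch), length(oracle))
    expect_equal(on_branch, oracle, tolerance = 1e-4)
  }
})

test_that("with all transcription off only the stable origin remains", {
  pr <- ng_params(s12 = 0, s3 = 0, s4 = 0, s5 = 0, s6 = 0, s7 = 0,
                  base = ref_params())
  fp <- find_fixed_points(pr)
  expect_equal(nrow(fp), 1)
  expect_equal(as.numeric(fp[1, c("OS", "N", "R", "E")]), rep(0, 4))
  expect_identical(fp$stability, "stable")
  # eigenvalues of the diagonal Jacobian are the negative degradation rates
  expect_equal(fp$eigenvalue_max_real, -min(unlist(pr[c("d_OS", "d_N",
                                                        "d_R", "d_E")])),
               tolerance = 1e-6)
})

test_that("the calibrated landscape is bistable under LIF/serum and monostable under 2i", {
  fp <- find_fixed_points(ref_params())
  stable_top <- fp[fp$branch %in% c("NL", "NH") & fp$stability == "stable", ]
  expect_equal(nrow(stable_top), 2)
  sep <- fp[fp$stability != "stable" &
              fp$N > min(stable_top$N) & fp$N < max(stable_top$N) &
              abs(fp$OS - max(fp$OS)) < 1, ]
  expect_equal(nrow(sep), 1) # coexisting stable states separated by a saddle
  fp0 <- find_fixed_points(two_i_params())
  expect_equal(sum(fp0$branch %in% c("NL", "NH") & fp0$stability == "stable"), 1)
  expect_identical(fp0$branch[fp0$branch %in% c("NL", "NH")], "NH")
  expect_error(find_fixed_points(ng_params(Y = 1, base = ref_params())),
               "Y must be 0")
})

test_that("stability labels agree with the sign of the reduced map derivative", {
  pr <- ref_params()
  fp <- find_fixed_points(pr)
  os_top <- max(fp$OS)
  top <- fp[abs(fp$OS - os_top) < 1e-3 * os_top, ]
  for (i in seq_len(nrow(top))) {
    eps <- max(1e-4, 1e-6 * top$N[i])
    dfdN <- (reduced_nanog_rhs(top$N[i] + eps, pr, os_top) -
               reduced_nanog_rhs(top$N[i] - eps, pr, os_top)) / (2 * eps)
    if (top$stability[i] == "stable") expect_lt(dfdN, 0)
    else expect_gt(dfdN, 0)
  }
})

test_that("bifurcation scans recover the bistable windows and branch labels", {
  pr <- ref_params()
  bs4 <- bifurcation_scan(pr, "s4", seq(5, 80, by = 5))
  bi <- bistable_interval(bs4)
  expect_true(all(c(30, 40, 50) >= bi[1] & c(30, 40, 50) <= bi[2]))
  # weak autoactivation: only the low state driven by Oct4-Sox2 remains
  low_end <- bs4[bs4$value == 5 & bs4$branch %in% c("NL", "NH") &
                   bs4$stability == "stable", ]
  expect_identical(low_end$branch, "NL")
  bp <- bifurcation_scan(pr, "p", seq(0, 36, by = 2))
  bip <- bistable_interval(bp)
  expect_true(bip[1] <= 15 && 15 <= bip[2]) # LIF/serum repression is bistable
  expect_gt(bip[1], 0) # 2i (p = 0) lies outside
  expect_error(bifurcation_scan(pr, "p", c(3, 1, 2)), "ascending")
})

test_that("removing the Erk repression shrinks the NL-only region of the s4 scan", {
  # the NL-only region ends where a stable NH state first appears
  nh_edge <- function(diagram) {
    has_nh <- tapply(diagram$branch == "NH" & diagram$stability == "stable",
                     diagram$value, any)
    min(as.numeric(names(has_nh)[has_nh]))
  }
  grid <- c(1, 2.5, 5, 10, 15, 20, 25)
  edge_p15 <- nh_edge(bifurcation_scan(ref_params(), "s4", grid))
  edge_p0 <- nh_edge(bifurcation_scan(two_i_params(), "s4", grid))
  expect_lt(edge_p0, edge_p15 / 2)
})

test_that("basin boundary is the separating saddle and is absent under 2i", {
  pr <- ref_params()
  b <- basin_boundary(pr)
  fp <- find_fixed_points(pr)
  expect_gt(b, fp$N[fp$branch == "NL"])
  expect_lt(b, fp$N[fp$branch == "NH"])
  os_top <- max(fp$OS)
  roots <- nanogate:::reduced_nanog_roots(pr, os_top)
  expect_equal(b, roots[2], tolerance = 1e-6) # middle root of the 1-D map
  expect_error(basin_boundary(two_i_params()), "not bistable|no basin")
})
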