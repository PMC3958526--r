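# Deterministic fixed points, stability classification and one-parameter
# bifurcation scans. All analysis here assumes Y = 0 (the pluripotency
# circuit alone); the Y > 0 regime is explored by simulation.

#' One-dimensional reduced Nanog dynamics
#'
#' At steady state with `Y = 0` the Oct4-Sox2 equation is autonomous and the
#' Erk level is slaved to it (`E* = s7 H(OS*) / d_E`), so all Nanog fixed
#' points on an Oct4-Sox2 branch are roots of the one-dimensional map
#' `f_N(N; OS*, E*)`. This reduction is the package's independent oracle for
#' the full four-dimensional root finder: sign changes of this function over
#' a dense `N` grid bracket every Nanog fixed point on that branch.
#'
#' @param N Nanog concentration(s), vectorised.
#' @param params an [ng_params()] object with `Y = 0` (the reduction is
#'   invalid when `Y_in` couples the equations; error otherwise).
#' @param OS_star a fixed point of the Oct4-Sox2 sub-equation.
#' @param E_star the slaved Erk level `s7 H(OS*) / d_E` (computed if `NULL`).
#' @return Rate(s) `f_N` (a.u./min).
#' @export
reduced_nanog_rhs <- function(N, params, OS_star, E_star = NULL) {
  stopifnot(inherits(params, "ng_params"))
  if (params$Y != 0)
    abort("reduced_nanog_rhs requires Y = 0 (reduction invalid when Y_in couples equations)")
  if (is.null(E_star)) E_star <- params$s7 * hill_act(OS_star, params$k, params$n) / params$d_E
  hOS <- hill_act(OS_star, params$k, params$n)
  hN <- hill_act(N, params$k, params$n)
  gp <- 1 / (1 + params$p * hill_act(E_star, params$k, params$n))
  (params$s3 * hOS + params$s4 * hN) * gp - params$d_N * N
}

# Brute-force root scan of the reduced 1-D map over a dense grid; used as an
# oracle in tests and by basin_boundary.
reduced_nanog_roots <- function(params, OS_star, n_grid = 4000) {
  E_star <- params$s7 * hill_act(OS_star, params$k, params$n) / params$d_E
  n_max <- 10 * (params$s3 + params$s4) / params$d_N
  grid <- seq(0, n_max, length.out = n_grid)
  f <- reduced_nanog_rhs(grid, params, OS_star, E_star)
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(function(x) reduced_nanog_rhs(x, params, OS_star, E_star),
                   lower = grid[i], upper = grid[i + 1], tol = 1e-12)$root
  }, numeric(1))
  # grid nodes that are exact roots (the origin when s3*H(OS*) = 0)
  exact <- grid[f == 0]
  sort(unique(c(roots, exact)))
}

drift_fun <- function(params) {
  function(x) deterministic_drift(pmax(x, 0), params)
}

fd_jacobian <- function(f, x, rel_step = 1e-6) {
  m <- length(f(x))
  J <- matrix(0, m, length(x))
  for (j in seq_along(x)) {
    hstep <- rel_step * max(abs(x[j]), 1)
    xp <- x; xm <- x
    xp[j] <- x[j] + hstep
    xm[j] <- max(x[j] - hstep, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

# damped Newton iteration with non-negativity projection
newton_root <- function(f, x0, tol = 1e-8, max_iter = 60) {
  x <- pmax(x0, 0)
  fx <- f(x)
  for (i in seq_len(max_iter)) {
    nrm <- sqrt(sum(fx^2))
    if (nrm < tol) return(list(root = x, norm = nrm, converged = TRUE))
    J <- fd_jacobian(f, x)
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) return(list(root = x, norm = nrm, converged = FALSE))
    lambda <- 1
    repeat {
      xn <- pmax(x + lambda * step, 0)
      fn <- f(xn)
      if (sqrt(sum(fn^2)) < nrm || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (sqrt(sum(fn^2)) >= nrm) # no descent possible
      return(list(root = x, norm = nrm, converged = FALSE))
    x <- xn; fx <- fn
  }
  list(root = x, norm = sqrt(sum(fx^2)), converged = sqrt(sum(fx^2)) < tol)
}

#' Classify the linear stability of a fixed point
#'
#' Computes the 4x4 Jacobian of [deterministic_drift()] by central finite
#' differences (relative step `1e-6`) and labels the point by the real parts
#' of its eigenvalues: `stable` if all are below `-tol_eig`, `unstable` if
#' all are above `+tol_eig`, `saddle` for a mixture, and `marginal` (with a
#' warning) if any real part lies within `tol_eig` of zero.
#'
#' @param state fixed-point state `(OS, N, R, E)`.
#' @param params an [ng_params()] object.
#' @param tol_eig half-width of the marginal band around zero.
#' @return A list with `stability` (character) and `eigenvalue_max_real`.
#' @export
classify_stability <- function(state, params, tol_eig = 1e-8) {
  J <- fd_jacobian(drift_fun(params), as.numeric(state))
  re <- Re(eigen(J, only.values = TRUE)$values)
  mx <- max(re)
  stability <- if (any(abs(re) < tol_eig)) {
    warn("eigenvalue real part within tolerance of 0: marginal fixed point")
    "marginal"
  } else if (all(re < 0)) "stable"
  else if (all(re > 0)) "unstable"
  else "saddle"
  list(stability = stability, eigenvalue_max_real = mx)
}

#' Find all deterministic fixed points
#'
#' Multi-start damped Newton iteration on the full four-variable drift with
#' `Y = 0`. Starts are a deterministic lattice: logarithmically spaced
#' Oct4-Sox2 and Nanog values spanning twice the maximal
#' production/degradation ratio, with Rex1 and Erk started at their
#' algebraically slaved values, plus the origin. Converged roots are
#' deduplicated at relative distance `dedup_tol` and classified by
#' [classify_stability()]. Each point is labelled by branch: `origin`,
#' `NL`/`NH` for stable points on the Oct4-Sox2-positive branch (ordered by
#' Nanog; a single stable point is `NH` when its Nanog autoactivation is
#' saturated above half-maximum, `NL` otherwise), `other` for the remaining
#' saddles.
#'
#' @param params an [ng_params()] object with `Y = 0`.
#' @param tol_fp convergence tolerance on the drift norm (a.u./min).
#' @param dedup_tol relative deduplication distance.
#' @param n_start lattice points per axis for the (OS, N) start grid.
#' @return A tibble with columns `OS`, `N`, `R`, `E`, `stability`, `branch`,
#'   `eigenvalue_max_real`, ordered by increasing `N`. Always contains the
#'   origin.
#' @export
find_fixed_points <- function(params, tol_fp = 1e-8, dedup_tol = 1e-6,
                              n_start = 7) {
  stopifnot(inherits(params, "ng_params"))
  if (params$Y != 0)
    abort("find_fixed_points analyses the pluripotency circuit alone: Y must be 0")
  f <- drift_fun(params)
  os_max <- 2 * params$s12 / params$d_OS
  n_max <- 2 * (params$s3 + params$s4) / params$d_N
  log_lattice <- function(top) {
    if (top <= 0) return(0)
    c(0, exp(seq(log(top * 1e-4), log(top), length.out = n_start)))
  }
  os_grid <- log_lattice(os_max)
  n_grid <- log_lattice(n_max)
  starts <- expand.grid(OS = os_grid, N = n_grid)
  roots <- list(); norms <- numeric(0)
  for (i in seq_len(nrow(starts))) {
    OS0 <- starts$OS[i]; N0 <- starts$N[i]
    R0 <- (params$s5 * hill_act(OS0, params$k, params$n) +
             params$s6 * hill_act(N0, params$k, params$n)) / params$d_R
    E0 <- params$s7 * hill_act(OS0, params$k, params$n) / params$d_E
    res <- newton_root(f, c(OS0, N0, R0, E0), tol = tol_fp)
    if (res$converged) {
      roots[[length(roots) + 1]] <- res$root
    } else {
      norms <- c(norms, res$norm)
    }
  }
  if (length(roots) == 0)
    abort(paste0("fixed-point search failed to converge from all starts; ",
                 "residual norms: ", paste(signif(norms, 3), collapse = ", ")))
  pts <- do.call(rbind, roots)
  scale <- pmax(sqrt(rowSums(pts^2)), 1)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(pts))) {
      if (j <= i || !keep[j]) next
      if (sqrt(sum((pts[i, ] - pts[j, ])^2)) < dedup_tol * scale[i])
        keep[j] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  cls <- apply(pts, 1, classify_stability, params = params)
  out <- tibble(
    OS = pts[, 1], N = pts[, 2], R = pts[, 3], E = pts[, 4],
    stability = vapply(cls, `[[`, character(1), "stability"),
    eigenvalue_max_real = vapply(cls, `[[`, numeric(1), "eigenvalue_max_real")
  )
  out <- label_branches(out, params)
  arrange(out, .data$N)
}

label_branches <- function(fp, params) {
  os_top <- max(fp$OS)
  scale <- max(os_top, 1)
  fp$branch <- "other"
  fp$branch[fp$OS < 1e-6 * scale & fp$N < 1e-6 * scale] <- "origin"
  on_top <- abs(fp$OS - os_top) < 1e-3 * scale & fp$branch != "origin" & os_top > 0
  stable_top <- which(on_top & fp$stability == "stable")
  if (length(stable_top) >= 2) {
    ord <- stable_top[order(fp$N[stable_top])]
    fp$branch[ord[1]] <- "NL"
    fp$branch[ord[length(ord)]] <- "NH"
  } else if (length(stable_top) == 1) {
    hN <- hill_act(fp$N[stable_top], params$k, params$n)
    fp$branch[stable_top] <- if (hN > 0.5) "NH" else "NL"
  }
  fp
}

#' One-parameter bifurcation scan
#'
#' Runs [find_fixed_points()] at each grid value of the scanned parameter
#' (`s4`, the Nanog autoregulatory transcription rate, or `p`, the Erk
#' repression strength) and reports all branches. The bistable interval is
#' the maximal contiguous grid sub-range on which exactly two stable
#' Oct4-Sox2-positive fixed points coexist; within it the stable Nanog-low
#' and Nanog-high branches are separated by an unstable (saddle) branch.
#' Continuation is naive (independent solves per grid value linked by the
#' per-value branch labels); branches here are well separated in Nanog, so
#' nearest-neighbour identity is unambiguous away from the folds.
#'
#' @param params base [ng_params()] object (`Y = 0`).
#' @param parameter `"s4"` or `"p"`.
#' @param grid ascending parameter values.
#' @return An `ng_bifurcation` tibble with columns `parameter`, `value`,
#'   `branch`, `stability`, `OS`, `N`, `R`, `E`, `eigenvalue_max_real`, and
#'   attribute `bistable_interval` (`c(lo, hi)` or `NULL`).
#' @export
bifurcation_scan <- function(params, parameter = c("s4", "p"), grid) {
  parameter <- match.arg(parameter)
  if (is.unsorted(grid, strictly = TRUE))
    abort("grid must be sorted ascending")
  rows <- purrr::map(grid, function(v) {
    pr <- do.call(ng_params, setNames(list(v, params), c(parameter, "base")))
    fp <- find_fixed_points(pr)
    fp$value <- v
    fp
  })
  out <- bind_rows(rows)
  out$parameter <- parameter
  out <- select(out, "parameter", "value", "branch", "stability",
                "OS", "N", "R", "E", "eigenvalue_max_real")
  n_stable_top <- out %>%
    filter(.data$stability == "stable", .data$branch %in% c("NL", "NH")) %>%
    group_by(.data$value) %>%
    summarise(n2 = dplyr::n() == 2, .groups = "drop")
  bi <- n_stable_top$value[n_stable_top$n2]
  interval <- NULL
  if (length(bi) > 0) {
    # maximal contiguous run of grid values with two stable states
    idx <- match(bi, grid)
    runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
    best <- runs[[which.max(lengths(runs))]]
    interval <- c(grid[min(best)], grid[max(best)])
  }
  structure(out, class = c("ng_bifurcation", class(out)),
            bistable_interval = interval)
}

#' @export
print.ng_bifurcation <- function(x, ...) {
  bi <- attr(x, "bistable_interval")
  cat("<ng_bifurcation> scan over", x$parameter[1], "\n")
  if (is.null(bi)) cat("no bistable interval on this grid\n")
  else cat("bistable interval: [", bi[1], ",", bi[2], "]\n")
  NextMethod()
}

#' Bistable interval of a bifurcation scan
#' @param diagram an `ng_bifurcation` object.
#' @return `c(lo, hi)` or `NULL`.
#' @export
bistable_interval <- function(diagram) {
  attr(diagram, "bistable_interval")
}

#' Nanog threshold separating the NL and NH attractor basins
#'
#' Returns the Nanog coordinate of the unstable fixed point lying between
#' the stable Nanog-low and Nanog-high states on the Oct4-Sox2-positive
#' branch. For monostable parameter sets (e.g. 2i, where `p = 0` removes the
#' low state and stochastic state transitions are not possible) there is no
#' basin boundary and an error is raised.
#'
#' @param params an [ng_params()] object with `Y = 0`, bistable.
#' @return Nanog threshold (a.u.).
#' @export
basin_boundary <- function(params) {
  fp <- find_fixed_points(params)
  nl <- fp$N[fp$branch == "NL"]
  nh <- fp$N[fp$branch == "NH"]
  if (length(nl) != 1 || length(nh) != 1)
    abort("no basin boundary: the deterministic system is not bistable at these parameters")
  os_top <- fp$OS[fp$branch == "NH"]
  sep <- fp %>% filter(.data$stability != "stable", .data$N > nl, .data$N < nh,
                       abs(.data$OS - os_top) < 1e-3 * max(os_top, 1))
  if (nrow(sep) == 0)
    abort("no basin boundary: no unstable fixed point between NL and NH")
  sep$N[which.min(abs(sep$N - sqrt(nl * nh)))]
}
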