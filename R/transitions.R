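# Attractor-basin classification, valid state transitions, residence
# statistics, and the s4 x sigma_N sweeps.
#
# A state transition is a crossing of the Nanog basin boundary followed by
# at least `min_residence` minutes of continuous residence on the
# destination side (default 60 min, i.e. "more than one hour"). Shorter
# excursions are stochastic fluctuations: they are ignored and do not reset
# the cell's basin label. Basin membership is assessed on the raw Nanog
# series without smoothing; the residence rule itself filters fluctuations.

# core detector: times (min, uniform), N series, boundary, min_residence.
# Returns integer indices of valid crossing samples and the basin sequence.
detect_core <- function(times, N, boundary, min_residence) {
  side <- N >= boundary # TRUE = NH side
  r <- rle(side)
  starts <- cumsum(c(1, head(r$lengths, -1)))
  start_t <- times[starts]
  # run duration: time to the start of the next run; last run extends to end
  dur <- c(diff(start_t), times[length(times)] - start_t[length(start_t)])
  basin <- r$values[1]
  ev_idx <- integer(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] != basin && dur[i] >= min_residence) {
      ev_idx <- c(ev_idx, starts[i])
      basin <- r$values[i]
    }
  }
  list(ev_idx = ev_idx, final_basin = basin, initial_basin = r$values[1])
}

#' Detect valid state transitions in a Nanog trajectory
#'
#' Scans the Nanog series of a trajectory for crossings of the basin
#' boundary that are followed by at least `min_residence` minutes of
#' continuous residence in the destination basin (the validity rule that
#' separates substantial expression changes from stochastic fluctuations).
#'
#' @param traj an `ng_trajectory` tibble (columns `t_min`, `N`), or any data
#'   frame with those columns sampled on a uniform grid.
#' @param boundary Nanog threshold from [basin_boundary()].
#' @param min_residence minutes of continuous residence required (default 60).
#' @return A tibble of transition events: `cell_id`, `t_min` (boundary
#'   crossing), `direction` (`"NH->NL"` or `"NL->NH"`), and
#'   `residence_in_destination` (minutes until the next valid transition, or
#'   until the trajectory end — then flagged `censored = TRUE`).
#' @export
detect_transitions <- function(traj, boundary, min_residence = 60) {
  t_min <- traj$t_min
  if (max(t_min) - min(t_min) < min_residence) {
    warn("trajectory shorter than min_residence: no transition can be validated")
    return(empty_events())
  }
  cell <- if ("cell_id" %in% names(traj)) traj$cell_id[1] else 1L
  res <- detect_core(t_min, traj$N, boundary, min_residence)
  events_from_idx(res$ev_idx, t_min, traj$N, boundary, cell)
}

empty_events <- function() {
  tibble(cell_id = integer(0), t_min = numeric(0), direction = character(0),
         residence_in_destination = numeric(0), censored = logical(0))
}

events_from_idx <- function(ev_idx, times, N, boundary, cell) {
  if (length(ev_idx) == 0) return(empty_events())
  t_ev <- times[ev_idx]
  dir <- ifelse(N[ev_idx] >= boundary, "NL->NH", "NH->NL")
  nxt <- c(t_ev[-1], times[length(times)])
  tibble(cell_id = cell, t_min = t_ev, direction = dir,
         residence_in_destination = nxt - t_ev,
         censored = c(rep(FALSE, length(t_ev) - 1), TRUE))
}

#' Detect transitions for every cell of a population run
#'
#' @param run an `ng_population` with Nanog recorded at a uniform grid.
#' @inheritParams detect_transitions
#' @return A tibble as [detect_transitions()], all cells stacked.
#' @export
population_transitions <- function(run, boundary, min_residence = 60) {
  stopifnot(inherits(run, "ng_population"))
  Nm <- species_matrix(run, "N")
  times <- run$times
  purrr::map_dfr(seq_len(run$n_cells), function(j) {
    res <- detect_core(times, Nm[, j], boundary, min_residence)
    events_from_idx(res$ev_idx, times, Nm[, j], boundary, j)
  })
}

#' Basin residence intervals of a population run
#'
#' Splits each cell's time axis at its valid transitions. Intervals bounded
#' by two valid transitions are uncensored; the leading and trailing
#' intervals are truncated by the simulation window and flagged censored.
#'
#' @inheritParams population_transitions
#' @return A tibble: `cell_id`, `basin` (`"NH"`/`"NL"`), `start`, `end`
#'   (minutes), `censored`.
#' @export
residence_records <- function(run, boundary, min_residence = 60) {
  stopifnot(inherits(run, "ng_population"))
  Nm <- species_matrix(run, "N")
  times <- run$times
  t_end <- times[length(times)]
  purrr::map_dfr(seq_len(run$n_cells), function(j) {
    res <- detect_core(times, Nm[, j], boundary, min_residence)
    t_ev <- times[res$ev_idx]
    bounds <- c(times[1], t_ev, t_end)
    k <- length(bounds) - 1
    basins <- rep(c(res$initial_basin, !res$initial_basin), length.out = k)
    tibble(cell_id = j,
           basin = ifelse(basins, "NH", "NL"),
           start = bounds[seq_len(k)],
           end = bounds[-1],
           censored = seq_len(k) == 1 | seq_len(k) == k)
  })
}

#' Transition rate per cell per 24 h
#'
#' @param events event tibble from [population_transitions()] (or
#'   [detect_transitions()]).
#' @param n_cells number of simulated cells (cells without events count in
#'   the denominator).
#' @param duration trajectory length in minutes.
#' @param ci_reps bootstrap replicates over cells (0 disables the CI).
#' @param ci_seed seed for the bootstrap resampling.
#' @return One-row tibble: `n_events`, `rate_per_day`, `rate_per_hour`,
#'   `ci_lo`, `ci_hi` (95% bootstrap CI of the per-day rate, resampling
#'   cells).
#' @export
transition_rate <- function(events, n_cells, duration, ci_reps = 1000,
                            ci_seed = 1) {
  if (duration <= 0) abort("duration must be > 0")
  cell_days <- n_cells * duration / 1440
  rate <- nrow(events) / cell_days
  ci <- c(NA_real_, NA_real_)
  if (ci_reps > 0 && n_cells > 1) {
    counts <- tabulate(factor(events$cell_id, levels = seq_len(n_cells)),
                       nbins = n_cells)
    ci <- withr::with_seed(ci_seed, {
      reps <- vapply(seq_len(ci_reps), function(i) {
        mean(counts[sample.int(n_cells, replace = TRUE)])
      }, numeric(1))
      quantile(reps / (duration / 1440), c(0.025, 0.975), names = FALSE)
    })
  }
  tibble(n_events = nrow(events), rate_per_day = rate,
         rate_per_hour = rate / 24, ci_lo = ci[1], ci_hi = ci[2])
}

#' Residence-time statistics per basin
#'
#' Collects uncensored residence intervals per basin, reports their mean (in
#' days), the maximum-likelihood exponential rate, and the maximum distance
#' between the empirical CDF and the fitted exponential CDF as a
#' goodness-of-fit statistic. Basins with fewer than `min_records`
#' uncensored intervals are flagged insufficient.
#'
#' @param records residence tibble from [residence_records()].
#' @param min_records minimum uncensored intervals per basin.
#' @return A tibble with one row per basin: `basin`, `n_uncensored`,
#'   `n_censored`, `mean_days`, `rate_per_day` (MLE), `ks_distance`,
#'   `insufficient`.
#' @export
residence_statistics <- function(records, min_records = 10) {
  purrr::map_dfr(c("NH", "NL"), function(b) {
    rec <- records[records$basin == b, ]
    unc <- rec[!rec$censored, ]
    durs <- (unc$end - unc$start) / 1440
    n <- length(durs)
    if (n < min_records) {
      return(tibble(basin = b, n_uncensored = n, n_censored = sum(rec$censored),
                    mean_days = if (n > 0) mean(durs) else NA_real_,
                    rate_per_day = NA_real_, ks_distance = NA_real_,
                    insufficient = TRUE))
    }
    m <- mean(durs)
    emp <- ecdf(durs)
    grid <- sort(durs)
    ks <- max(abs(emp(grid) - stats::pexp(grid, rate = 1 / m)),
              abs(emp(grid) - 1 / n - stats::pexp(grid, rate = 1 / m)))
    tibble(basin = b, n_uncensored = n, n_censored = sum(rec$censored),
           mean_days = m, rate_per_day = 1 / m, ks_distance = ks,
           insufficient = FALSE)
  })
}

#' Proportion of Nanog-low cells over an s4 x sigma_N grid
#'
#' For each combination of the Nanog autoregulatory transcription rate `s4`
#' and the Nanog noise amplitude `sigma_N`, simulates a population for
#' `duration` minutes and reports the fraction of cells on the Nanog-low
#' side of the basin boundary at the final snapshot. The boundary is
#' recomputed per `s4`; for monostable `s4` values cells are classified
#' against the Nanog value of the unique stable state's half-distance to
#' zero or, when only the high state exists, all-NH unless below half the
#' stable Nanog level.
#'
#' @param params_base base [ng_params()] (LIF/serum scenario).
#' @param s4_grid,sigma_grid grids of `s4` and `sigma_N` values.
#' @param n_cells cells per grid point.
#' @param duration minutes (default 4320, i.e. 3 days).
#' @param init init policy passed to [simulate_population()]; the default
#'   starts every cell in the prevailing Nanog-high state.
#' @param dt,master_seed integrator settings; the master seed is varied
#'   deterministically across grid points.
#' @return An `ng_sweep` tibble in long format: `s4`, `sigma_N`,
#'   `nl_fraction`, `n_cells`, `seed`.
#' @export
nl_fraction_sweep <- function(params_base, s4_grid, sigma_grid, n_cells,
                              duration = 4320, init = "at_NH", dt = 0.1,
                              master_seed = 1) {
  if (length(s4_grid) == 0 || length(sigma_grid) == 0)
    abort("grids must be nonempty")
  combos <- expand.grid(s4 = s4_grid, sigma_N = sigma_grid)
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    s4 <- combos$s4[i]; sg <- combos$sigma_N[i]
    pr <- ng_params(s4 = s4, sigma_N = sg, base = params_base)
    thr <- nl_threshold(pr)
    seed_i <- master_seed + 7919 * (i - 1)
    # monostable grid values have no NH state to start from; every cell
    # then starts in the unique stable state
    init_i <- init
    if (identical(init, "at_NH")) {
      fp <- find_fixed_points(pr)
      stable <- fp[fp$branch %in% c("NL", "NH") & fp$stability == "stable", ]
      pick <- if (any(stable$branch == "NH")) "NH" else stable$branch[1]
      init_i <- as.numeric(stable[stable$branch == pick, c("OS", "N", "R", "E")])
    }
    run <- tryCatch(
      simulate_population(pr, n_cells = n_cells, init = init_i,
                          duration = duration, dt = dt,
                          master_seed = seed_i, species = "N"),
      error = function(e) abort(paste0("sweep failed at s4=", s4, ", sigma_N=",
                                       sg, ": ", conditionMessage(e))))
    tibble(s4 = s4, sigma_N = sg,
           nl_fraction = mean(terminal_states(run)$N < thr),
           n_cells = n_cells, seed = seed_i)
  })
  out <- bind_rows(rows)
  structure(out, class = c("ng_sweep", class(out)))
}

# Snapshot classification threshold: the separating unstable point when
# bistable. For monostable parameters every cell belongs to the basin of
# the unique stable state (nearest-stable-state rule): the threshold
# degenerates to +Inf (only NL exists) or 0 (only NH exists).
nl_threshold <- function(params) {
  tryCatch(basin_boundary(params), error = function(e) {
    fp <- find_fixed_points(params)
    stable <- fp[fp$stability == "stable" & fp$branch %in% c("NL", "NH"), ]
    if (nrow(stable) == 0) abort("no stable Oct4-Sox2-positive state")
    if (stable$branch[1] == "NH") 0 else Inf
  })
}

#' Transitions-per-day curves over the noise grid
#'
#' For each `s4` (which must lie in the bistable interval) and each
#' `sigma_N`, simulates a population and reports the mean and standard
#' deviation across cells of the number of valid transitions per cell per
#' 24 h. The non-monotone shape of these curves -- rising from zero with
#' noise, then declining when noise overwhelms the attractor dynamics so
#' that cells no longer reside anywhere long enough to validate a
#' transition -- is the model's signature of noise-regulated switching.
#'
#' @inheritParams nl_fraction_sweep
#' @param s4_values `s4` values, each inside the bistable interval.
#' @param record_every sampling interval of the Nanog series (min).
#' @return A tibble: `s4`, `sigma_N`, `mean_per_day`, `sd_per_day`,
#'   `n_events`, `seed`.
#' @export
transitions_vs_noise <- function(params_base, s4_values, sigma_grid, n_cells,
                                 duration = 4320, dt = 0.1, record_every = 1,
                                 master_seed = 1) {
  days <- duration / 1440
  rows <- list()
  for (s4 in s4_values) {
    pr0 <- ng_params(s4 = s4, base = params_base)
    thr <- tryCatch(basin_boundary(pr0), error = function(e)
      abort(paste0("s4 = ", s4, " is outside the bistable interval; ",
                   "check bifurcation_scan(params, 's4', ...)")))
    for (sg in sigma_grid) {
      pr <- ng_params(sigma_N = sg, base = pr0)
      seed_i <- master_seed + 104729 * length(rows)
      run <- simulate_population(pr, n_cells = n_cells, init = "at_NH",
                                 duration = duration, dt = dt,
                                 master_seed = seed_i,
                                 record_every = record_every, species = "N")
      ev <- population_transitions(run, thr)
      counts <- tabulate(factor(ev$cell_id, levels = seq_len(n_cells)),
                         nbins = n_cells) / days
      rows[[length(rows) + 1]] <-
        tibble(s4 = s4, sigma_N = sg, mean_per_day = mean(counts),
               sd_per_day = sd(counts), n_events = nrow(ev), seed = seed_i)
    }
  }
  bind_rows(rows)
}

#' Write transition events / sweep results as CSV
#'
#' Events: columns `(cell_id, t_min, direction, residence_min)`. Sweeps:
#' long format `(s4, sigma_N, nl_fraction, n_cells, seed)`.
#'
#' @param x event or sweep tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(x, path) {
  out <- tibble(cell_id = x$cell_id, t_min = x$t_min, direction = x$direction,
                residence_min = x$residence_in_destination)
  readr::write_csv(out, path)
  invisible(path)
}

#' @method autoplot ng_sweep
#' @export
autoplot.ng_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s4, y = .data$sigma_N,
                                       fill = .data$nl_fraction)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = expression(s[4]), y = expression(sigma[N]),
                  fill = "NL fraction")
}
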