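# Differentiation experiments: the Nanog gate on the extrinsic signal Y and
# the 2i-withdrawal time course with a per-cell stochastic ramp of the Erk
# repression rate p.

#' Specify the stochastic ramp of the Erk repression rate
#'
#' After 2i withdrawal, Erk activity accumulates: the repression rate rises
#' from ~0 to `p_max` along a logistic ramp
#' `p_i(t) = p_max / (1 + exp(-slope (t - t_mid_i)))`. The midpoint
#' `t_mid_i` is drawn per cell from a lognormal distribution (median
#' `t_mid_median` minutes, log-sd `t_mid_logsd`), modelling cell-to-cell
#' variation in the transduction of autocrine FGF4 signalling. With
#' `t_mid_logsd = 0` the population responds synchronously; the spread of
#' midpoints is what makes Rex1 downregulation asynchronous.
#'
#' `p_max` must exceed the upper end of the bistable p-interval so that the
#' Nanog-high state vanishes and every cell is eventually forced into the
#' Nanog-low state.
#'
#' @param p_max terminal repression strength (default 40, beyond the fold of
#'   the reference set whose bistable interval ends near 28).
#' @param t_mid_median median ramp midpoint, minutes (default 12 h).
#' @param t_mid_logsd log-sd of the midpoint distribution.
#' @param slope logistic steepness, 1/min.
#' @return An object of class `ng_ramp_spec`.
#' @export
ramp_spec <- function(p_max = 40, t_mid_median = 720, t_mid_logsd = 0.5,
                      slope = 0.015) {
  if (p_max < 0) abort("p_max must be >= 0")
  if (t_mid_median <= 0) abort("t_mid_median must be > 0")
  if (t_mid_logsd < 0) abort("t_mid_logsd must be >= 0")
  if (slope <= 0) abort("slope must be > 0")
  structure(list(p_max = p_max, t_mid_median = t_mid_median,
                 t_mid_logsd = t_mid_logsd, slope = slope),
            class = "ng_ramp_spec")
}

#' Sample per-cell repression ramps
#'
#' Draws one ramp midpoint per cell and returns the midpoints together with
#' an evaluator for the per-cell repression rate `p_i(t)`. Deterministic
#' given `master_seed`.
#'
#' @param spec an [ramp_spec()] object.
#' @param n_cells number of cells.
#' @param master_seed integer seed.
#' @return A list with `t_mid` (length `n_cells`), `spec`, and `p_of_t`, a
#'   function `(t, cell)` returning the repression rate.
#' @export
sample_ramps <- function(spec, n_cells, master_seed = 1) {
  stopifnot(inherits(spec, "ng_ramp_spec"))
  t_mid <- withr::with_seed(master_seed, {
    rlnorm(n_cells, meanlog = log(spec$t_mid_median), sdlog = spec$t_mid_logsd)
  })
  list(t_mid = t_mid, spec = spec,
       p_of_t = function(t, cell) {
         spec$p_max / (1 + exp(-spec$slope * (t - t_mid[cell])))
       })
}

#' Simulate differentiation after 2i withdrawal
#'
#' Cells start at the 2i Nanog-high fixed point (`params_2i` must have
#' `p = 0`). At `t = 0` the inhibitors are removed: each cell's repression
#' rate follows its own stochastic ramp, the extrinsic differentiation
#' signal is set to `Y_level`, and the Rex1 turnover (`s5`, `s6`, `d_R`) is
#' scaled by `rex1_turnover_scale` (steady level preserved, kinetics
#' slowed). The induced sequence is: Nanog falls from NH to NL once the ramp
#' passes the fold of the bistable interval; low Nanog opens the gate
#' (`Y_in` rises); enhanced degradation then collapses Oct4-Sox2, which is
#' the differentiated state. A cell is classified differentiated once its
#' Oct4-Sox2 level stays below `os_threshold` times the initial Oct4-Sox2
#' level for at least 60 consecutive minutes; the classification is
#' absorbing (no reversion into pluripotency).
#'
#' @param params_2i an [ng_params()] object with `p = 0`.
#' @param ramp an [ramp_spec()] object.
#' @param Y_level extrinsic signal strength during withdrawal.
#' @param rex1_turnover_scale factor in (0, 1] on `s5`, `s6`, `d_R`.
#' @param n_cells number of cells.
#' @param duration minutes (default 48 h).
#' @param dt integration step, minutes.
#' @param master_seed integer seed (drives both the ramp midpoints and the
#'   simulation noise).
#' @param os_threshold fraction of the initial Oct4-Sox2 level below which a
#'   cell counts as Oct4-Sox2-negative.
#' @param record_every snapshot spacing, minutes.
#' @return An `ng_diffrun` object with elements `timecourse` (tibble:
#'   `t_min`, `mean_OS`, `mean_N`, `mean_R`, `sd_N`, `sd_R`,
#'   `frac_differentiated`, means normalised to 1 at `t = 0`), `outcomes`
#'   (tibble: `cell_id`, `t_diff_min` or `NA`, `final_basin`), `run`
#'   (the `ng_population`), and metadata (`ramp`, `t_mid`, `Y_level`,
#'   `rex1_turnover_scale`). Reported differentiated counts reflect the
#'   model without proliferation or cell death; absolute fractions are not
#'   quantitative predictions.
#' @export
simulate_differentiation <- function(params_2i, ramp = ramp_spec(),
                                     Y_level = 5, rex1_turnover_scale = 0.06,
                                     n_cells = 200, duration = 2880, dt = 0.1,
                                     master_seed = 1, os_threshold = 0.1,
                                     record_every = 10) {
  stopifnot(inherits(params_2i, "ng_params"))
  if (params_2i$p != 0)
    abort("params_2i must have p = 0 (cells start from the 2i ground state)")
  scn <- scenario("N2B27_withdrawal", Y_level = Y_level,
                  rex1_turnover_scale = rex1_turnover_scale)
  pr <- apply_scenario(params_2i, scn)
  # start at the 2i NH fixed point of the *unscaled* Rex1 turnover (the
  # culture before withdrawal), Y = 0 there
  fp <- find_fixed_points(params_2i)
  nh <- fp[fp$branch == "NH", ]
  if (nrow(nh) != 1) abort("params_2i has no unique Nanog-high state")
  init <- as.numeric(nh[1, c("OS", "N", "R", "E")])
  ramps <- sample_ramps(ramp, n_cells, master_seed)
  rec_times <- seq(0, duration, by = record_every)
  raw <- sim_population_cpp(par_vector(pr),
                            matrix(rep(init, each = n_cells), ncol = 4),
                            duration, dt, master_seed + 1, rec_times,
                            rep(TRUE, 4),
                            TRUE, ramps$t_mid, ramp$p_max, ramp$slope,
                            seq_len(n_cells))
  run <- structure(list(times = raw$times, OS = raw$OS, N = raw$N, R = raw$R,
                        E = raw$E, n_cells = n_cells, dt = dt,
                        master_seed = master_seed + 1, duration = duration,
                        params = pr, species = c("OS", "N", "R", "E")),
                   class = "ng_population")
  outcomes <- classify_differentiation(run, init[1] * os_threshold,
                                       min_persist = 60)
  # basin of undifferentiated cells relative to the LIF-like bistable layout
  # is not defined here (p varies per cell); report terminal Nanog side of
  # the withdrawal endpoint landscape instead
  tc <- tibble(
    t_min = run$times,
    mean_OS = rowMeans(run$OS) / init[1],
    mean_N = rowMeans(run$N) / init[2],
    mean_R = rowMeans(run$R) / init[3],
    sd_N = apply(run$N / init[2], 1, sd),
    sd_R = apply(run$R / init[3], 1, sd),
    frac_differentiated = vapply(run$times, function(t) {
      mean(!is.na(outcomes$t_diff_min) & outcomes$t_diff_min <= t)
    }, numeric(1))
  )
  structure(list(timecourse = tc, outcomes = outcomes, run = run,
                 ramp = ramp, t_mid = ramps$t_mid, Y_level = Y_level,
                 rex1_turnover_scale = rex1_turnover_scale,
                 init = init, os_threshold = os_threshold),
            class = "ng_diffrun")
}

# absorbing classification: first time OS stays below `threshold` for
# >= min_persist minutes continuously. Undifferentiated cells are labelled
# NL once their Nanog has fallen below a tenth of its starting level.
classify_differentiation <- function(run, threshold, min_persist = 60) {
  times <- run$times
  purrr::map_dfr(seq_len(run$n_cells), function(j) {
    low <- run$OS[, j] < threshold
    r <- rle(low)
    starts <- cumsum(c(1, head(r$lengths, -1)))
    start_t <- times[starts]
    dur <- c(diff(start_t), times[length(times)] - start_t[length(start_t)])
    ok <- which(r$values & dur >= min_persist)
    t_diff <- if (length(ok) > 0) start_t[ok[1]] else NA_real_
    n_low <- !is.null(run$N) && run$N[length(times), j] < 0.1 * run$N[1, j]
    tibble(cell_id = j, t_diff_min = t_diff,
           final_basin = if (!is.na(t_diff)) "differentiated"
                         else if (n_low) "NL" else "NH")
  })
}

#' @export
print.ng_diffrun <- function(x, ...) {
  n_diff <- sum(!is.na(x$outcomes$t_diff_min))
  cat("<ng_diffrun>", x$run$n_cells, "cells,", x$run$duration / 60, "h,",
      "Y =", x$Y_level, "\n")
  cat(sprintf("differentiated: %d/%d (%.1f%%)\n", n_diff, x$run$n_cells,
              100 * n_diff / x$run$n_cells))
  cat("note: absolute differentiated fractions are not quantitative\n")
  cat("predictions (proliferation and cell death are not modelled)\n")
  invisible(x)
}

#' @method autoplot ng_diffrun
#' @export
autoplot.ng_diffrun <- function(object, ...) {
  tc <- tidyr::pivot_longer(object$timecourse,
                            cols = c("mean_OS", "mean_N", "mean_R"),
                            names_to = "species", values_to = "rel")
  ggplot2::ggplot(tc, ggplot2::aes(x = .data$t_min / 60, y = .data$rel,
                                   colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time after 2i withdrawal (h)",
                  y = "population mean (relative to t = 0)", colour = NULL)
}

#' Terminal cell fractions versus the differentiation signal
#'
#' For each value of the extrinsic signal `Y`, simulates a LIF/serum
#' population for `duration` minutes (starting from the Nanog-high state)
#' and reports the terminal fractions of undifferentiated Nanog-high,
#' undifferentiated Nanog-low, and differentiated (Oct4-Sox2-negative)
#' cells. With `Y = 0` the gate output `Y_in` is zero everywhere and no
#' cell differentiates; for strong `Y` essentially every cell that enters
#' the Nanog-low basin loses Oct4-Sox2, so the differentiated fraction
#' approaches the accumulated NL occupancy; at intermediate `Y` some
#' Nanog-low cells re-express Nanog while others differentiate by chance.
#'
#' @param params_LIF a bistable [ng_params()] set (the LIF/serum scenario).
#' @param Y_grid signal levels to test.
#' @param n_cells cells per level.
#' @param duration minutes (default 3 days).
#' @param dt step, minutes.
#' @param master_seed seed; the same cell streams are reused across `Y`
#'   levels (paired comparison).
#' @param os_threshold Oct4-Sox2-negative cutoff as in
#'   [simulate_differentiation()].
#' @return A tibble: `Y`, `frac_NH`, `frac_NL`, `frac_differentiated`,
#'   `n_cells`, `seed`.
#' @export
differentiated_fraction_vs_Y <- function(params_LIF, Y_grid, n_cells = 500,
                                         duration = 4320, dt = 0.1,
                                         master_seed = 1, os_threshold = 0.1) {
  stopifnot(inherits(params_LIF, "ng_params"))
  boundary <- basin_boundary(ng_params(Y = 0, base = params_LIF))
  fp <- find_fixed_points(ng_params(Y = 0, base = params_LIF))
  nh <- fp[fp$branch == "NH", ]
  init <- as.numeric(nh[1, c("OS", "N", "R", "E")])
  purrr::map_dfr(Y_grid, function(y) {
    pr <- ng_params(Y = y, base = params_LIF)
    run <- simulate_population(pr, n_cells = n_cells, init = init,
                               duration = duration, dt = dt,
                               master_seed = master_seed,
                               record_every = 10,
                               species = c("OS", "N"))
    out <- classify_differentiation(run, init[1] * os_threshold)
    diff <- !is.na(out$t_diff_min)
    termN <- run$N[length(run$times), ]
    tibble(Y = y,
           frac_NH = mean(!diff & termN >= boundary),
           frac_NL = mean(!diff & termN < boundary),
           frac_differentiated = mean(diff),
           n_cells = n_cells, seed = master_seed)
  })
}

#' Write differentiation time-course / outcome CSVs
#'
#' Time course: `(t_min, mean_OS, mean_N, mean_R, sd_N, sd_R,
#' frac_differentiated)`. Outcomes: `(cell_id, t_diff_min, final_basin)`.
#'
#' @param x an `ng_diffrun`.
#' @param path_timecourse,path_outcomes output paths (`NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_diffrun_csv <- function(x, path_timecourse = NULL, path_outcomes = NULL) {
  stopifnot(inherits(x, "ng_diffrun"))
  if (!is.null(path_timecourse))
    readr::write_csv(x$timecourse, path_timecourse)
  if (!is.null(path_outcomes))
    readr::write_csv(x$outcomes, path_outcomes)
  invisible(c(path_timecourse, path_outcomes))
}
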