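# Euler-Maruyama simulation of single cells and vectorised populations,
# wrapping the compiled stepper. Per-step update for X in {OS, N, R}:
#   X <- max(0, X + f_X dt + sigma_X X sqrt(dt) Z),  Z ~ N(0, 1)
# and deterministically for E. Clamping at zero happens after the full
# update; the noise is evaluated at the pre-update concentration.

#' Simulate a single cell
#'
#' Integrates the stochastic system for one cell with the Euler-Maruyama
#' scheme. The trajectory is reproducible: the same `(seed, dt, duration)`
#' always yields bit-identical output, independent of R's global RNG.
#'
#' @param params an [ng_params()] object.
#' @param init initial state `(OS, N, R, E)`; defaults to the Nanog-high
#'   fixed point of `params`.
#' @param duration total simulated time, minutes.
#' @param dt integration step, minutes (default 0.1).
#' @param seed integer seed for this cell's noise stream.
#' @param record_every store every `record_every` minutes (default: every
#'   step).
#' @return An `ng_trajectory` tibble with columns `cell_id`, `t_min`, `OS`,
#'   `N`, `R`, `E` and attributes `params`, `dt`, `seed`.
#' @export
simulate_cell <- function(params, init = NULL, duration, dt = 0.1, seed = 1,
                          record_every = dt) {
  run <- simulate_population(params, n_cells = 1, init = init,
                             duration = duration, dt = dt, master_seed = seed,
                             record_every = record_every)
  traj <- as_tibble(run)
  attr(traj, "params") <- params
  attr(traj, "dt") <- dt
  attr(traj, "seed") <- seed
  class(traj) <- c("ng_trajectory", class(traj))
  traj
}

resolve_init <- function(params, init, n_cells) {
  if (is.matrix(init)) {
    if (ncol(init) != 4 || nrow(init) != n_cells)
      abort("explicit init must be an n_cells x 4 matrix (OS, N, R, E)")
    return(init)
  }
  if (is.numeric(init) && length(init) == 4)
    return(matrix(rep(as.numeric(init), each = n_cells), ncol = 4))
  fp <- find_fixed_points(ng_params(Y = 0, base = params))
  stable <- fp[fp$branch %in% c("NL", "NH") & fp$stability == "stable", ]
  pick <- function(branch) {
    row <- stable[stable$branch == branch, ]
    if (nrow(row) == 0)
      abort(paste0("init policy '", branch, "': no such stable state at these parameters"))
    as.numeric(row[1, c("OS", "N", "R", "E")])
  }
  if (is.null(init) || identical(init, "at_NH"))
    return(matrix(rep(pick("NH"), each = n_cells), ncol = 4))
  if (identical(init, "at_NL"))
    return(matrix(rep(pick("NL"), each = n_cells), ncol = 4))
  if (is.list(init) && identical(init$policy, "mixed")) {
    frac <- init$fraction_NL
    if (!is.numeric(frac) || frac < 0 || frac > 1)
      abort("mixed init policy needs fraction_NL in [0, 1]")
    n_low <- round(frac * n_cells)
    states <- rbind(matrix(rep(pick("NL"), each = n_low), ncol = 4),
                    matrix(rep(pick("NH"), each = n_cells - n_low), ncol = 4))
    return(states)
  }
  abort("init must be NULL, 'at_NH', 'at_NL', list(policy='mixed', fraction_NL=), a length-4 state or an n x 4 matrix")
}

#' Simulate a population of independent cells
#'
#' Runs `n_cells` independent realisations of the stochastic network. Each
#' cell's noise stream is derived deterministically from
#' `(master_seed, cell_id)` by a counter-based hash, so the population is
#' reproducible bit-for-bit and independent of execution order. Snapshots
#' are thinned to every `record_every` minutes for memory control; recording
#' can be restricted to a subset of species for long runs.
#'
#' @param params an [ng_params()] object.
#' @param n_cells number of cells (>= 1).
#' @param init init policy: `NULL` or `"at_NH"` (Nanog-high fixed point),
#'   `"at_NL"`, `list(policy = "mixed", fraction_NL = )`, a single state
#'   vector, or an explicit `n_cells x 4` matrix.
#' @param duration,dt minutes; `dt` defaults to 0.1.
#' @param master_seed integer master seed.
#' @param record_every snapshot spacing in minutes (default: final state
#'   only). Must be a multiple of `dt`.
#' @param species character subset of `c("OS", "N", "R", "E")` to record.
#' @return An `ng_population` object: recorded matrices (time x cell) per
#'   species plus run metadata. Use [as_tibble()] for a long tibble or
#'   [terminal_states()] for the final snapshot.
#' @export
simulate_population <- function(params, n_cells, init = NULL, duration,
                                dt = 0.1, master_seed = 1,
                                record_every = NULL,
                                species = c("OS", "N", "R", "E")) {
  stopifnot(inherits(params, "ng_params"))
  if (n_cells < 1) abort("n_cells must be >= 1")
  if (dt <= 0 || duration < dt) abort("need dt > 0 and duration >= dt")
  species <- match.arg(species, several.ok = TRUE)
  check_dt_stability(params, dt)
  if (is.null(record_every)) record_every <- duration
  if (abs(record_every / dt - round(record_every / dt)) > 1e-8)
    abort("record_every must be a multiple of dt")
  rec_times <- seq(0, duration, by = record_every)
  if (tail(rec_times, 1) < duration) rec_times <- c(rec_times, duration)
  init_m <- resolve_init(params, init, n_cells)
  raw <- sim_population_cpp(par_vector(params), init_m, duration, dt,
                            master_seed, rec_times,
                            c("OS", "N", "R", "E") %in% species,
                            FALSE, numeric(0), 0, 0,
                            seq_len(n_cells))
  structure(list(times = raw$times, OS = raw$OS, N = raw$N, R = raw$R,
                 E = raw$E, n_cells = n_cells, dt = dt,
                 master_seed = master_seed, duration = duration,
                 params = params, species = species),
            class = "ng_population")
}

check_dt_stability <- function(params, dt) {
  # fastest linear relaxation rate, including maximal Y_in enhancement
  dmax <- max(params$d_OS * (1 + params$i_OS * params$Y),
              params$d_N * (1 + params$i_N * params$Y),
              params$d_R * (1 + params$i_R * params$Y),
              params$d_E)
  if (dmax * dt > 0.5)
    warn(paste0("dt = ", dt, " min is large for the fastest degradation rate (",
                signif(dmax, 3), "/min); the explicit scheme may be unstable"))
  invisible(TRUE)
}

#' @export
print.ng_population <- function(x, ...) {
  cat("<ng_population>", x$n_cells, "cells,", x$duration, "min, dt =", x$dt,
      "min, master_seed =", x$master_seed, "\n")
  cat("recorded:", paste(x$species, collapse = ", "), "at",
      length(x$times), "time points\n")
  invisible(x)
}

#' @method as_tibble ng_population
#' @export
as_tibble.ng_population <- function(x, ...) {
  per_species <- purrr::map(
    x$species,
    function(s) {
      m <- x[[s]]
      tibble(cell_id = rep(seq_len(x$n_cells), each = length(x$times)),
             t_min = rep(x$times, x$n_cells),
             value = as.vector(m))
    })
  wide <- per_species[[1]][c("cell_id", "t_min")]
  for (i in seq_along(x$species)) wide[[x$species[i]]] <- per_species[[i]]$value
  wide
}

#' Terminal snapshot of a population run
#'
#' @param run an `ng_population` object.
#' @return A tibble with one row per cell: `cell_id` plus the recorded
#'   species at the final time point.
#' @export
terminal_states <- function(run) {
  stopifnot(inherits(run, "ng_population"))
  out <- tibble(cell_id = seq_len(run$n_cells))
  last <- length(run$times)
  for (s in run$species) out[[s]] <- run[[s]][last, ]
  out
}

#' Extract one species as a time x cell matrix
#' @param run an `ng_population` object.
#' @param species one of `"OS"`, `"N"`, `"R"`, `"E"`.
#' @return Numeric matrix, rows = recorded times (attribute `times`).
#' @export
species_matrix <- function(run, species = "N") {
  stopifnot(inherits(run, "ng_population"))
  m <- run[[species]]
  if (is.null(m)) abort(paste0("species ", species, " was not recorded"))
  attr(m, "times") <- run$times
  m
}

#' Write trajectory / snapshot CSV
#'
#' Long-format CSV `(cell_id, t_min, OS, N, R, E)` with a `#` header comment
#' recording parameters and seeds; re-readable by [read_run_csv()].
#'
#' @param run an `ng_population` object or `ng_trajectory` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_csv <- function(run, path) {
  if (inherits(run, "ng_population")) {
    tb <- as_tibble(run)
    meta <- paste0("# nanogate run: n_cells=", run$n_cells, " dt=", run$dt,
                   " master_seed=", run$master_seed, " params: ",
                   paste(PARAM_KEYS, format_num_v(par_vector(run$params)),
                         sep = "=", collapse = " "))
  } else {
    tb <- run
    pr <- attr(run, "params")
    meta <- paste0("# nanogate trajectory: dt=", attr(run, "dt"),
                   " seed=", attr(run, "seed"), " params: ",
                   paste(PARAM_KEYS, format_num_v(par_vector(pr)),
                         sep = "=", collapse = " "))
  }
  writeLines(meta, path)
  readr::write_csv(tb, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

format_num_v <- function(x) vapply(x, format_num, character(1))

#' @rdname write_run_csv
#' @export
read_run_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' @method autoplot ng_trajectory
#' @export
autoplot.ng_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, cols = dplyr::any_of(c("OS", "N", "R", "E")),
                              names_to = "species", values_to = "conc")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_min / 60, y = .data$conc,
                                     colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "concentration (a.u.)",
                  colour = NULL)
}
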