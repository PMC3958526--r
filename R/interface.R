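# Config-driven entry point: parses a flat key = value run configuration,
# dispatches to the named operation, writes CSV artifacts plus a plain-text
# manifest recording the resolved configuration, seeds and file checksums.

RUN_OPERATIONS <- c("simulate", "bifurcate", "sweep", "transitions",
                    "differentiate", "fraction_vs_y", "synth_flow",
                    "synth_qpcr")

#' Run a configured operation and write its artifacts
#'
#' The configuration is a flat `key = value` text file (or an equivalent
#' named list). Required keys: `operation` (one of `simulate`, `bifurcate`,
#' `sweep`, `transitions`, `differentiate`, `fraction_vs_y`, `synth_flow`,
#' `synth_qpcr`) and `out_dir`. Optional: `params_file` (defaults to the
#' calibrated reference set), `scenario` (`LIF_serum`, `TwoI`), `seed`,
#' `cells`, `days`, `dt`, plus operation-specific keys (`param`, `from`,
#' `to`, `steps` for `bifurcate`; `s4_values`, `sigma_values` for `sweep`;
#' `Y_values` for `fraction_vs_y`). All randomness derives from `seed`.
#' Every run writes `manifest.txt` with the resolved configuration and an
#' md5 checksum per artifact.
#'
#' @param config path to a config file, or a named list.
#' @return Invisibly, a character vector of the written file paths.
#' @export
run_config <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    parse_config_lines(readLines(config))
  } else if (is.list(config)) config
  else abort("config must be a file path or a named list")
  for (key in c("operation", "out_dir")) {
    if (is.null(cfg[[key]]))
      abort(paste0("config is missing required key(s): ", key))
  }
  op <- cfg$operation
  if (!op %in% RUN_OPERATIONS)
    abort(paste0("unknown operation '", op, "'; valid operations: ",
                 paste(RUN_OPERATIONS, collapse = ", ")))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- if (!is.null(cfg$params_file)) read_params_config(cfg$params_file)
            else lif_serum_params()
  if (!is.null(cfg$scenario)) {
    scn <- scenario(cfg$scenario, Y_level = cfg$Y_level %||% 0)
    params <- apply_scenario(params, scn)
  }
  seed <- as.integer(cfg$seed %||% 1)
  cells <- as.integer(cfg$cells %||% 100)
  days <- as.numeric(cfg$days %||% 3)
  dt <- as.numeric(cfg$dt %||% 0.1)
  log_line(cfg, "run", paste0("operation=", op, " seed=", seed))

  files <- character(0)
  out <- function(name) file.path(cfg$out_dir, name)
  if (op == "simulate") {
    run <- simulate_population(params, n_cells = cells, init = "at_NH",
                               duration = days * 1440, dt = dt,
                               master_seed = seed,
                               record_every = as.numeric(cfg$record_every %||% 60))
    files <- c(files, write_run_csv(run, out("snapshots.csv")))
  } else if (op == "bifurcate") {
    grid <- seq(as.numeric(cfg$from %||% 0), as.numeric(cfg$to %||% 40),
                length.out = as.integer(cfg$steps %||% 41))
    dg <- bifurcation_scan(params, cfg$param %||% "p", grid)
    files <- c(files, write_diagram_csv(dg, out("bifurcation.csv")))
  } else if (op == "sweep") {
    sw <- nl_fraction_sweep(params,
                            s4_grid = parse_values(cfg$s4_values %||% "30,40,50"),
                            sigma_grid = parse_values(cfg$sigma_values %||% "0.08,0.12,0.16"),
                            n_cells = cells, duration = days * 1440, dt = dt,
                            master_seed = seed)
    files <- c(files, {readr::write_csv(sw, out("nl_fraction_sweep.csv"));
                       out("nl_fraction_sweep.csv")})
  } else if (op == "transitions") {
    boundary <- basin_boundary(ng_params(Y = 0, base = params))
    run <- simulate_population(params, n_cells = cells, init = "at_NH",
                               duration = days * 1440, dt = dt,
                               master_seed = seed, record_every = 1,
                               species = "N")
    ev <- population_transitions(run, boundary)
    files <- c(files, write_events_csv(ev, out("transition_events.csv")))
    rate <- transition_rate(ev, cells, days * 1440)
    readr::write_csv(rate, out("transition_rate.csv"))
    files <- c(files, out("transition_rate.csv"))
  } else if (op == "differentiate") {
    dr <- simulate_differentiation(ng_params(p = 0, base = params),
                                   Y_level = as.numeric(cfg$Y_level %||% 5),
                                   rex1_turnover_scale =
                                     as.numeric(cfg$rex1_turnover_scale %||% 0.1),
                                   n_cells = cells,
                                   duration = days * 1440, dt = dt,
                                   master_seed = seed)
    write_diffrun_csv(dr, out("timecourse.csv"), out("outcomes.csv"))
    files <- c(files, out("timecourse.csv"), out("outcomes.csv"))
  } else if (op == "fraction_vs_y") {
    fr <- differentiated_fraction_vs_Y(params,
                                       Y_grid = parse_values(cfg$Y_values %||% "0,0.5,1,2,5"),
                                       n_cells = cells, duration = days * 1440,
                                       dt = dt, master_seed = seed)
    readr::write_csv(fr, out("fraction_vs_y.csv"))
    files <- c(files, out("fraction_vs_y.csv"))
  } else if (op == "synth_flow") {
    spec <- mixture_spec(n_cells = cells, seed = seed)
    files <- c(files, write_synthetic_csv(gen_flow_sample(spec),
                                          out("flow_sample.csv")))
  } else if (op == "synth_qpcr") {
    files <- c(files, write_synthetic_csv(gen_qpcr_timecourse(
      timecourse_spec(seed = seed)), out("qpcr_timecourse.csv")))
  }
  manifest <- out("manifest.txt")
  write_manifest(cfg, params, seed, files, manifest)
  log_line(cfg, "run", paste0("wrote ", length(files), " artifact(s)"))
  invisible(c(files, manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_values <- function(x) {
  if (is.numeric(x)) return(x)
  as.numeric(strsplit(as.character(x), ",")[[1]])
}

log_line <- function(cfg, module, msg) {
  line <- sprintf("%s [INFO] %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), module, msg)
  message(line)
  if (!is.null(cfg$out_dir) && dir.exists(cfg$out_dir))
    cat(line, "\n", file = file.path(cfg$out_dir, "run.log"), append = TRUE)
  invisible(line)
}

write_manifest <- function(cfg, params, seed, files, path) {
  lines <- c("# nanogate run manifest",
             paste0("timestamp = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             paste0("seed = ", seed),
             paste0("config.", names(cfg), " = ",
                    vapply(cfg, as.character, character(1))),
             paste0("params.", PARAM_KEYS, " = ",
                    format_num_v(par_vector(params))),
             vapply(files, function(f) {
               paste0("artifact ", basename(f), " md5=",
                      unname(tools::md5sum(f)))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Export a bifurcation diagram as CSV
#'
#' Columns `(parameter, value, branch, stability, OS, N, R, E)`.
#'
#' @param diagram an `ng_bifurcation` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagram_csv <- function(diagram, path) {
  readr::write_csv(select(as_tibble(diagram), "parameter", "value", "branch",
                          "stability", "OS", "N", "R", "E"), path)
  invisible(path)
}

#' @method autoplot ng_bifurcation
#' @export
autoplot.ng_bifurcation <- function(object, ...) {
  bi <- attr(object, "bistable_interval")
  pl <- ggplot2::ggplot(
    filter(as_tibble(object), .data$branch != "origin"),
    ggplot2::aes(x = .data$value, y = .data$N,
                 group = interaction(.data$branch, .data$stability),
                 linetype = .data$stability == "stable")) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = object$parameter[1], y = "Nanog (a.u.)")
  if (!is.null(bi))
    pl <- pl + ggplot2::annotate("rect", xmin = bi[1], xmax = bi[2],
                                 ymin = -Inf, ymax = Inf, alpha = 0.1)
  pl
}
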