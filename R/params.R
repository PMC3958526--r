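# Parameter sets, scenarios and their flat-text serialisation.

PARAM_KEYS <- c("s12", "s3", "s4", "s5", "s6", "s7", "k", "n", "p",
                "d_OS", "d_N", "d_R", "d_E", "i_OS", "i_N", "i_R",
                "sigma_OS", "sigma_N", "sigma_R", "Y", "k_Y", "h")

#' Construct a model parameter set
#'
#' Bundles every rate constant of the pluripotency network: transcription
#' rates `s12` (combined Oct4-Sox2 autoactivation), `s3` (Oct4-Sox2 to Nanog),
#' `s4` (Nanog autoregulation), `s5`/`s6` (Oct4-Sox2/Nanog to Rex1), `s7`
#' (Oct4-Sox2 to Erk via FGF4); the shared Hill half-saturation constant `k`
#' and coefficient `n` (fixed to 2, reflecting Nanog homodimer binding);
#' the Erk-to-Nanog repression strength `p`; first-order degradation rates
#' `d_OS`, `d_N`, `d_R`, `d_E`; inhibition factors `i_OS`, `i_N`, `i_R`
#' scaling the degradation enhancement by the intracellular differentiation
#' activity `Y_in`; multiplicative noise amplitudes `sigma_OS`, `sigma_N`,
#' `sigma_R`; the extrinsic differentiation-signal level `Y`; and the
#' half-saturation `k_Y` and coefficient `h` of the Nanog gate on `Y`.
#'
#' Time is measured in minutes and concentrations in arbitrary units (a.u.);
#' degradation rates are 1/min and noise amplitudes 1/sqrt(min). Erk carries
#' neither noise nor `Y_in`-enhanced degradation (the signalling pathway is
#' treated as fluctuation-free).
#'
#' @param ... named parameter values overriding the defaults of `base`.
#' @param base a parameter set (named list) supplying unspecified values;
#'   defaults to the calibrated LIF/serum reference set.
#' @return An object of class `ng_params`: a named list with the 22 fields
#'   above, validated (finite, non-negative, `k > 0`, `k_Y > 0`, `h >= 1`).
#' @examples
#' p <- ng_params(p = 0) # 2i: Erk repression removed
#' p$s4
#' @export
ng_params <- function(..., base = lif_serum_params()) {
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == "")))
    abort("all parameter overrides must be named")
  unknown <- setdiff(names(over), PARAM_KEYS)
  if (length(unknown) > 0)
    abort(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  pars <- modifyList(unclass(base), over)
  validate_params(pars)
}

validate_params <- function(pars) {
  missing <- setdiff(PARAM_KEYS, names(pars))
  if (length(missing) > 0)
    abort(paste0("missing parameter(s): ", paste(missing, collapse = ", ")))
  pars <- pars[PARAM_KEYS]
  vals <- unlist(pars)
  if (!all(is.finite(vals)))
    abort("all parameters must be finite numbers")
  if (any(vals < 0))
    abort(paste0("negative parameter(s): ",
                 paste(PARAM_KEYS[vals < 0], collapse = ", ")))
  if (pars$k <= 0) abort("k must be > 0")
  if (pars$k_Y <= 0) abort("k_Y must be > 0")
  if (pars$h < 1) abort("h must be >= 1")
  structure(pars, class = "ng_params")
}

#' @export
print.ng_params <- function(x, ...) {
  cat("<ng_params> pluripotency-network parameter set (min, a.u.)\n")
  v <- unlist(x)
  cat(paste0(format(names(v), width = 9), " = ", format(v, digits = 6),
             collapse = "\n"), "\n")
  invisible(x)
}

# flatten to the positional vector the compiled stepper expects
par_vector <- function(params) {
  unlist(params[PARAM_KEYS], use.names = FALSE)
}

#' Calibrated reference parameter sets
#'
#' `lif_serum_params()` loads the calibrated LIF/serum reference parameter
#' set shipped with the package (produced by [calibrate()] against the
#' phenotype constraints: ~20% Nanog-low cells after 3 days, ~2 log10 units
#' of NH/NL separation, rare valid state transitions, bistability at the
#' scenario repression rate and monostability at `p = 0`).
#' `two_i_params()` is the same set with the Erk repression removed
#' (`p = 0`), which is the whole of the 2i condition in this model.
#'
#' @return An [ng_params()] object.
#' @export
lif_serum_params <- function() {
  path <- system.file("extdata", "params_lif_serum.cfg", package = "nanogate")
  if (path == "") abort("reference parameter file not found")
  read_params_config(path)
}

#' @rdname lif_serum_params
#' @export
two_i_params <- function() {
  ng_params(p = 0, base = lif_serum_params())
}

#' Define a culture-condition scenario
#'
#' A scenario maps a culture condition onto parameter overrides: `LIF_serum`
#' keeps the Erk repression active (`p > 0`); `TwoI` forces `p = 0` (the two
#' inhibitors block Mek/Erk, removing the negative feedback); and
#' `N2B27_withdrawal` replaces the constant `p` by a per-cell stochastic ramp
#' ([ramp_spec()]) and may reduce the Rex1 turnover (scaling `s5`, `s6`,
#' `d_R` jointly so the Rex1 steady level is preserved while its kinetics
#' slow down).
#'
#' @param label one of `"LIF_serum"`, `"TwoI"`, `"N2B27_withdrawal"`.
#' @param p_override repression strength replacing the parameter set's `p`
#'   (a number), or a [ramp_spec()] for the withdrawal scenario; `NULL`
#'   keeps the parameter set's value.
#' @param Y_level extrinsic differentiation-signal strength.
#' @param rex1_turnover_scale multiplicative factor in (0, 1] applied to
#'   `s5`, `s6` and `d_R`; must be 1 except under `N2B27_withdrawal`.
#' @return An object of class `ng_scenario`.
#' @export
scenario <- function(label = c("LIF_serum", "TwoI", "N2B27_withdrawal"),
                     p_override = NULL, Y_level = 0,
                     rex1_turnover_scale = 1) {
  label <- match.arg(label)
  if (label == "TwoI") {
    if (!is.null(p_override) && !identical(p_override, 0))
      abort("a TwoI scenario forces p_override = 0")
    p_override <- 0
  }
  if (rex1_turnover_scale <= 0 || rex1_turnover_scale > 1)
    abort("rex1_turnover_scale must be in (0, 1]")
  if (label != "N2B27_withdrawal" && rex1_turnover_scale != 1)
    abort("rex1_turnover_scale must be 1 outside the N2B27_withdrawal scenario")
  if (!is.numeric(Y_level) || length(Y_level) != 1 || Y_level < 0)
    abort("Y_level must be a single non-negative number")
  structure(list(label = label, p_override = p_override, Y_level = Y_level,
                 rex1_turnover_scale = rex1_turnover_scale),
            class = "ng_scenario")
}

#' Apply a scenario to a parameter set
#'
#' Returns the parameter set with the scenario's overrides applied. A ramp
#' `p_override` is not resolvable to a constant and is left to
#' [simulate_differentiation()]; here it leaves `p` untouched.
#'
#' @param params an [ng_params()] object.
#' @param scn an [ng_scenario()] object.
#' @return An [ng_params()] object.
#' @export
apply_scenario <- function(params, scn) {
  stopifnot(inherits(scn, "ng_scenario"))
  over <- list(Y = scn$Y_level)
  if (!is.null(scn$p_override) && is.numeric(scn$p_override))
    over$p <- scn$p_override
  if (scn$rex1_turnover_scale != 1) {
    over$s5 <- params$s5 * scn$rex1_turnover_scale
    over$s6 <- params$s6 * scn$rex1_turnover_scale
    over$d_R <- params$d_R * scn$rex1_turnover_scale
    # slower turnover time-averages transcriptional noise; scaling the
    # amplitude by sqrt(scale) keeps the stationary spread invariant
    over$sigma_R <- params$sigma_R * sqrt(scn$rex1_turnover_scale)
  }
  do.call(ng_params, c(over, list(base = params)))
}

#' Read and write parameter configuration files
#'
#' The on-disk format is flat structured text, one `key = value` pair per
#' line, keys spelled exactly as in [ng_params()]. Lines starting with `#`
#' are comments. Unknown keys raise a warning and are ignored; missing keys
#' are an error listing them. `write_params_config()` formats numbers with
#' full precision so that write -> read -> write round-trips byte-identically.
#'
#' @param path file path.
#' @param params an [ng_params()] object.
#' @return `read_params_config()` returns an [ng_params()] object;
#'   `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  kv <- parse_config_lines(readLines(path))
  unknown <- setdiff(names(kv), PARAM_KEYS)
  if (length(unknown) > 0) {
    warn(paste0("ignoring unknown config key(s): ",
                paste(unknown, collapse = ", ")))
    kv <- kv[setdiff(names(kv), unknown)]
  }
  missing <- setdiff(PARAM_KEYS, names(kv))
  if (length(missing) > 0)
    abort(paste0("config is missing required key(s): ",
                 paste(missing, collapse = ", ")))
  validate_params(as.list(kv))
}

parse_config_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad))
    abort(paste0("malformed config line(s): ",
                 paste(lines[bad], collapse = "; ")))
  keys <- trimws(sub("=.*$", "", lines))
  raw <- trimws(sub("^[^=]*=", "", lines))
  vals <- suppressWarnings(as.numeric(raw))
  non_num <- is.na(vals)
  out <- as.list(vals)
  out[non_num] <- raw[non_num]
  names(out) <- keys
  if (anyDuplicated(keys))
    abort(paste0("duplicated config key(s): ",
                 paste(unique(keys[duplicated(keys)]), collapse = ", ")))
  out
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "ng_params"))
  lines <- vapply(PARAM_KEYS, function(k) {
    paste0(k, " = ", format_num(params[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

format_num <- function(x) {
  # shortest representation that survives a parse round-trip
  for (d in 1:17) {
    s <- trimws(formatC(x, digits = d, format = "g"))
    if (as.numeric(s) == x) return(s)
  }
  trimws(formatC(x, digits = 17, format = "g"))
}
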