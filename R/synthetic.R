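# Surrogate observed data. No flow-cytometry or qRT-PCR measurements are
# shipped with the package; these generators emulate the *statistical
# shape* of such data -- log-normal mixture fluorescence samples (a
# destabilised-GFP Rex1 reporter read out by flow cytometry) and
# population-mean mRNA time courses normalised to 1 at t = 0. They are
# synthetic stand-ins, not measured values.

#' Specify a log-normal mixture of fluorescence intensities
#'
#' Log-normal mixtures are the natural emulation here: on the logarithmic
#' fluorescence scale the observed high- and low-expressing subpopulations
#' appear about equally wide, which is the signature of multiplicative
#' noise. The default LIF/serum-like spec has a low mode holding 20% of
#' cells two decades below the high mode; the 2i-like spec is a single high
#' component.
#'
#' @param medians component medians, a.u. (positive).
#' @param log10_sds per-component standard deviations on the log10 scale.
#' @param weights mixture weights summing to 1.
#' @param n_cells sample size.
#' @param seed integer seed.
#' @return An object of class `ng_mixture_spec`.
#' @export
mixture_spec <- function(medians = c(4, 400), log10_sds = c(0.25, 0.25),
                         weights = c(0.2, 0.8), n_cells = 10000, seed = 1) {
  if (length(medians) != length(weights) || length(log10_sds) != length(weights))
    abort("medians, log10_sds and weights must have equal lengths")
  if (any(medians <= 0)) abort("component medians must be positive")
  if (any(log10_sds < 0)) abort("log10_sds must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  structure(list(medians = medians, log10_sds = log10_sds, weights = weights,
                 n_cells = n_cells, seed = seed), class = "ng_mixture_spec")
}

#' @rdname mixture_spec
#' @export
mixture_spec_2i <- function(n_cells = 10000, seed = 1) {
  mixture_spec(medians = 400, log10_sds = 0.2, weights = 1,
               n_cells = n_cells, seed = seed)
}

#' Generate a flow-cytometry-like intensity sample
#'
#' Draws one positive intensity per cell from the log-normal mixture.
#' Deterministic given the spec's seed.
#'
#' @param spec a [mixture_spec()].
#' @return A tibble `(cell_id, intensity)`.
#' @export
gen_flow_sample <- function(spec) {
  stopifnot(inherits(spec, "ng_mixture_spec"))
  withr::with_seed(spec$seed, {
    comp <- sample.int(length(spec$weights), spec$n_cells, replace = TRUE,
                       prob = spec$weights)
    lg <- rnorm(spec$n_cells, mean = log10(spec$medians[comp]),
                sd = spec$log10_sds[comp])
    tibble(cell_id = seq_len(spec$n_cells), intensity = 10^lg)
  })
}

#' Specify a qRT-PCR-like population time course
#'
#' Each species decays as `exp(-rate * max(0, t - delay))` times
#' multiplicative log-normal noise, renormalised to exactly 1 at `t = 0`.
#' Samples are taken every 3 h by default (the cadence at which cultures
#' are typically harvested after a media change). The default delays put
#' the Nanog decline before the Rex1 decline, the hallmark of the
#' withdrawal kinetics.
#'
#' @param species species labels.
#' @param delays_h onset delays, hours (same order as `species`).
#' @param rates_h decay rates, 1/h (positive).
#' @param t_max_h last time point, hours.
#' @param by_h sampling interval, hours.
#' @param noise_sd log-normal noise sd (natural log scale).
#' @param seed integer seed.
#' @return An object of class `ng_timecourse_spec`.
#' @export
timecourse_spec <- function(species = c("nanog", "rex1"),
                            delays_h = c(0, 12), rates_h = c(0.18, 0.15),
                            t_max_h = 48, by_h = 3, noise_sd = 0.05,
                            seed = 1) {
  if (length(delays_h) != length(species) || length(rates_h) != length(species))
    abort("delays_h and rates_h must match species")
  if (any(rates_h < 0)) abort("decay rates must be >= 0")
  if (any(delays_h < 0)) abort("delays must be >= 0")
  structure(list(species = species, delays_h = delays_h, rates_h = rates_h,
                 t_max_h = t_max_h, by_h = by_h, noise_sd = noise_sd,
                 seed = seed), class = "ng_timecourse_spec")
}

#' Generate a qRT-PCR-like time course
#'
#' @param spec a [timecourse_spec()].
#' @return A tibble with column `t_h` and one relative-expression column per
#'   species (`<species>_rel`), each exactly 1 at `t = 0`.
#' @export
gen_qpcr_timecourse <- function(spec) {
  stopifnot(inherits(spec, "ng_timecourse_spec"))
  t_h <- seq(0, spec$t_max_h, by = spec$by_h)
  out <- tibble(t_h = t_h)
  withr::with_seed(spec$seed, {
    for (i in seq_along(spec$species)) {
      v <- exp(-spec$rates_h[i] * pmax(0, t_h - spec$delays_h[i]))
      if (spec$noise_sd > 0)
        v <- v * exp(rnorm(length(t_h), 0, spec$noise_sd))
      v <- v / v[1]
      out[[paste0(spec$species[i], "_rel")]] <- v
    }
  })
  out
}

#' Distance between two positive samples
#'
#' Two-sample empirical-CDF maximum distance (the Kolmogorov-Smirnov
#' statistic) computed on log10-transformed values; 0 for identical
#' samples, 1 for samples with disjoint support.
#'
#' @param sample_a,sample_b positive numeric vectors (or tibbles with an
#'   `intensity` column).
#' @return A scalar in `[0, 1]`.
#' @export
distribution_distance <- function(sample_a, sample_b) {
  a <- extract_intensity(sample_a)
  b <- extract_intensity(sample_b)
  if (length(a) == 0 || length(b) == 0) abort("samples must be nonempty")
  if (any(a <= 0) || any(b <= 0))
    abort("samples must be positive (log10 scale is used)")
  la <- log10(a); lb <- log10(b)
  grid <- sort(c(la, lb))
  Fa <- ecdf(la)(grid)
  Fb <- ecdf(lb)(grid)
  max(abs(Fa - Fb))
}

extract_intensity <- function(x) {
  if (is.data.frame(x)) {
    if (!"intensity" %in% names(x)) abort("data frame needs an 'intensity' column")
    x <- x$intensity
  }
  as.numeric(x)
}

#' Write flow-like / time-course CSVs
#'
#' Flow samples: `(cell_id, intensity)`. Time courses: `(t_h, <species>_rel
#' ...)`. CSV is the supported interchange format; binary cytometry formats
#' are out of scope.
#'
#' @param x tibble from [gen_flow_sample()] or [gen_qpcr_timecourse()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}
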