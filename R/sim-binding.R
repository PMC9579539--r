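#' SPR sensorgram generator configuration
#'
#' 1:1 Langmuir binding world: association
#' \eqn{R(t) = R_{eq}(1 - e^{-(k_a C + k_d) t})} with
#' \eqn{R_{eq} = R_{max} k_a C / (k_a C + k_d)}, dissociation
#' \eqn{R(t) = R_0 e^{-k_d (t - t_{assoc})}}.  Defaults follow the
#' emulated instrument protocol: six insulin concentrations (100 uM, 20
#' uM, 4 uM, 800 nM, 160 nM, 32 nM), 1 minute association, 15 minutes
#' dissociation, plus a baseline segment, Gaussian read noise, a constant
#' baseline offset, and short fluidics spikes at the phase boundaries.
#'
#' @param ka association rate constant, 1/(M*s).
#' @param kd dissociation rate constant, 1/s.
#' @param rmax saturating response, RU.
#' @param concentrations analyte concentration series, M (positive,
#'   distinct).
#' @param t_assoc,t_dissoc association / dissociation durations, s.
#' @param dt sampling interval, s.
#' @param noise_sd Gaussian noise SD, RU.
#' @param baseline_ru constant instrument offset, RU.
#' @param baseline_duration pre-injection baseline length, s.
#' @param spike_amplitude,spike_width fluidics spike height (RU) and
#'   duration (s) at the two phase boundaries.
#' @return an `spr_config` object.
#' @export
spr_config <- function(ka = 1e5, kd = 1e-3, rmax = 100,
                       concentrations = c(100e-6, 20e-6, 4e-6, 800e-9,
                                          160e-9, 32e-9),
                       t_assoc = 60, t_dissoc = 900, dt = 1,
                       noise_sd = 1, baseline_ru = 20,
                       baseline_duration = 10,
                       spike_amplitude = 15, spike_width = 1) {
  if (ka <= 0 || kd <= 0 || rmax <= 0)
    stop_ibcrep("ka, kd and rmax must be positive", "ibcrep_config_error")
  if (any(concentrations <= 0))
    stop_ibcrep("concentrations must be strictly positive",
                "ibcrep_config_error")
  if (anyDuplicated(concentrations))
    stop_ibcrep("concentrations must be distinct", "ibcrep_config_error")
  stopifnot(t_assoc > 0, t_dissoc > 0, dt > 0, noise_sd >= 0,
            baseline_duration >= 0, spike_width >= 0)
  structure(as.list(environment()), class = "spr_config")
}

#' Simulate a raw sensorgram set
#'
#' Times are absolute within a trace (baseline starts at 0, injection at
#' `baseline_duration`); [preprocess_sensorgram()] re-zeroes them at the
#' injection.  Fluidics spikes are added in the first `spike_width`
#' seconds after each phase boundary.
#'
#' @param config an [spr_config()].
#' @param seed integer seed.
#' @return data.frame of class `sensorgram_set` with columns `time_s`,
#'   `ru`, `conc_M`, `phase` (`baseline` / `assoc` / `dissoc`), and
#'   attributes `t_assoc`, `t_dissoc`, `injection_time`.
#' @export
simulate_sensorgram <- function(config, seed) {
  stopifnot(inherits(config, "spr_config"))
  set.seed(seed)
  t0 <- config$baseline_duration
  traces <- lapply(config$concentrations, function(C) {
    tb <- if (t0 > 0) seq(0, t0 - config$dt, by = config$dt) else numeric(0)
    ta <- seq(0, config$t_assoc, by = config$dt)
    td <- seq(config$dt, config$t_dissoc, by = config$dt) + config$t_assoc
    r_assoc <- langmuir_predict(config$ka, config$kd, config$rmax, C,
                                ta, phase = "assoc",
                                t_assoc = config$t_assoc)
    r_dissoc <- langmuir_predict(config$ka, config$kd, config$rmax, C,
                                 td, phase = "dissoc",
                                 t_assoc = config$t_assoc)
    time_s <- c(tb, ta + t0, td + t0)
    ru <- c(rep(0, length(tb)), r_assoc, r_dissoc) + config$baseline_ru
    rel <- time_s - t0
    spike <- (rel >= 0 & rel < config$spike_width) |
      (rel >= config$t_assoc & rel < config$t_assoc + config$spike_width)
    ru <- ru + spike * config$spike_amplitude
    if (config$noise_sd > 0) ru <- ru + rnorm(length(ru), 0, config$noise_sd)
    data.frame(time_s = time_s, ru = ru, conc_M = C,
               phase = c(rep("baseline", length(tb)),
                         rep("assoc", length(ta)),
                         rep("dissoc", length(td))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, traces)
  attr(out, "t_assoc") <- config$t_assoc
  attr(out, "t_dissoc") <- config$t_dissoc
  attr(out, "injection_time") <- t0
  class(out) <- c("sensorgram_set", "data.frame")
  out
}

#' Simulate an ELISA titration table
#'
#' OD values follow a saturating one-site binding curve of the analyte
#' concentration, sampled over a serial dilution series (default: a load
#' plus 7 doublings, i.e. 8 points spanning a 2^7 range).
#'
#' @param top_concentration concentration of the undiluted load
#'   (arbitrary units).
#' @param dilution_factor fold dilution per step, must be > 1.
#' @param points number of points (>= 2), default 8.
#' @param od_max,ec50,od_background binding-curve parameters: saturating
#'   OD, concentration of half-maximal OD, and background OD.
#' @param noise_sd Gaussian OD noise.
#' @param seed integer seed.
#' @param group group label (e.g. the V-kappa family of the antibody).
#' @return data.frame with columns `dilution` (fold, increasing),
#'   `od450`, `group`.
#' @export
simulate_elisa <- function(top_concentration = 10, dilution_factor = 2,
                           points = 8L, od_max = 2.5, ec50 = 0.5,
                           od_background = 0.05, noise_sd = 0.02,
                           seed = 1L, group = "Vk4-74") {
  if (dilution_factor <= 1)
    stop_ibcrep("dilution_factor must be > 1", "ibcrep_config_error")
  if (points < 2)
    stop_ibcrep("at least 2 titration points are required",
                "ibcrep_config_error")
  set.seed(seed)
  dilution <- dilution_factor^(seq_len(points) - 1)
  conc <- top_concentration / dilution
  od <- od_background + (od_max - od_background) * conc / (conc + ec50)
  if (noise_sd > 0) od <- od + rnorm(points, 0, noise_sd)
  data.frame(dilution = dilution, od450 = od, group = group,
             stringsAsFactors = FALSE)
}
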