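#' Specify a ratiometric trace simulation
#'
#' Emulates dual-excitation PercevalHR recordings with a pHrodo pH proxy:
#' a premix baseline, a treatment window, washout, and a terminal NH4Cl
#' pulse used for empirical pH calibration. The true (corrected-scale)
#' ratio is 1 during baseline; the raw ratio is
#' `(1 + treatment deflection + ph_coupling * pHrodo deviation + noise) *
#' exp(-bleach_rate * t)`. The pHrodo channel idles at 1 AU and rises by a
#' smooth rise-and-decay pulse during the NH4Cl window, so its deviation
#' varies within the window.
#'
#' @param n_rois number of neuronal ROIs (a shared background ROI is added).
#' @param dt sampling interval, seconds.
#' @param baseline_duration seconds of premix baseline (treatment starts
#'   at this time).
#' @param treatment_time,washout_time,nh4cl_window event times in seconds;
#'   `nh4cl_window` is `c(start, end)`. Must be strictly ordered
#'   baseline < treatment <= washout < NH4Cl start < end.
#' @param bleach_rate photobleach decay rate per second (>= 0).
#' @param treatment_effect additive deflection of the true ratio during
#'   the treatment window (e.g. -0.2).
#' @param ph_coupling slope linking pHrodo deviation (AU) to ratio
#'   deviation during the NH4Cl pulse (dimensionless).
#' @param phrodo_pulse peak amplitude of the NH4Cl pHrodo pulse, AU.
#' @param noise_sd Gaussian noise SD on the corrected-scale ratio.
#' @param total_duration total recording length, seconds.
#' @param seed integer RNG seed.
#' @return object of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(n_rois = 15,
                           dt = 2,
                           baseline_duration = 120,
                           treatment_time = 120,
                           washout_time = 480,
                           nh4cl_window = c(600, 720),
                           bleach_rate = 5e-4,
                           treatment_effect = -0.2,
                           ph_coupling = 0.5,
                           phrodo_pulse = 0.4,
                           noise_sd = 0.01,
                           total_duration = 780,
                           seed = 1L) {
  check_count(n_rois, "n_rois", min = 1L)
  check_number(dt, "dt", lower = 0)
  check_number(bleach_rate, "bleach_rate", lower = 0, allow_equal_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0, allow_equal_lower = TRUE)
  stop_if(length(nh4cl_window) != 2L, "'nh4cl_window' must be c(start, end)")
  ok <- baseline_duration <= treatment_time &&
    treatment_time < washout_time &&
    washout_time < nh4cl_window[1] && nh4cl_window[1] < nh4cl_window[2] &&
    nh4cl_window[2] <= total_duration
  stop_if(!ok, "event times must be ordered baseline <= treatment < washout < NH4Cl start < NH4Cl end <= total")
  structure(list(n_rois = as.integer(n_rois), dt = dt,
                 baseline_duration = baseline_duration,
                 treatment_time = treatment_time,
                 washout_time = washout_time,
                 nh4cl_window = nh4cl_window,
                 bleach_rate = bleach_rate,
                 treatment_effect = treatment_effect,
                 ph_coupling = ph_coupling,
                 phrodo_pulse = phrodo_pulse,
                 noise_sd = noise_sd,
                 total_duration = total_duration,
                 seed = as.integer(seed)),
            class = "trace_sim_spec")
}

# smooth NH4Cl pulse shape on [0, 1] time fraction: rises with tau ~ 15 s,
# decays with tau ~ 90 s; nonconstant inside the window by construction
nh4cl_pulse_shape <- function(t, start, end) {
  s <- numeric(length(t))
  inside <- t >= start & t <= end
  u <- t[inside] - start
  s[inside] <- (1 - exp(-u / 15)) * exp(-u / 90)
  s
}

#' Simulate a dual-channel ROI trace set
#'
#' @param spec a [trace_sim_spec()].
#' @return a `ratio_trace_set`: list with `data` (data.frame roi, time_s,
#'   f405, f488, phrodo, is_background) and `events` (treatment, washout,
#'   nh4cl_start, nh4cl_end). True generator quantities are attached as
#'   attribute `truth` for round-trip tests.
#' @export
simulate_traces <- function(spec) {
  stop_if(!inherits(spec, "trace_sim_spec"), "need a trace_sim_spec")
  with_seed(spec$seed, {
    tgrid <- seq(0, spec$total_duration, by = spec$dt)
    bg405 <- 50; bg488 <- 60; f405_amp <- 500
    pulse <- spec$phrodo_pulse *
      nh4cl_pulse_shape(tgrid, spec$nh4cl_window[1], spec$nh4cl_window[2])
    deflect <- ifelse(tgrid >= spec$treatment_time &
                        tgrid < spec$washout_time,
                      spec$treatment_effect, 0)
    env <- exp(-spec$bleach_rate * tgrid)
    rois <- vector("list", spec$n_rois + 1L)
    for (r in seq_len(spec$n_rois)) {
      noise <- rnorm(length(tgrid), 0, spec$noise_sd)
      true_corrected <- 1 + deflect
      raw_ratio <- (true_corrected + spec$ph_coupling * pulse + noise) * env
      f405 <- rep(f405_amp, length(tgrid)) + bg405
      f488 <- raw_ratio * f405_amp + bg488
      phrodo <- 1 + pulse +
        rnorm(length(tgrid), 0, spec$noise_sd / 4)
      rois[[r]] <- data.frame(roi = sprintf("roi%02d", r), time_s = tgrid,
                              f405 = f405, f488 = f488, phrodo = phrodo,
                              is_background = FALSE)
    }
    rois[[spec$n_rois + 1L]] <- data.frame(
      roi = "background", time_s = tgrid,
      f405 = bg405, f488 = bg488, phrodo = 1, is_background = TRUE)
    res <- list(data = do.call(rbind, rois),
                events = list(treatment = spec$treatment_time,
                              washout = spec$washout_time,
                              nh4cl_start = spec$nh4cl_window[1],
                              nh4cl_end = spec$nh4cl_window[2]))
    attr(res, "truth") <- list(envelope = env, pulse = pulse,
                               deflect = deflect, time = tgrid)
    class(res) <- "ratio_trace_set"
    res
  })
}

#' Construct a trace set from a long data.frame
#'
#' @param data data.frame with columns roi, time_s, f405, f488, phrodo,
#'   is_background (one ROI flagged as background).
#' @param events named list/vector with treatment, washout, nh4cl_start,
#'   nh4cl_end (seconds).
#' @return a `ratio_trace_set`.
#' @export
as_ratio_trace_set <- function(data, events) {
  need <- c("roi", "time_s", "f405", "f488", "phrodo", "is_background")
  stop_if(!all(need %in% names(data)), "trace data missing required columns")
  stop_if(!any(data$is_background), "a background ROI is required")
  ev <- as.list(events)
  stop_if(!all(c("treatment", "washout", "nh4cl_start", "nh4cl_end") %in%
                 names(ev)), "events need treatment, washout, nh4cl_start, nh4cl_end")
  stop_if(!(ev$treatment < ev$washout && ev$washout < ev$nh4cl_start &&
              ev$nh4cl_start < ev$nh4cl_end),
          "events must be ordered treatment < washout < NH4Cl start < NH4Cl end")
  structure(list(data = data, events = ev), class = "ratio_trace_set")
}

#' @export
print.ratio_trace_set <- function(x, ...) {
  n_roi <- length(unique(x$data$roi[!x$data$is_background]))
  cat(sprintf("Ratio trace set: %d ROIs, %d timepoints, treatment at %gs, washout %gs, NH4Cl [%g, %g]s\n",
              n_roi, length(unique(x$data$time_s)), x$events$treatment,
              x$events$washout, x$events$nh4cl_start, x$events$nh4cl_end))
  invisible(x)
}

#' Write / read a trace CSV
#'
#' @param x a `ratio_trace_set`.
#' @param path output CSV path. Events are not stored in the CSV; supply
#'   them to the reader.
#' @param events event list for the reader (see [as_ratio_trace_set()]).
#' @return `path` invisibly (writer); a `ratio_trace_set` (reader).
#' @export
write_trace_csv <- function(x, path) {
  write.csv(x$data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path, events) {
  as_ratio_trace_set(read.csv(path), events)
}
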