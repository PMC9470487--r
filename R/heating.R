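#' Construct a thermocouple trace
#'
#' A time-stamped temperature series from one logger channel, nominally
#' sampled every 20 s.
#'
#' @param time_s strictly increasing timestamps in seconds.
#' @param temp_C temperatures in degrees Celsius, same length, finite.
#' @param channel channel label (e.g. `"T1"`, `"T2"`, `"chamber"`,
#'   `"water"`).
#' @return An object of class `elytherm_trace`.
#' @export
thermal_trace <- function(time_s, temp_C, channel = "T1") {
  time_s <- as.numeric(time_s); temp_C <- as.numeric(temp_C)
  if (length(time_s) != length(temp_C)) {
    stop("time_s and temp_C must have the same length", call. = FALSE)
  }
  if (length(time_s) < 1L) stop("empty trace", call. = FALSE)
  if (any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(temp_C)) || any(!is.finite(time_s))) {
    stop("non-finite values in trace", call. = FALSE)
  }
  structure(list(time_s = time_s, temp_C = temp_C, channel = channel),
            class = "elytherm_trace")
}

#' @export
print.elytherm_trace <- function(x, ...) {
  cat(sprintf("<trace %s> %d samples, %g-%g s, %.2f-%.2f degC\n",
              x$channel, length(x$time_s), min(x$time_s), max(x$time_s),
              min(x$temp_C), max(x$temp_C)))
  invisible(x)
}

#' Read thermocouple traces from CSV
#'
#' Expects columns `time_s`, `temp_C` and optionally `channel`; returns one
#' `elytherm_trace` per channel.
#'
#' @param path CSV file path.
#' @return A named list of `elytherm_trace` objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "temp_C")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns time_s, temp_C: ", path, call. = FALSE)
  }
  if (is.null(df$channel)) df$channel <- "T1"
  out <- lapply(split(df, df$channel), function(d) {
    d <- d[order(d$time_s), ]
    thermal_trace(d$time_s, d$temp_C, channel = d$channel[[1]])
  })
  out
}

#' Trial plan of illumination and cooling phases
#'
#' A trial alternates 5-min illumination and cooling periods. The canonical
#' cycle is: initial cooling, TOTAL, cooling, NIR, cooling, VIS, cooling.
#'
#' @param labels character vector of phase labels drawn from
#'   `COOL`, `TOTAL`, `NIR`, `VIS`.
#' @param start_s,end_s phase boundaries in seconds; phases must be
#'   contiguous, ordered and non-overlapping.
#' @return A data.frame of class `elytherm_plan` with columns `label`,
#'   `start_s`, `end_s`.
#' @export
trial_plan <- function(labels, start_s, end_s) {
  ok <- labels %in% c("COOL", "TOTAL", "NIR", "VIS")
  if (!all(ok)) stop("unknown phase label(s): ",
                     paste(unique(labels[!ok]), collapse = ", "), call. = FALSE)
  if (length(labels) != length(start_s) || length(labels) != length(end_s)) {
    stop("labels, start_s, end_s must have equal length", call. = FALSE)
  }
  if (any(end_s <= start_s)) stop("phases must have end_s > start_s", call. = FALSE)
  if (length(start_s) > 1 &&
      any(abs(start_s[-1] - end_s[-length(end_s)]) > 1e-9)) {
    stop("phases must be contiguous and ordered", call. = FALSE)
  }
  structure(data.frame(label = labels, start_s = start_s, end_s = end_s,
                       stringsAsFactors = FALSE),
            class = c("elytherm_plan", "data.frame"))
}

#' @rdname trial_plan
#' @param phase_s duration of each illumination/cooling phase in seconds
#'   (default 300 s = 5 min).
#' @export
canonical_trial_plan <- function(phase_s = 300) {
  labels <- c("COOL", "TOTAL", "COOL", "NIR", "COOL", "VIS", "COOL")
  start_s <- (seq_along(labels) - 1) * phase_s
  trial_plan(labels, start_s, start_s + phase_s)
}

#' Read a trial plan from YAML or JSON
#'
#' The file holds a list of phases, each with `label` and either
#' `duration_s` (phases then run back-to-back from `start_s` of the first,
#' default 0) or explicit `start_s`/`end_s`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return An `elytherm_plan`.
#' @export
read_trial_plan <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  phases <- raw$phases %||% raw
  labels <- vapply(phases, function(p) as.character(p$label), character(1))
  if (!is.null(phases[[1]]$duration_s)) {
    dur <- vapply(phases, function(p) as.numeric(p$duration_s), numeric(1))
    start0 <- as.numeric(phases[[1]]$start_s %||% 0)
    end_s <- start0 + cumsum(dur)
    start_s <- c(start0, end_s[-length(end_s)])
  } else {
    start_s <- vapply(phases, function(p) as.numeric(p$start_s), numeric(1))
    end_s <- vapply(phases, function(p) as.numeric(p$end_s), numeric(1))
  }
  trial_plan(labels, start_s, end_s)
}

#' Write a trial plan to YAML
#' @param plan an `elytherm_plan`.
#' @param path output path.
#' @export
write_trial_plan <- function(plan, path) {
  phases <- lapply(seq_len(nrow(plan)), function(i) {
    list(label = plan$label[[i]], start_s = plan$start_s[[i]],
         end_s = plan$end_s[[i]])
  })
  yaml::write_yaml(list(phases = phases), path)
  invisible(path)
}

#' Segment a trace into the trial's phases
#'
#' Each phase slice contains the samples with `start_s <= t <= end_s`, so a
#' sample lying exactly on a boundary appears as the last point of the
#' earlier slice and the first point (the onset) of the later one: boundary
#' samples are attributed to the later phase for onset purposes.
#'
#' @param trace an `elytherm_trace`.
#' @param plan an `elytherm_plan`; must lie within the trace's time span.
#' @return A list with one element per phase: `label` and `slice`
#'   (an `elytherm_trace`).
#' @export
segment_trial <- function(trace, plan) {
  stopifnot(inherits(trace, "elytherm_trace"), inherits(plan, "elytherm_plan"))
  if (min(plan$start_s) < min(trace$time_s) - 1e-9 ||
      max(plan$end_s) > max(trace$time_s) + 1e-9) {
    stop("trial plan extends outside the trace's time span", call. = FALSE)
  }
  lapply(seq_len(nrow(plan)), function(i) {
    keep <- trace$time_s >= plan$start_s[[i]] - 1e-9 &
            trace$time_s <= plan$end_s[[i]] + 1e-9
    if (sum(keep) < 2L) {
      stop(sprintf("phase %s [%g, %g] s has fewer than 2 samples",
                   plan$label[[i]], plan$start_s[[i]], plan$end_s[[i]]),
           call. = FALSE)
    }
    list(label = plan$label[[i]],
         slice = thermal_trace(trace$time_s[keep], trace$temp_C[keep],
                               channel = trace$channel))
  })
}

#' Temperature change over 5 minutes of illumination
#'
#' `T(onset + 300 s) - T(onset)`, where the onset is the first sample of
#' the phase slice. If no sample falls within 1 s of onset + 300 s, the
#' 300-s value is linearly interpolated from the bracketing samples
#' (robustness to logger jitter).
#'
#' @param slice an `elytherm_trace` covering at least 300 s from its first
#'   sample.
#' @param window_s evaluation horizon in seconds (default 300).
#' @return Temperature change in degrees C over the window.
#' @export
delta_t5 <- function(slice, window_s = 300) {
  stopifnot(inherits(slice, "elytherm_trace"))
  onset_t <- slice$time_s[[1]]
  target <- onset_t + window_s
  if (max(slice$time_s) < target - 1e-9) {
    stop(sprintf("slice spans %g s; %g s needed from onset",
                 max(slice$time_s) - onset_t, window_s), call. = FALSE)
  }
  near <- which(abs(slice$time_s - target) <= 1)
  t_end <- if (length(near)) {
    slice$temp_C[[near[which.min(abs(slice$time_s[near] - target))]]]
  } else {
    stats::approx(slice$time_s, slice$temp_C, xout = target,
                  ties = "ordered")$y
  }
  t_end - slice$temp_C[[1]]
}

#' Maximum heating rate of a phase
#'
#' The maximum slope between two adjacent samples of the heating curve,
#' `max_i (T[i+1] - T[i]) / (t[i+1] - t[i])`, using the actual timestamp
#' gaps (nominally 20 s). For a cooling trace this is the least-negative
#' slope; no smoothing is applied. Ties go to the earliest pair.
#'
#' @param slice an `elytherm_trace` with at least 2 samples.
#' @return A numeric scalar in degC/s with attribute `at_time_s`, the start
#'   time of the winning interval.
#' @export
max_heating_rate <- function(slice) {
  stopifnot(inherits(slice, "elytherm_trace"))
  n <- length(slice$time_s)
  if (n < 2L) stop("need at least 2 samples for a heating rate", call. = FALSE)
  slopes <- diff(slice$temp_C) / diff(slice$time_s)
  i <- which.max(slopes)  # which.max returns the earliest maximum
  structure(slopes[[i]], at_time_s = slice$time_s[[i]])
}

#' Heating metrics for every illumination phase of a trial
#'
#' @param trace sample-channel `elytherm_trace`.
#' @param plan trial plan.
#' @param window_s the dT window (default 300 s).
#' @param baseline baseline rule for the temperature change: `"onset"`
#'   (default) subtracts the phase's first sample; `"precool"` subtracts
#'   the mean of the last 60 s of the preceding cooling phase (the cooling
#'   plateau), when one exists.
#' @return data.frame with columns `phase`, `onset_temp_C`, `delta_t5_C`,
#'   `max_hr_C_per_s`.
#' @export
heating_metrics <- function(trace, plan, window_s = 300,
                            baseline = c("onset", "precool")) {
  baseline <- match.arg(baseline)
  slices <- segment_trial(trace, plan)
  rows <- list()
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    if (s$label == "COOL") next
    dt <- delta_t5(s$slice, window_s)
    if (baseline == "precool" && i > 1 && slices[[i - 1]]$label == "COOL") {
      pre <- slices[[i - 1]]$slice
      tail_keep <- pre$time_s >= max(pre$time_s) - 60
      plateau <- mean(pre$temp_C[tail_keep])
      # shift the reference point; the 300-s endpoint is unchanged
      dt <- dt + (s$slice$temp_C[[1]] - plateau)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      phase = s$label,
      onset_temp_C = s$slice$temp_C[[1]],
      delta_t5_C = dt,
      max_hr_C_per_s = as.numeric(max_heating_rate(s$slice)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' QC check for reference channels
#'
#' Chamber and water-jacket temperatures should remain constant within a
#' trial; drift beyond `max_drift_C` is flagged.
#'
#' @param trace reference-channel `elytherm_trace`.
#' @param max_drift_C allowed peak-to-peak drift (default 0.5 degC).
#' @return Character vector of QC flags (empty if the channel is stable).
#' @export
check_reference_channel <- function(trace, max_drift_C = 0.5) {
  stopifnot(inherits(trace, "elytherm_trace"))
  drift <- diff(range(trace$temp_C))
  if (drift > max_drift_C) {
    sprintf("reference_channel_drift:%s:%.2fC", trace$channel, drift)
  } else {
    character(0)
  }
}
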