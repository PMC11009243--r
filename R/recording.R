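#' Microelectrode recording container
#'
#' The common currency of the synthetic generator, the simulator readout
#' and the analysis pipeline: a regularly sampled voltage trace with the
#' stimulation pulse onsets and (optionally) sorted spike timestamps.
#'
#' @param fs sampling rate (Hz); microelectrode recordings are >= 10 kHz.
#' @param voltage numeric trace (uV; the simulator readout uses
#'   conductance units, which the normalization makes immaterial).
#' @param pulse_times stimulus onsets (s), strictly increasing.
#' @param spike_times action-potential timestamps (s).
#' @param metadata free-form list (site id, intensity uA, frequency Hz).
#' @return An object of class `erna_recording`.
#' @export
erna_recording <- function(fs, voltage, pulse_times,
                           spike_times = numeric(0), metadata = list()) {
  stopifnot(fs > 0, is.numeric(voltage), length(voltage) > 1)
  if (length(pulse_times) > 1 && any(diff(pulse_times) <= 0)) {
    stop("pulse_times must be strictly increasing")
  }
  structure(list(fs = fs, voltage = as.numeric(voltage),
                 pulse_times = as.numeric(pulse_times),
                 spike_times = as.numeric(spike_times),
                 metadata = metadata),
            class = "erna_recording")
}

#' @export
print.erna_recording <- function(x, ...) {
  cat(sprintf("Recording: %.1f s at %g Hz, %d pulses, %d spikes\n",
              length(x$voltage) / x$fs, x$fs, length(x$pulse_times),
              length(x$spike_times)))
  invisible(x)
}

#' Duration of the pre-stimulation window of a recording (s)
#' @param recording an [erna_recording()].
#' @export
prestim_duration <- function(recording) {
  if (length(recording$pulse_times) == 0) {
    return(length(recording$voltage) / recording$fs)
  }
  recording$pulse_times[1]
}

#' Write a recording as a trio of plain-text CSV files
#'
#' `"<stem>_trace.csv"` (time_s, voltage_uv), `"<stem>_pulses.csv"` and
#' `"<stem>_spikes.csv"` (time_s each), the interchange format of the
#' pipeline.
#'
#' @param recording an [erna_recording()].
#' @param stem file path stem.
#' @return The stem, invisibly.
#' @export
write_recording <- function(recording, stem) {
  t <- seq_along(recording$voltage) / recording$fs
  utils::write.csv(data.frame(time_s = t, voltage_uv = recording$voltage),
                   paste0(stem, "_trace.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = recording$pulse_times),
                   paste0(stem, "_pulses.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = recording$spike_times),
                   paste0(stem, "_spikes.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#'
#' @param stem file path stem.
#' @param metadata optional metadata list to attach.
#' @return An [erna_recording()].
#' @export
read_recording <- function(stem, metadata = list()) {
  tr <- utils::read.csv(paste0(stem, "_trace.csv"))
  pu <- utils::read.csv(paste0(stem, "_pulses.csv"))
  sp <- utils::read.csv(paste0(stem, "_spikes.csv"))
  fs <- 1 / stats::median(diff(tr$time_s))
  erna_recording(fs = round(fs), voltage = tr$voltage_uv,
                 pulse_times = pu$time_s, spike_times = sp$time_s,
                 metadata = metadata)
}
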