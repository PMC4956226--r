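#' Preprocess an ECG signal to the AED analysis bandwidth
#'
#' Applies the four-step conditioning chain used by shock-advise algorithms:
#' mean subtraction, a 5-point moving average (smoothing), a 1 Hz high-pass
#' (drift suppression) and a 4th-order 30 Hz Butterworth low-pass, yielding
#' the typical 1--30 Hz monitor bandwidth. Recordings sampled at 500 Hz are
#' first brought to the 250 Hz analysis rate ([decimate_by_two()]). The
#' high- and low-pass stages are applied forward-backward so the waveform
#' morphology is not phase-distorted.
#'
#' @param x numeric ECG signal in microvolts.
#' @param fs sampling rate in Hz; 250 or 500.
#' @return the filtered signal at 250 Hz.
#' @examples
#' x <- ecg_preprocess(sin(2 * pi * 5 * seq(0, 4, by = 1 / 250)), 250)
#' @export
ecg_preprocess <- function(x, fs) {
  if (length(x) == 0 || !is.numeric(x)) {
    abort("empty or non-numeric signal", class = "shockable_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be positive", class = "shockable_error")
  }
  if (!fs %in% c(250, 500)) {
    abort("`fs` must be 250 or 500 Hz", class = "shockable_error")
  }
  if (fs == 500) x <- decimate_by_two(x, 500)
  f <- pp_filters()
  x <- x - mean(x)
  x <- moving_average(x, 5L)
  x <- filtfilt(f$hp, x)
  filtfilt(f$lp, x)
}

# filter bank fixed at the 250 Hz analysis rate (cached after first use)
.pp_cache <- new.env(parent = emptyenv())

pp_filters <- function() {
  if (is.null(.pp_cache$f)) {
    .pp_cache$f <- list(
      hp = butter_filter(1, 1, 250, "high"),
      lp = butter_filter(4, 30, 250, "low")
    )
  }
  .pp_cache$f
}

#' Preprocess every record of a corpus
#'
#' Maps [ecg_preprocess()] over the `samples` list-column; all records end
#' up at 250 Hz with `fs` updated accordingly.
#'
#' @param corpus a corpus tibble (rows from [ecg_record()]).
#' @return the corpus with filtered `samples` and `fs = 250`.
#' @export
preprocess_records <- function(corpus) {
  corpus |>
    mutate(
      samples = map2(.data$samples, .data$fs, ecg_preprocess),
      fs = 250
    )
}
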