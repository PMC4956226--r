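#' Cut annotated records into fixed-duration analysis windows
#'
#' Each single-rhythm annotation interval is tiled with consecutive,
#' non-overlapping, left-aligned windows of `duration` seconds; a trailing
#' remainder shorter than the window is dropped, and windows never span two
#' annotation intervals. Windows are half-open `[t, t + duration)` with
#' 0-based sample indexing.
#'
#' The returned tibble carries an `"audit"` attribute counting, per record,
#' the windows of a continuous record tiling that would straddle an
#' annotation boundary (`n_transition`) and the per-annotation remainders
#' dropped (`n_remainder`) -- the book-keeping needed to reconcile segment
#' counts with the source recordings.
#'
#' @param corpus a preprocessed corpus tibble (250 Hz).
#' @param duration window length in seconds; 4 or 8.
#' @return tibble with one row per candidate segment: `patient_id`,
#'   `record_id`, `segment_id`, `duration`, `start_s`, `source_rhythm`,
#'   `rate_bpm` (annotated, may be `NA`) and `samples` (list-column).
#' @export
segment_records <- function(corpus, duration) {
  if (!duration %in% c(4, 8)) {
    abort("`duration` must be 4 or 8 seconds", class = "shockable_error")
  }
  out <- vector("list", nrow(corpus))
  audit <- vector("list", nrow(corpus))
  for (r in seq_len(nrow(corpus))) {
    fs <- corpus$fs[r]
    x <- corpus$samples[[r]]
    ann <- corpus$annotations[[r]]
    win <- as.integer(round(duration * fs))
    segs <- list()
    n_rem <- 0L
    if (nrow(ann)) {
      for (a in seq_len(nrow(ann))) {
        i0 <- as.integer(round(ann$start_s[a] * fs)) # 0-based
        i1 <- as.integer(round(ann$end_s[a] * fs))
        nwin <- (i1 - i0) %/% win
        if ((i1 - i0) %% win > 0) n_rem <- n_rem + 1L
        if (nwin < 1) next
        for (k in seq_len(nwin)) {
          s0 <- i0 + (k - 1L) * win
          segs[[length(segs) + 1L]] <- tibble(
            patient_id = corpus$patient_id[r],
            record_id = corpus$record_id[r],
            start_s = s0 / fs,
            source_rhythm = ann$rhythm[a],
            rate_bpm = ann$rate_bpm[a],
            samples = list(x[(s0 + 1L):(s0 + win)])
          )
        }
      }
    }
    # audit: windows of the continuous record tiling crossing a boundary
    n_tr <- 0L
    if (nrow(ann) > 1) {
      bounds <- ann$start_s[-1]
      starts <- seq(0, length(x) / fs - duration, by = duration)
      for (s in starts) {
        if (any(bounds > s + 1e-9 & bounds < s + duration - 1e-9)) {
          n_tr <- n_tr + 1L
        }
      }
    }
    audit[[r]] <- tibble(
      record_id = corpus$record_id[r], n_transition = n_tr,
      n_remainder = n_rem
    )
    out[[r]] <- if (length(segs)) bind_rows(segs) else NULL
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble(
      patient_id = character(), record_id = character(), start_s = numeric(),
      source_rhythm = character(), rate_bpm = numeric(), samples = list()
    )
  }
  res <- res |>
    mutate(
      duration = duration,
      segment_id = paste0(.data$record_id, "_", .data$duration, "s_",
        format(.data$start_s, trim = TRUE)
      ),
      .before = 1
    ) |>
    relocate("patient_id", "record_id", "segment_id")
  attr(res, "audit") <- bind_rows(audit)
  res
}

#' Detect rhythm peaks and estimate a rate
#'
#' Simple amplitude-threshold peak picker used by the exclusion rules:
#' local maxima of `|x|` above `threshold_frac` of the segment maximum, with
#' a refractory period. Intended for exclusion logic on synthetic or
#' annotated data, not as a general QRS detector.
#'
#' @param x numeric signal (preprocessed).
#' @param fs sampling rate in Hz.
#' @param threshold_frac detection threshold relative to `max(abs(x))`.
#' @param refractory_s minimum spacing between accepted peaks, seconds.
#' @return `detect_peaks()`: integer vector of peak sample indices (1-based).
#' @export
detect_peaks <- function(x, fs, threshold_frac = 0.4, refractory_s = 0.2) {
  ax <- abs(x)
  n <- length(ax)
  if (n < 3 || max(ax) == 0) return(integer(0))
  thr <- threshold_frac * max(ax)
  cand <- which(
    ax[2:(n - 1)] >= thr &
      ax[2:(n - 1)] >= ax[1:(n - 2)] &
      ax[2:(n - 1)] >= ax[3:n]
  ) + 1L
  if (!length(cand)) return(integer(0))
  cand <- cand[order(ax[cand], decreasing = TRUE)]
  keep <- integer(0)
  refr <- refractory_s * fs
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= refr)) keep <- c(keep, i)
  }
  sort(keep)
}

#' @rdname detect_peaks
#' @return `peak_rate()`: estimated rate in beats per minute.
#' @export
peak_rate <- function(x, fs) {
  length(detect_peaks(x, fs)) / (length(x) / fs) * 60
}

peak_to_peak <- function(x) max(x) - min(x)

#' Label candidate segments and apply the AHA-style exclusion rules
#'
#' Retained segments get `label = +1` (shockable: VF, VT at or above
#' 150 bpm, flutter) or `label = -1` (non-shockable organized rhythms).
#' Excluded, with a reason code:
#' * `noise` -- `NOISE`-annotated windows (noise is excluded by annotation,
#'   not detected algorithmically);
#' * `AS` -- asystole-level windows: peak-to-peak below 100 uV or estimated
#'   rate below 12 bpm;
#' * `fine_VF` -- VF with peak-to-peak below 200 uV;
#' * `slow_VT` -- VT under 150 bpm (annotated rate if present, else the
#'   peak-estimated rate);
#' * `unknown_rhythm` -- any rhythm label outside the recognised set (never
#'   silently dropped).
#'
#' Peak-to-peak amplitudes are measured on the preprocessed signal within
#' the segment by default; set `amplitude_on = "raw"` and supply raw
#' windows to apply the thresholds pre-filtering instead.
#'
#' @param segments tibble from [segment_records()].
#' @param fs sampling rate of the segment samples.
#' @param amplitude_on which signal the amplitude thresholds refer to
#'   (`"filtered"` is how the package applies them; `"raw"` documents the
#'   alternative convention and only changes the audit note).
#' @return `segments` with `p2p_uv`, `est_rate_bpm`, `label` (+1/-1, `NA`
#'   when excluded), `retained` and `reason` columns; the `"audit"`
#'   attribute gains per-reason counts.
#' @export
label_segments <- function(segments, fs = 250,
                           amplitude_on = c("filtered", "raw")) {
  amplitude_on <- match.arg(amplitude_on)
  audit0 <- attr(segments, "audit")
  if (nrow(segments) == 0) {
    res <- segments |>
      mutate(
        p2p_uv = numeric(0), est_rate_bpm = numeric(0),
        label = numeric(0), retained = logical(0), reason = character(0)
      )
    attr(res, "audit") <- audit0
    return(res)
  }
  res <- segments |>
    mutate(
      p2p_uv = map_dbl(.data$samples, peak_to_peak),
      est_rate_bpm = map_dbl(.data$samples, peak_rate, fs = fs)
    ) |>
    mutate(
      reason = dplyr::case_when(
        !.data$source_rhythm %in% rhythm_labels ~ "unknown_rhythm",
        .data$source_rhythm == "NOISE" ~ "noise",
        .data$source_rhythm == "AS" ~ "AS",
        .data$p2p_uv < 100 | .data$est_rate_bpm < 12 ~ "AS",
        .data$source_rhythm == "VF" & .data$p2p_uv < 200 ~ "fine_VF",
        .data$source_rhythm == "VT" &
          dplyr::coalesce(.data$rate_bpm, .data$est_rate_bpm) < 150 ~
          "slow_VT",
        TRUE ~ NA_character_
      ),
      retained = is.na(.data$reason),
      label = dplyr::case_when(
        !.data$retained ~ NA_real_,
        .data$source_rhythm %in% c("VF", "VT") ~ 1,
        TRUE ~ -1
      )
    )
  counts <- res |>
    filter(!.data$retained) |>
    count(.data$reason, name = "n")
  attr(res, "audit") <- list(
    segmentation = audit0,
    exclusions = counts,
    amplitude_on = amplitude_on,
    n_retained = sum(res$retained),
    n_candidates = nrow(res)
  )
  res
}

#' Summarise the segmentation/labelling audit trail
#'
#' @param segments a labelled segment tibble from [label_segments()].
#' @return the audit list (segmentation counts, exclusion counts, totals).
#' @export
segment_audit <- function(segments) {
  attr(segments, "audit")
}

#' Write the per-segment dataset as a delimited table
#'
#' One row per candidate segment (`patient_id`, `duration`, `label`,
#' exclusion reason if any); raw windows go to a companion `.windows.csv`
#' with one sample column per row index, so the archive stays plain text.
#'
#' @param segments labelled segment tibble.
#' @param path output CSV path.
#' @param windows also write the raw-window archive next to `path`.
#' @export
write_segment_table <- function(segments, path, windows = FALSE) {
  tab <- segments |>
    select(dplyr::any_of(c(
      "patient_id", "record_id", "segment_id", "duration", "start_s",
      "source_rhythm", "p2p_uv", "est_rate_bpm", "label", "retained",
      "reason"
    )))
  readr::write_csv(tab, path)
  if (windows) {
    w <- do.call(rbind, segments$samples)
    readr::write_csv(
      as_tibble(as.data.frame(w), .name_repair = "minimal"),
      sub("\\.csv$", ".windows.csv", path)
    )
  }
  invisible(path)
}
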