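#' Extraction configuration for per-cycle feature computation
#'
#' Detector and gating parameters for the cycle-segmentation and feature
#' stage. Defaults are deliberately permissive physiologic gates; none of
#' them is data-set specific.
#'
#' @param refractory_s minimum distance between consecutive R-peaks, in
#'   seconds. Default 0.25 s (240 bpm ceiling for the detector).
#' @param smoothing_window_s moving-average window applied to the second
#'   derivative of the PPG before the landmark search, in seconds.
#'   Default 0.04 s.
#' @param min_hr_bpm,max_hr_bpm physiologic heart-rate gates in beats per
#'   minute; cycles outside are flagged invalid. Defaults 30 and 220.
#' @param min_ptt_s,max_ptt_s pulse-transit-time gates in seconds;
#'   defaults 0.05 and 0.6.
#' @param invert_pir logical; if `TRUE` the PPG intensity ratio is
#'   reported as IL/IH (valley over peak, <= 1) instead of the default
#'   IH/IL (peak over valley, >= 1).
#' @param ppg_dc_offset constant added to a PPG window whose minimum is
#'   <= 0 before the intensity ratio is formed; if the shifted minimum is
#'   still <= 0 the cycle is flagged invalid. Default 0 (no shift).
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(refractory_s = 0.25,
                              smoothing_window_s = 0.04,
                              min_hr_bpm = 30, max_hr_bpm = 220,
                              min_ptt_s = 0.05, max_ptt_s = 0.6,
                              invert_pir = FALSE,
                              ppg_dc_offset = 0) {
  stopifnot(refractory_s > 0, smoothing_window_s >= 0,
            min_hr_bpm > 0, max_hr_bpm > min_hr_bpm,
            min_ptt_s > 0, max_ptt_s > min_ptt_s)
  structure(list(refractory_s = refractory_s,
                 smoothing_window_s = smoothing_window_s,
                 min_hr_bpm = min_hr_bpm, max_hr_bpm = max_hr_bpm,
                 min_ptt_s = min_ptt_s, max_ptt_s = max_ptt_s,
                 invert_pir = isTRUE(invert_pir),
                 ppg_dc_offset = ppg_dc_offset),
            class = "extraction_config")
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  k <- rep(1 / w, w)
  y <- as.numeric(stats::filter(x, k, sides = 2L, method = "convolution"))
  # fall back to the raw samples where the centered window runs off an edge
  y[is.na(y)] <- x[is.na(y)]
  y
}

#' Detect ECG R-peaks
#'
#' Energy-based QRS detection in the Pan-Tompkins spirit: the ECG is
#' differenced, squared and smoothed into a detection envelope; regions
#' exceeding an adaptive threshold (a fraction of the upper envelope
#' quantile) are candidate beats; each candidate is refined to the local
#' maximum of the raw ECG, and candidates closer than the refractory
#' period keep only the larger peak.
#'
#' @param ecg numeric ECG sample vector (>= 2 s of signal).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param config an [extraction_config()].
#' @return integer vector of strictly increasing 0-based R-peak sample
#'   indices (empty when no beat is found).
#' @export
detect_r_peaks <- function(ecg, sampling_rate_hz, config = extraction_config()) {
  stopifnot_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  n <- length(ecg)
  if (n < 2 * sampling_rate_hz) {
    stop("detect_r_peaks: need at least 2 s of signal", call. = FALSE)
  }
  # detection envelope: smoothed squared first difference
  d <- c(0, diff(ecg))
  env <- moving_average(d^2, max(1L, round(0.08 * sampling_rate_hz)))
  top <- stats::quantile(env, 0.99, names = FALSE)
  if (!is.finite(top) || top <= 0) return(integer(0))
  thr <- 0.2 * top
  above <- env > thr
  if (!any(above)) return(integer(0))
  # candidate runs of supra-threshold envelope
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand_start <- starts[r$values]
  cand_end <- ends[r$values]
  # refine each candidate to the raw-ECG maximum in a slightly widened window
  pad <- round(0.05 * sampling_rate_hz)
  peaks <- mapply(function(s, e) {
    s <- max(1L, s - pad); e <- min(n, e + pad)
    s + which.max(ecg[s:e]) - 1L
  }, cand_start, cand_end)
  peaks <- sort(unique(peaks))
  # refractory rule: among peaks closer than refractory_s, keep the larger
  refr <- config$refractory_s * sampling_rate_hz
  keep <- rep(TRUE, length(peaks))
  i <- 1L
  while (i < length(peaks)) {
    nxt <- i + 1L
    while (nxt <= length(peaks) && keep[nxt] == FALSE) nxt <- nxt + 1L
    if (nxt > length(peaks)) break
    if (peaks[nxt] - peaks[i] < refr) {
      if (ecg[peaks[nxt]] > ecg[peaks[i]]) { keep[i] <- FALSE; i <- nxt }
      else keep[nxt] <- FALSE
    } else {
      i <- nxt
    }
  }
  as.integer(peaks[keep] - 1L)  # 0-based
}

#' Second derivative of the PPG (SDPPG)
#'
#' Smoothed second central difference of the PPG scaled by the squared
#' sampling rate, i.e. an estimate of d2 PPG / dt2 in signal units per
#' second squared. Edges are padded by replicating the nearest interior
#' value so the output has the input's length.
#'
#' @param ppg numeric PPG sample vector, length >= 5.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param config an [extraction_config()]; `smoothing_window_s` controls
#'   the moving-average pre-smoothing (0 disables it).
#' @return numeric vector, same length as `ppg`.
#' @export
second_derivative_ppg <- function(ppg, sampling_rate_hz,
                                  config = extraction_config()) {
  n <- length(ppg)
  if (n < 5L) stop("second_derivative_ppg: need at least 5 samples", call. = FALSE)
  d2 <- c(0, diff(diff(ppg)), 0) * sampling_rate_hz^2
  d2[1L] <- d2[2L]
  d2[n] <- d2[n - 1L]
  w <- round(config$smoothing_window_s * sampling_rate_hz)
  if (w %% 2L == 0L) w <- w + 1L  # symmetric window keeps peaks centered
  moving_average(d2, max(1L, w))
}

beat_windows <- function(r_peaks, n_samples) {
  # half-open [r_i, r_{i+1}) windows; the last R-peak closes no cycle
  k <- length(r_peaks)
  if (k < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = r_peaks[-k], end = r_peaks[-1L])
}

#' Per-cycle pulse transit time from R-peaks and the SDPPG
#'
#' For each beat window `[r_i, r_(i+1))` the PTT is the lag, in seconds,
#' from the R-peak to the maximum of the SDPPG within the window. Values
#' outside the configured `[min_ptt_s, max_ptt_s]` gate are returned as
#' `NA` (cycle invalid).
#'
#' @param r_peaks 0-based strictly increasing R-peak indices.
#' @param sdppg SDPPG sample vector (see [second_derivative_ppg()]).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param config an [extraction_config()].
#' @return numeric vector of length `length(r_peaks) - 1`, seconds.
#' @export
extract_ptt <- function(r_peaks, sdppg, sampling_rate_hz,
                        config = extraction_config()) {
  win <- beat_windows(r_peaks, length(sdppg))
  if (!nrow(win)) return(numeric(0))
  vapply(seq_len(nrow(win)), function(i) {
    s <- win$start[i] + 1L  # to 1-based
    e <- min(win$end[i], length(sdppg))
    if (e < s) return(NA_real_)
    ptt <- (which.max(sdppg[s:e]) - 1L) / sampling_rate_hz
    if (ptt < config$min_ptt_s || ptt > config$max_ptt_s) NA_real_ else ptt
  }, numeric(1L))
}

#' Per-cycle PPG intensity ratio
#'
#' The PPG intensity ratio of a cycle is IH/IL, the ratio of the peak
#' (IH) to the valley (IL) PPG intensity within the beat window; it is
#' >= 1 by construction and tracks the arterial diameter change over the
#' cardiac cycle. If the window minimum is <= 0 the configured DC offset
#' is added first; a still non-positive valley leaves the ratio undefined
#' (`NA`). With `invert_pir` the reciprocal IL/IH is reported.
#'
#' @param ppg PPG sample vector.
#' @param r_peaks 0-based R-peak indices delimiting the beat windows.
#' @param config an [extraction_config()].
#' @return numeric vector of length `length(r_peaks) - 1`.
#' @export
extract_pir <- function(ppg, r_peaks, config = extraction_config()) {
  win <- beat_windows(r_peaks, length(ppg))
  if (!nrow(win)) return(numeric(0))
  vapply(seq_len(nrow(win)), function(i) {
    s <- win$start[i] + 1L
    e <- min(win$end[i], length(ppg))
    if (e < s) return(NA_real_)
    w <- ppg[s:e]
    if (min(w) <= 0) w <- w + config$ppg_dc_offset
    ih <- max(w); il <- min(w)
    if (il <= 0) return(NA_real_)
    if (config$invert_pir) il / ih else ih / il
  }, numeric(1L))
}

#' Per-cycle heart rate from R-R intervals
#'
#' `hr_i = 60 * fs / (r_(i+1) - r_i)` beats per minute; values outside
#' the physiologic gate are `NA`.
#'
#' @param r_peaks 0-based strictly increasing R-peak indices (>= 2).
#' @param sampling_rate_hz sampling rate in Hz.
#' @param config an [extraction_config()].
#' @return numeric vector of length `length(r_peaks) - 1`, bpm.
#' @export
extract_hr <- function(r_peaks, sampling_rate_hz, config = extraction_config()) {
  if (length(r_peaks) < 2L) return(numeric(0))
  hr <- 60 * sampling_rate_hz / diff(r_peaks)
  hr[hr < config$min_hr_bpm | hr > config$max_hr_bpm] <- NA_real_
  hr
}

#' Per-cycle systolic and diastolic pressure from the ABP channel
#'
#' SBP is the maximum and DBP the minimum of the ABP waveform over each
#' cycle interval (half-open, 0-based `[start, end)`).
#'
#' @param abp ABP sample vector in mmHg.
#' @param cycle_bounds data.frame with integer columns `start`, `end`.
#' @return data.frame with columns `sbp_mmHg`, `dbp_mmHg` (NA for empty
#'   intervals).
#' @export
extract_sbp_dbp <- function(abp, cycle_bounds) {
  if (!nrow(cycle_bounds)) {
    return(data.frame(sbp_mmHg = numeric(0), dbp_mmHg = numeric(0)))
  }
  sbp <- dbp <- rep(NA_real_, nrow(cycle_bounds))
  for (i in seq_len(nrow(cycle_bounds))) {
    s <- cycle_bounds$start[i] + 1L
    e <- min(cycle_bounds$end[i], length(abp))
    if (e >= s) {
      w <- abp[s:e]
      sbp[i] <- max(w); dbp[i] <- min(w)
    }
  }
  data.frame(sbp_mmHg = sbp, dbp_mmHg = dbp)
}

#' Build the per-cycle feature table of a waveform record
#'
#' Runs the full extraction stage: R-peak detection segments the record
#' into beat windows; PTT, PIR and HR are computed from ECG+PPG and
#' SBP/DBP from ABP, one row per cardiac cycle in which all five
#' quantities pass their validity gates. Cycles with any invalid quantity
#' are dropped and counted in the `dropped_cycles` attribute
#' (`cycles_detected = rows kept + cycles dropped`).
#'
#' @param record a [waveform_record()].
#' @param config an [extraction_config()].
#' @return a feature table data.frame (possibly 0-row) with attributes
#'   `dropped_cycles` and `cycles_detected`.
#' @export
build_feature_table <- function(record, config = extraction_config()) {
  stopifnot(inherits(record, "waveform_record"))
  fs <- record$sampling_rate_hz
  r_peaks <- detect_r_peaks(record$ecg, fs, config)
  empty <- data.frame(record_id = character(0), cycle_index = integer(0),
                      ptt_s = numeric(0), pir_ratio = numeric(0),
                      hr_bpm = numeric(0), sbp_mmHg = numeric(0),
                      dbp_mmHg = numeric(0))
  if (length(r_peaks) < 2L) {
    message(sprintf("build_feature_table('%s'): no complete cardiac cycle detected",
                    record$record_id))
    attr(empty, "dropped_cycles") <- 0L
    attr(empty, "cycles_detected") <- 0L
    return(empty)
  }
  sdppg <- second_derivative_ppg(record$ppg, fs, config)
  ptt <- extract_ptt(r_peaks, sdppg, fs, config)
  pir <- extract_pir(record$ppg, r_peaks, config)
  hr <- extract_hr(r_peaks, fs, config)
  bp <- extract_sbp_dbp(record$abp, beat_windows(r_peaks, length(record$abp)))
  ok <- !is.na(ptt) & !is.na(pir) & !is.na(hr) &
    !is.na(bp$sbp_mmHg) & !is.na(bp$dbp_mmHg) &
    bp$sbp_mmHg >= bp$dbp_mmHg & pir > 0
  n_cycles <- length(ptt)
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(sprintf("build_feature_table('%s'): dropped %d of %d cycle(s)",
                    record$record_id, dropped, n_cycles))
  }
  out <- if (any(ok)) {
    data.frame(record_id = record$record_id,
               cycle_index = which(ok) - 1L,
               ptt_s = ptt[ok], pir_ratio = pir[ok], hr_bpm = hr[ok],
               sbp_mmHg = bp$sbp_mmHg[ok], dbp_mmHg = bp$dbp_mmHg[ok])
  } else {
    empty
  }
  out <- validate_feature_table(out)
  attr(out, "dropped_cycles") <- dropped
  attr(out, "cycles_detected") <- n_cycles
  out
}
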