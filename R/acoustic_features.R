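# Acoustic features of a mono recording: F0 mean/SD via normalized
# autocorrelation over a sex-specific pitch band, intensity mean/SD in dB with
# a low-level gate, and HF500 (high- to low-frequency spectral energy ratio).

# Analysis defaults: 40 ms Hann frames with a 10 ms hop for both the pitch and
# intensity tracks; spectra zero-padded to at least 1024 points for HF500.
acoustic_defaults <- function() {
  list(frame_s = 0.040, hop_s = 0.010, voicing_threshold = 0.45,
       intensity_gate_db = 10, p_ref = 4e-10)
}

#' Sex-specific pitch analysis band
#'
#' The pitch search band acts as the floor/ceiling of the F0 candidate range:
#' 140-300 Hz for female speakers and 75-300 Hz for male speakers.
#'
#' @param speaker_sex `"female"` or `"male"`.
#' @return Numeric vector `c(floor_hz, ceiling_hz)`.
#' @export
pitch_band <- function(speaker_sex = c("female", "male")) {
  speaker_sex <- match.arg(speaker_sex)
  if (speaker_sex == "female") c(140, 300) else c(75, 300)
}

# frame a signal into a frame_len x n_frames matrix (Hann applied by callers)
frame_signal <- function(x, frame_len, hop) {
  n_frames <- 1L + max(0L, (length(x) - frame_len) %/% hop)
  starts <- (seq_len(n_frames) - 1L) * hop + 1L
  idx <- outer(seq_len(frame_len) - 1L, starts, `+`)
  matrix(x[idx], nrow = frame_len)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

#' Frame-level F0 track
#'
#' Estimates per-frame fundamental frequency by the peak of the normalized
#' autocorrelation over the sex-specific candidate lag range, with parabolic
#' interpolation around the peak. Frames whose peak falls below
#' `voicing_threshold` are marked unvoiced, as are frames whose best candidate
#' is a sub-octave of a periodicity above the band ceiling (guards against a
#' pure tone above the ceiling being reported at half its frequency).
#'
#' @param recording An [audio_recording()].
#' @param band Pitch search band `c(floor_hz, ceiling_hz)`; defaults to the
#'   sex-specific band of the recording's speaker.
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @param voicing_threshold Minimum normalized autocorrelation peak for a
#'   frame to count as voiced (default 0.45).
#' @return A `frame_track` list with `frame_times_s`, `values` (Hz, `NA` when
#'   unvoiced), and `voiced` flags.
#' @export
estimate_f0_track <- function(recording, band = NULL,
                              frame_s = acoustic_defaults()$frame_s,
                              hop_s = acoustic_defaults()$hop_s,
                              voicing_threshold = acoustic_defaults()$voicing_threshold) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate_hz
  if (is.null(band)) band <- pitch_band(recording$speaker_sex)
  frame_len <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  if (length(recording$samples) < 2L * frame_len - hop) {
    stop("recording shorter than the minimum analysis length (two frames)")
  }
  lag_min <- floor(fs / band[2])
  lag_max <- ceiling(fs / band[1])
  if (lag_max >= frame_len) stop("frame too short for the pitch floor ", band[1], " Hz")

  frames <- frame_signal(recording$samples, frame_len, hop)
  w <- hann_window(frame_len)
  fw <- (frames - rep(colMeans(frames), each = frame_len)) * w
  nfft <- 2^ceiling(log2(2L * frame_len))
  padded <- rbind(fw, matrix(0, nfft - frame_len, ncol(fw)))
  spec <- stats::mvfft(padded)
  acf_mat <- Re(stats::mvfft(Mod(spec)^2, inverse = TRUE)) / nfft

  n_frames <- ncol(frames)
  times <- ((seq_len(n_frames) - 1L) * hop + frame_len / 2) / fs
  f0 <- rep(NA_real_, n_frames)
  voiced <- logical(n_frames)
  for (j in seq_len(n_frames)) {
    r0 <- acf_mat[1L, j]
    if (r0 <= .Machine$double.eps) next
    r <- acf_mat[, j] / r0
    lags <- lag_min:lag_max
    k <- lags[which.max(r[lags + 1L])]
    peak <- r[k + 1L]
    if (peak < voicing_threshold) next
    # sub-octave guard: if half the lag correlates almost as well, the true
    # periodicity is at twice the candidate frequency, outside the band
    half <- round(k / 2)
    if (half >= 2L && fs / half > band[2] && r[half + 1L] >= 0.9 * peak) next
    # parabolic interpolation around the integer peak lag
    k_star <- k
    if (k > lag_min && k < lag_max) {
      y1 <- r[k]; y2 <- r[k + 1L]; y3 <- r[k + 2L]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > .Machine$double.eps) {
        k_star <- k + 0.5 * (y1 - y3) / denom
      }
    }
    voiced[j] <- TRUE
    f0[j] <- fs / k_star
  }
  structure(list(frame_times_s = times, values = f0, voiced = voiced),
            class = "frame_track")
}

#' @export
print.frame_track <- function(x, ...) {
  flag <- if (!is.null(x$voiced)) x$voiced else x$valid
  cat(sprintf("<frame_track> %d frames (%d valid)\n", length(x$values), sum(flag)))
  invisible(x)
}

#' F0 mean and SD over voiced frames
#'
#' @param track A voiced/unvoiced F0 `frame_track` from [estimate_f0_track()].
#' @return Named vector `c(f0_m = , f0_sd = )` (Hz); sample SD.
#' @export
f0_stats <- function(track) {
  v <- track$values[track$voiced]
  if (length(v) < 2) stop("insufficient voicing: need at least 2 voiced frames")
  c(f0_m = mean(v), f0_sd = stats::sd(v))
}

#' Frame-level intensity track in dB
#'
#' Per-frame intensity is `10 * log10(mean_square / p_ref)` with the mean
#' square taken under a normalized Hann weighting and `p_ref = 4e-10` (the
#' square of the 2e-5 reference pressure, treating samples as pressure-like).
#' All-zero frames are marked invalid.
#'
#' @param recording An [audio_recording()].
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @param p_ref Squared reference pressure.
#' @return A `frame_track` with `frame_times_s`, `values` (dB), `valid` flags.
#' @export
intensity_track <- function(recording,
                            frame_s = acoustic_defaults()$frame_s,
                            hop_s = acoustic_defaults()$hop_s,
                            p_ref = acoustic_defaults()$p_ref) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate_hz
  frame_len <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  if (length(recording$samples) < frame_len) stop("recording shorter than one frame")
  frames <- frame_signal(recording$samples, frame_len, hop)
  w <- hann_window(frame_len)
  w <- w / sum(w)
  ms <- colSums(frames^2 * w)
  valid <- ms > 0
  db <- rep(NA_real_, length(ms))
  db[valid] <- 10 * log10(ms[valid] / p_ref)
  times <- ((seq_len(ncol(frames)) - 1L) * hop + frame_len / 2) / fs
  structure(list(frame_times_s = times, values = db, valid = valid),
            class = "frame_track")
}

#' Intensity mean and SD over gated frames
#'
#' Frames below the gate (default 10 dB) are omitted to reduce the effect of
#' ambient sound.
#'
#' @param track An intensity `frame_track` from [intensity_track()].
#' @param gate_db Gate threshold in dB.
#' @return Named vector `c(int_m = , int_sd = )` (dB); sample SD.
#' @export
intensity_stats <- function(track, gate_db = acoustic_defaults()$intensity_gate_db) {
  v <- track$values[track$valid & !is.na(track$values) & track$values >= gate_db]
  if (length(v) < 2) stop("fewer than 2 frames at or above the ", gate_db, " dB gate")
  c(int_m = mean(v), int_sd = stats::sd(v))
}

#' HF500: high- to low-frequency spectral energy ratio
#'
#' The ratio of summed power above 500 Hz to summed power at or below 500 Hz
#' in the averaged power spectrum of intensity-gated frames (silences
#' excluded). The DC bin is excluded from the low band.
#'
#' @param recording An [audio_recording()].
#' @param intensity_gate Gate in dB applied framewise before averaging
#'   spectra.
#' @param split_hz Band boundary (default 500 Hz).
#' @param frame_s,hop_s Frame length and hop in seconds.
#' @return HF500 ratio (>= 0).
#' @export
compute_hf500 <- function(recording,
                          intensity_gate = acoustic_defaults()$intensity_gate_db,
                          split_hz = 500,
                          frame_s = acoustic_defaults()$frame_s,
                          hop_s = acoustic_defaults()$hop_s) {
  stopifnot(inherits(recording, "audio_recording"))
  fs <- recording$sample_rate_hz
  frame_len <- round(frame_s * fs)
  hop <- round(hop_s * fs)
  if (length(recording$samples) < frame_len) stop("recording shorter than one frame")
  itrack <- intensity_track(recording, frame_s, hop_s)
  keep <- itrack$valid & !is.na(itrack$values) & itrack$values >= intensity_gate
  if (!any(keep)) stop("no frame passes the ", intensity_gate, " dB intensity gate")
  frames <- frame_signal(recording$samples, frame_len, hop)[, keep, drop = FALSE]
  w <- hann_window(frame_len)
  nfft <- max(1024L, 2^ceiling(log2(frame_len)))
  padded <- rbind(frames * w, matrix(0, nfft - frame_len, ncol(frames)))
  P <- rowMeans(Mod(stats::mvfft(padded))^2)
  freqs <- (seq_len(nfft) - 1L) * fs / nfft
  half <- freqs <= fs / 2
  lo <- sum(P[half & freqs > 0 & freqs <= split_hz])
  hi <- sum(P[half & freqs > split_hz])
  if (lo <= 0 || lo / (lo + hi) < 1e-6) {
    stop("degenerate low band: no energy below ", split_hz, " Hz")
  }
  hi / lo
}

#' Extract all five acoustic features
#'
#' @param recording An [audio_recording()].
#' @param voicing_threshold Passed to [estimate_f0_track()].
#' @param intensity_gate_db Gate used for intensity statistics and HF500.
#' @return A one-row data frame with columns `F0_m`, `F0_sd`, `Int_m`,
#'   `Int_sd`, `HF500`.
#' @export
extract_acoustic <- function(recording,
                             voicing_threshold = acoustic_defaults()$voicing_threshold,
                             intensity_gate_db = acoustic_defaults()$intensity_gate_db) {
  f0 <- f0_stats(estimate_f0_track(recording, voicing_threshold = voicing_threshold))
  it <- intensity_stats(intensity_track(recording), gate_db = intensity_gate_db)
  data.frame(
    F0_m = unname(f0["f0_m"]), F0_sd = unname(f0["f0_sd"]),
    Int_m = unname(it["int_m"]), Int_sd = unname(it["int_sd"]),
    HF500 = compute_hf500(recording, intensity_gate = intensity_gate_db)
  )
}
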