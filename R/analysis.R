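#' Spectrogram and epoch power spectra of summed cortical activity
#'
#' The summed middle-layer voltage (400 Hz) is linearly detrended, then a
#' short-time Fourier spectrogram is computed with a 400 ms Hann window and
#' 360 ms overlap (hop 40 ms), along with plain FFT power spectra for the
#' requested epochs (each epoch detrended separately).
#'
#' @param mln_sum numeric series sampled at `fs`.
#' @param epochs named list of `c(start, end)` epochs in seconds
#'   (default: the normal 4-6 s and perturbed 6-8 s epochs).
#' @param fs sampling rate, Hz.
#' @param window_s,overlap_s spectrogram window and overlap in seconds.
#' @return list with `spectrogram` (list `time`, `freq`, `power`: frames in
#'   columns) and `epochs` (per epoch a data.frame `freq`, `power`).
#' @export
epoch_spectra <- function(mln_sum, epochs = list(normal = c(4, 6),
                                                 perturbed = c(6, 8)),
                          fs = 400, window_s = 0.4, overlap_s = 0.36) {
  n <- length(mln_sum)
  x <- pracma::detrend(as.numeric(mln_sum), tt = "linear")[, 1]
  win <- round(window_s * fs)
  hop <- win - round(overlap_s * fs)
  n_frames <- floor((n - win) / hop) + 1
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, win - 1) / (win - 1)))
  nk <- floor(win / 2) + 1
  power <- matrix(0, nk, n_frames)
  for (j in seq_len(n_frames)) {
    seg <- x[((j - 1) * hop + 1):((j - 1) * hop + win)] * hann
    power[, j] <- (Mod(fft(seg))^2 / win)[seq_len(nk)]
  }
  ep <- lapply(epochs, function(e) {
    i0 <- floor(e[1] * fs) + 1; i1 <- floor(e[2] * fs)
    if (i0 < 1 || i1 > n) stop("epoch outside series", call. = FALSE)
    seg <- pracma::detrend(as.numeric(mln_sum[i0:i1]), tt = "linear")[, 1]
    m <- length(seg)
    pw <- Mod(fft(seg))^2 / m
    k <- seq_len(floor(m / 2) + 1)
    data.frame(freq = (k - 1) * fs / m, power = pw[k])
  })
  list(spectrogram = list(time = ((seq_len(n_frames) - 1) * hop + win / 2) / fs,
                          freq = (seq_len(nk) - 1) * fs / win,
                          power = power),
       epochs = ep)
}

#' Peak frequency of a power spectrum
#'
#' @param spec data.frame with `freq` and `power` (as returned in
#'   `epoch_spectra()$epochs`).
#' @param band optional `c(lo, hi)` restriction in Hz.
#' @param min_freq frequencies below this are ignored (drops the DC bin).
#' @return frequency of maximal power, Hz.
#' @export
spectral_peak <- function(spec, band = NULL, min_freq = 1) {
  keep <- spec$freq >= min_freq
  if (!is.null(band)) keep <- keep & spec$freq >= band[1] & spec$freq <= band[2]
  spec$freq[keep][which.max(spec$power[keep])]
}

#' Band-integrated power
#'
#' @param spec data.frame with `freq` and `power`.
#' @param band `c(lo, hi)` in Hz (default the 8-12 Hz alpha band).
#' @return summed power within the band.
#' @export
band_power <- function(spec, band = c(8, 12)) {
  sum(spec$power[spec$freq >= band[1] & spec$freq <= band[2]])
}

#' Dominant spectrogram frequency over a time interval
#'
#' Peak frequency of the spectrogram power averaged over the frames whose
#' centers fall inside the interval (the dominant rhythm of the interval).
#'
#' @param sg the `spectrogram` element of [epoch_spectra()].
#' @param interval `c(start, end)` in seconds.
#' @param min_freq ignore bins below this frequency, Hz.
#' @return peak frequency of the time-averaged spectrogram, Hz.
#' @export
spectrogram_peak_frequency <- function(sg, interval, min_freq = 2) {
  frames <- which(sg$time >= interval[1] & sg$time <= interval[2])
  keep <- sg$freq >= min_freq
  avg <- rowMeans(sg$power[, frames, drop = FALSE])
  sg$freq[keep][which.max(avg[keep])]
}

#' Power-weighted dominant frequency of a spectrogram interval
#'
#' The spectrogram's 400 ms window quantizes frequency to 2.5 Hz bins, so
#' the argmax peak of a rhythm near 10 Hz alternates between adjacent bins
#' from trial to trial.  The power-weighted mean frequency (spectral
#' centroid) of the time-averaged spectrogram over a band containing the
#' rhythm is a stable estimator of the dominant frequency.
#'
#' @param sg the `spectrogram` element of [epoch_spectra()].
#' @param interval `c(start, end)` in seconds.
#' @param band frequency band considered, Hz.
#' @return power-weighted mean frequency, Hz.
#' @export
spectrogram_dominant_frequency <- function(sg, interval, band = c(2, 20)) {
  frames <- which(sg$time >= interval[1] & sg$time <= interval[2])
  avg <- rowMeans(sg$power[, frames, drop = FALSE])
  k <- sg$freq >= band[1] & sg$freq <= band[2]
  sum(sg$freq[k] * avg[k]) / sum(avg[k])
}

#' Dominant oscillation frequency of the eye trace
#'
#' Subtracts the target trajectory from the eye position, linearly detrends
#' the residual over the epoch, projects out any remaining component at the
#' target frequency (lag-induced leakage), and returns the peak of the FFT
#' power spectrum.
#'
#' @param eye,target aligned series at `fs`.
#' @param epoch `c(start, end)` window in seconds.
#' @param fs sampling rate, Hz.
#' @param target_freq frequency of the target sinusoid to remove, Hz.
#' @param min_freq lowest frequency considered for the peak, Hz.
#' @return peak frequency, Hz.
#' @export
eye_oscillation_peak <- function(eye, target, epoch, fs = 400,
                                 target_freq = 1, min_freq = 1) {
  idx <- seq(floor(epoch[1] * fs) + 1, floor(epoch[2] * fs))
  seg <- pracma::detrend(as.numeric(eye[idx] - target[idx]), tt = "linear")[, 1]
  tt <- (seq_along(seg) - 1) / fs
  X <- cbind(sin(2 * pi * target_freq * tt), cos(2 * pi * target_freq * tt))
  seg <- seg - X %*% solve(crossprod(X), crossprod(X, seg))
  pw <- Mod(fft(seg))^2
  freqs <- (seq_along(seg) - 1) * fs / length(seg)
  keep <- freqs >= min_freq & freqs <= fs / 2
  freqs[keep][which.max(pw[keep])]
}

#' Root-mean-square gaze error
#'
#' @param eye,target aligned series at `fs`.
#' @param epoch `c(start, end)` in seconds (half-open); `NULL` for the
#'   whole series.
#' @param fs sampling rate, Hz.
#' @return sqrt of the mean squared eye-target difference (index units).
#' @export
rms_error <- function(eye, target, epoch = NULL, fs = 400) {
  if (length(eye) != length(target))
    stop("eye and target lengths differ", call. = FALSE)
  if (!is.null(epoch)) {
    idx <- seq(floor(epoch[1] * fs) + 1, floor(epoch[2] * fs))
    eye <- eye[idx]; target <- target[idx]
  }
  sqrt(mean((eye - target)^2))
}

#' Count high-velocity ("saccade-like") eye movements
#'
#' Number of samples at which the absolute instantaneous eye speed, in
#' index units per sampling epoch (2.5 ms at 400 Hz), strictly exceeds the
#' threshold.  Counts both large catch-up saccades and small jerky
#' movements.
#'
#' @param eye eye-position series at `fs`.
#' @param epoch optional `c(start, end)` window in seconds.
#' @param threshold speed threshold in index units per sample (default 0.5).
#' @param fs sampling rate, Hz.
#' @return nonnegative integer count.
#' @export
count_high_velocity <- function(eye, epoch = NULL, threshold = 0.5, fs = 400) {
  if (!is.null(epoch)) {
    idx <- seq(floor(epoch[1] * fs) + 1, floor(epoch[2] * fs))
    eye <- eye[idx]
  }
  sum(abs(diff(eye)) > threshold)
}

#' Per-trial epoch metrics
#'
#' @param record a `trial_record`.
#' @param normal,perturbed epochs in seconds.
#' @return one-row data.frame with rms error, high-velocity counts and
#'   alpha-band power for both epochs, plus the perturbed/normal rms ratio.
#' @export
epoch_metrics <- function(record, normal = c(4, 6), perturbed = c(6, 8)) {
  fs <- record$record_rate
  sp <- epoch_spectra(record$mln_sum, epochs = list(normal = normal,
                                                    perturbed = perturbed),
                      fs = fs)
  rms_n <- rms_error(record$eye, record$target, normal, fs)
  rms_p <- rms_error(record$eye, record$target, perturbed, fs)
  data.frame(
    kind = record$perturbation$kind,
    strength = record$perturbation$strength,
    seed = record$seed,
    task = record$task$kind,
    rms_normal = rms_n, rms_perturbed = rms_p, rms_ratio = rms_p / rms_n,
    nhv_normal = count_high_velocity(record$eye, normal, fs = fs),
    nhv_perturbed = count_high_velocity(record$eye, perturbed, fs = fs),
    alpha_normal = band_power(sp$epochs$normal),
    alpha_perturbed = band_power(sp$epochs$perturbed))
}

#' Summarize a perturbation sweep
#'
#' @param records list of `trial_record` objects.
#' @return list with `trials` (one row per record, from [epoch_metrics()])
#'   and `cells` (mean and SD across seeds per task x kind x strength
#'   cell).
#' @export
summarize_sweep <- function(records) {
  if (length(records) == 0) {
    empty <- epoch_metrics_template()
    return(list(trials = empty, cells = aggregate_cells(empty)))
  }
  trials <- do.call(rbind, lapply(records, epoch_metrics))
  list(trials = trials, cells = aggregate_cells(trials))
}

epoch_metrics_template <- function() {
  data.frame(kind = character(), strength = numeric(), seed = integer(),
             task = character(), rms_normal = numeric(),
             rms_perturbed = numeric(), rms_ratio = numeric(),
             nhv_normal = integer(), nhv_perturbed = integer(),
             alpha_normal = numeric(), alpha_perturbed = numeric())
}

aggregate_cells <- function(trials) {
  if (nrow(trials) == 0) {
    return(data.frame(task = character(), kind = character(),
                      strength = numeric(), n_seeds = integer(),
                      mean_rms_ratio = numeric(), sd_rms_ratio = numeric(),
                      mean_nhv_perturbed = numeric(),
                      sd_nhv_perturbed = numeric(),
                      mean_nhv_normal = numeric()))
  }
  key <- interaction(trials$task, trials$kind, trials$strength, drop = TRUE)
  rows <- lapply(split(trials, key), function(d) {
    data.frame(task = d$task[1], kind = d$kind[1], strength = d$strength[1],
               n_seeds = nrow(d),
               mean_rms_ratio = mean(d$rms_ratio),
               sd_rms_ratio = sd_or_zero(d$rms_ratio),
               mean_nhv_perturbed = mean(d$nhv_perturbed),
               sd_nhv_perturbed = sd_or_zero(d$nhv_perturbed),
               mean_nhv_normal = mean(d$nhv_normal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$task, out$kind, abs(out$strength)), ]
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0
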