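# Preprocessing of raw 12-lead records into model-ready 12x400 median beats:
# band-pass filtering, amplitude quality control, R-peak detection, R-aligned
# median-beat extraction, cohort filtering and stratified splitting.

#' Construct a raw 12-lead ECG record
#'
#' Signals are stored in raw amplitude units (the stored mV/100 scale: a value
#' of 100 is 1 mV). Lead order is fixed to [lead_names()].
#'
#' @param signals 12 x T numeric matrix (T >= fs, i.e. at least one second)
#' @param fs sampling rate, Hz (default 500)
#' @param subject_id identifier
#' @return object of class `ecg_record`
#' @export
ecg_record <- function(signals, fs = 500, subject_id = "S1") {
  signals <- as.matrix(signals)
  if (nrow(signals) != 12 || ncol(signals) < fs || !all(is.finite(signals))) {
    abort_ecgvae("record must be a finite 12 x T matrix with T >= fs", "bad_input")
  }
  rownames(signals) <- lead_names()
  structure(list(signals = signals, fs = fs, lead_order = lead_names(),
                 subject_id = subject_id),
            class = "ecg_record")
}

#' Low-level median-beat constructor
#'
#' @param signals 12 x L numeric matrix in raw amplitude units
#' @param fs sampling rate the beat is referenced to
#' @return object of class `median_beat`
#' @export
new_median_beat <- function(signals, fs = 500) {
  signals <- as.matrix(signals)
  if (nrow(signals) != 12 || !all(is.finite(signals))) {
    abort_ecgvae("median beat must be a finite 12 x L matrix", "bad_input")
  }
  rownames(signals) <- lead_names()
  structure(list(signals = signals, fs = fs), class = "median_beat")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: 12 x %d @ %g Hz\n", x$subject_id,
              ncol(x$signals), x$fs))
  invisible(x)
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("<median_beat> 12 x %d @ %g Hz\n", ncol(x$signals), x$fs))
  invisible(x)
}

#' Design the band-pass FIR used for baseline-drift removal
#'
#' Hamming-windowed linear-phase FIR, passband `low_hz`-`high_hz`. The tap
#' count is 4 fs / low_hz rounded up to an odd integer so the group delay
#' (ntaps - 1)/2 is a whole number of samples; the residual DC gain of the
#' windowed design is nulled exactly by subtracting the tap mean (the induced
#' passband perturbation is below 3e-5 at 10 Hz for the default design).
#'
#' @param fs sampling rate, Hz
#' @param low_hz,high_hz band edges, Hz
#' @return numeric vector of filter taps
#' @export
design_bandpass <- function(fs = 500, low_hz = 3, high_hz = 45) {
  if (low_hz >= high_hz || high_hz >= fs / 2) {
    abort_ecgvae("need 0 < low_hz < high_hz < fs/2", "invalid_band")
  }
  ntaps <- ceiling(4 * fs / low_hz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, c(low_hz, high_hz) / (fs / 2), type = "pass")
  as.numeric(h) - mean(h)
}

#' Band-pass filter a 12-lead record
#'
#' Applies the linear-phase FIR of [design_bandpass()] by direct convolution
#' with zero padding; the integer group delay is compensated by an index
#' shift, so features stay aligned with the input.
#'
#' @param rec `ecg_record`
#' @param low_hz,high_hz band edges, Hz (defaults 3 and 45)
#' @return filtered `ecg_record`
#' @export
bandpass_filter <- function(rec, low_hz = 3, high_hz = 45) {
  stopifnot(inherits(rec, "ecg_record"))
  h <- design_bandpass(rec$fs, low_hz, high_hz)
  delay <- (length(h) - 1) / 2
  Tn <- ncol(rec$signals)
  out <- t(apply(rec$signals, 1, function(x) {
    y <- stats::convolve(x, rev(h), type = "open")
    y[delay + seq_len(Tn)]
  }))
  ecg_record(out, fs = rec$fs, subject_id = rec$subject_id)
}

#' Amplitude quality control
#'
#' Fails any record or beat whose absolute amplitude exceeds the threshold
#' (strictly) in any lead at any sample. The default of 800 raw units is 8 mV
#' on the stored mV/100 scale; a value exactly at the threshold passes.
#'
#' @param x `ecg_record`, `median_beat`, or a numeric matrix
#' @param threshold raw-unit amplitude threshold (default 800)
#' @return TRUE (pass) or FALSE (fail)
#' @export
amplitude_qc <- function(x, threshold = 800) {
  sig <- if (inherits(x, "ecg_record") || inherits(x, "median_beat")) x$signals else x
  max(abs(sig)) <= threshold
}

moving_avg <- function(x, w) {
  # centered moving average via cumulative sums, edges shrink
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect R peaks in one lead
#'
#' Squared-derivative energy detector in the Pan-Tompkins spirit: the chosen
#' lead is differentiated, squared and smoothed with a 150 ms moving average;
#' strict local maxima of the energy envelope separated by at least 200 ms are
#' candidate beats; candidates below 0.3 x the median candidate height are
#' dropped; finally each peak is refined to the maximum of the signal itself
#' within +/- 75 ms. The input is expected to be band-pass filtered.
#'
#' @param rec `ecg_record`
#' @param lead lead name used for detection (default "II")
#' @param min_sep_s minimum peak separation, seconds (default 0.2)
#' @return increasing integer vector of R-peak sample indices
#' @export
detect_r_peaks <- function(rec, lead = "II", min_sep_s = 0.2) {
  stopifnot(inherits(rec, "ecg_record"))
  x <- rec$signals[lead, ]
  fs <- rec$fs
  e <- moving_avg(c(0, diff(x))^2, max(3, round(0.15 * fs)))
  sep <- round(min_sep_s * fs)
  n <- length(e)
  if (max(e) <= 0) abort_ecgvae("no beats found", "no_beats")
  # strict local maxima of the envelope
  cand <- which(e > c(-Inf, e[-n]) & e >= c(e[-1], -Inf) & e > 1e-9 * max(e))
  if (!length(cand)) abort_ecgvae("no beats found", "no_beats")
  # greedy non-maximum suppression by envelope height
  keep <- logical(length(cand))
  ord <- order(e[cand], decreasing = TRUE)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(cand[i] - taken) >= sep)) {
      keep[i] <- TRUE
      taken <- c(taken, cand[i])
    }
  }
  cand <- sort(cand[keep])
  # adaptive threshold: robust to both many sub-QRS candidates (T waves,
  # noise) and to a single large artifact dominating the record
  thr <- 0.3 * stats::quantile(e[cand], 0.85, names = FALSE)
  cand <- cand[e[cand] > thr]
  # refine to the signal maximum nearby
  half <- round(0.075 * fs)
  peaks <- vapply(cand, function(i) {
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + half))
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # dedupe refined peaks that collapsed onto the same R wave
  if (length(peaks) > 1) {
    d <- diff(peaks)
    while (any(d < sep)) {
      i <- which(d < sep)[1]
      drop <- if (x[peaks[i]] >= x[peaks[i + 1]]) i + 1 else i
      peaks <- peaks[-drop]
      if (length(peaks) < 2) break
      d <- diff(peaks)
    }
  }
  if (length(peaks) < 2) abort_ecgvae("fewer than 2 beats found", "no_beats")
  peaks
}

#' Extract the median beat of a record
#'
#' Beats are windowed 300 ms before to 500 ms after each detected R peak
#' (windows extending past the record are dropped), the per-sample median is
#' taken across beats, and the result is uniformly resampled to `out_len`
#' columns. At 500 Hz the window is exactly 400 samples, so resampling to the
#' default length is the identity.
#'
#' @param rec `ecg_record` (band-pass filtered)
#' @param out_len output beat length (default 400)
#' @param peaks optional precomputed R-peak indices; detected if NULL
#' @param lead detection lead passed to [detect_r_peaks()]
#' @return `median_beat` (12 x out_len)
#' @export
median_beat <- function(rec, out_len = 400, peaks = NULL, lead = "II") {
  stopifnot(inherits(rec, "ecg_record"))
  if (is.null(peaks)) peaks <- detect_r_peaks(rec, lead = lead)
  fs <- rec$fs
  pre <- round(0.3 * fs); post <- round(0.5 * fs)
  Tn <- ncol(rec$signals)
  ok <- peaks - pre >= 1 & peaks + post - 1 <= Tn
  peaks <- peaks[ok]
  if (length(peaks) < 2) abort_ecgvae("fewer than 2 complete beats in record", "no_beats")
  wlen <- pre + post
  stack <- array(0, c(length(peaks), 12, wlen))
  for (k in seq_along(peaks)) {
    stack[k, , ] <- rec$signals[, (peaks[k] - pre):(peaks[k] + post - 1)]
  }
  med <- apply(stack, c(2, 3), stats::median)
  if (wlen != out_len) {
    med <- t(apply(med, 1, function(v) {
      stats::approx(seq(0, 1, length.out = wlen), v,
                    xout = seq(0, 1, length.out = out_len))$y
    }))
  }
  new_median_beat(med, fs = fs)
}

#' Filter a cohort for risk modelling
#'
#' Applies, in order: amplitude quality control on the raw signals; exclusion
#' of subjects with no row in the diagnosis table (missing diagnosis);
#' exclusion of prevalent cases (event date on or before the ECG date).
#' Remaining subjects are labelled `incident` (event strictly after the ECG)
#' or `healthy` (no event date). Every exclusion carries a machine-readable
#' reason.
#'
#' @param records named list of `ecg_record` (names = subject ids), or a
#'   data.frame with columns subject_id and qc_pass
#' @param diagnoses data.frame: subject_id, ecg_date, event_date (NA if none),
#'   icd10_code (NA if none); dates must be comparable with `<=`
#' @param threshold amplitude threshold passed to [amplitude_qc()]
#' @return list with `included` (data.frame subject_id, status, subtype) and
#'   `excluded` (data.frame subject_id, reason)
#' @export
cohort_filter <- function(records, diagnoses, threshold = 800) {
  if (is.data.frame(records)) {
    ids <- as.character(records$subject_id)
    qc <- records$qc_pass
  } else {
    ids <- names(records)
    qc <- vapply(records, amplitude_qc, logical(1), threshold = threshold)
  }
  diagnoses$subject_id <- as.character(diagnoses$subject_id)
  inc <- character(0); inc_status <- character(0); inc_sub <- character(0)
  exc <- character(0); exc_reason <- character(0)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!qc[i]) {
      exc <- c(exc, id); exc_reason <- c(exc_reason, "amplitude_qc")
      next
    }
    row <- diagnoses[diagnoses$subject_id == id, , drop = FALSE]
    if (nrow(row) == 0) {
      exc <- c(exc, id); exc_reason <- c(exc_reason, "missing_diagnosis")
      next
    }
    ev <- row$event_date[1]
    if (!is.na(ev) && ev <= row$ecg_date[1]) {
      exc <- c(exc, id); exc_reason <- c(exc_reason, "prevalent_cvd")
      next
    }
    inc <- c(inc, id)
    inc_status <- c(inc_status, if (is.na(ev)) "healthy" else "incident")
    inc_sub <- c(inc_sub, if (is.na(ev)) NA_character_ else row$icd10_code[1])
  }
  list(included = data.frame(subject_id = inc, status = inc_status,
                             subtype = inc_sub, stringsAsFactors = FALSE),
       excluded = data.frame(subject_id = exc, reason = exc_reason,
                             stringsAsFactors = FALSE))
}

#' Stratified train/test split
#'
#' Within every stratum (the 7 CVD subtypes, plus healthy subjects as their
#' own stratum), round(n * test_frac) subjects are drawn into the test set.
#' Strata smaller than ceiling(1 / test_frac) stay entirely in the training
#' set. The split is a partition, seeded and reproducible.
#'
#' @param subjects data.frame with subject_id and a `stratum` column (for
#'   output of [cohort_filter()], use subtype with NA replaced by "healthy")
#' @param test_frac test fraction (default 0.2)
#' @param seed RNG seed
#' @return list with `train` and `test` data.frames
#' @export
stratified_split <- function(subjects, test_frac = 0.2, seed = 1) {
  stopifnot(is.data.frame(subjects), "stratum" %in% names(subjects))
  test_idx <- integer(0)
  with_seed(seed, {
    for (st in sort(unique(subjects$stratum))) {
      idx <- which(subjects$stratum == st)
      n <- length(idx)
      if (n < ceiling(1 / test_frac)) next
      k <- round(n * test_frac)
      if (k >= 1) test_idx <- c(test_idx, sample(idx, k))
    }
  })
  list(train = subjects[setdiff(seq_len(nrow(subjects)), test_idx), , drop = FALSE],
       test = subjects[sort(test_idx), , drop = FALSE])
}
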