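#' Experimental conditions and index codes
#'
#' The six conditions of the stress-induction protocol: a resting
#' `Baseline`, four media-based stress-imitation conditions (`VR`, `AUDIO`,
#' `TEXT`, `VIDEO`) and a time-pressure `COGNITIVE_TASK`.  Adoption
#' fraction is estimated from the cognitive task; imitation effectiveness
#' from the four media conditions.
#'
#' @return Character vectors of condition labels.
#' @export
behavdyn_conditions <- function() {
  c("Baseline", "VR", "AUDIO", "TEXT", "VIDEO", "COGNITIVE_TASK")
}

#' @rdname behavdyn_conditions
#' @export
media_conditions <- function() c("VR", "AUDIO", "TEXT", "VIDEO")

autonomic_indexes <- function() {
  c("RSA", "LFbyHF", "HF", "LF", "TOTPWR", "pNN50", "rMSSD", "SDNN", "AVNN")
}
eeg_indexes <- function() c("Alpha", "Beta", "EEG_Asym")
selfreport_indexes <- function() c("SUS", "PMQ_Anxiety", "PMQ_Relax")

#' Time-domain heart-rate-variability indexes
#'
#' From a series of normal-to-normal (NN) inter-beat intervals in
#' milliseconds: `AVNN` (mean), `SDNN` (standard deviation), `RMSSD`
#' (root mean square of successive differences) and `pNN50` (percentage of
#' successive differences larger than 50 ms in magnitude).
#'
#' @param nn Numeric vector of NN intervals in ms (all > 0, length >= 2).
#' @return A list with `avnn`, `sdnn`, `rmssd`, `pnn50`.
#' @examples
#' hrv_time_domain(c(800, 860, 800, 860))
#' @export
hrv_time_domain <- function(nn) {
  if (length(nn) < 2L) stop("need at least 2 NN intervals", call. = FALSE)
  if (any(nn <= 0)) stop("NN intervals must be positive", call. = FALSE)
  d <- diff(nn)
  list(avnn = mean(nn),
       sdnn = stats::sd(nn),
       rmssd = sqrt(mean(d^2)),
       pnn50 = 100 * mean(abs(d) > 50))
}

#' Frequency-domain heart-rate-variability indexes
#'
#' Resamples the tachogram (NN interval against cumulative time) evenly,
#' removes the mean, and integrates the periodogram over the standard
#' bands: VLF below 0.04 Hz, LF 0.04-0.15 Hz, HF from 0.15 Hz up to
#' `hf_upper` (default 0.4 Hz).  `TOTPWR` is the total power up to the HF
#' upper bound.  Normalised units follow
#' `LFnu = 100 LF / (sigma^2_RR - VLF)` (and analogously for HF), where
#' `sigma^2_RR` is the RR variance.
#'
#' @param nn NN intervals in ms; the recording must span at least 60 s.
#' @param resample_hz Even resampling rate in Hz (default 4).
#' @param hf_upper Upper bound of the HF band in Hz (default 0.4; 0.5 is
#'   also seen in the literature).
#' @return A list with `vlf`, `lf`, `hf`, `totpwr` (ms^2), `lf_nu`,
#'   `hf_nu`, `lf_hf`, `rr_variance`.
#' @export
hrv_frequency_domain <- function(nn, resample_hz = 4, hf_upper = 0.4) {
  if (any(nn <= 0)) stop("NN intervals must be positive", call. = FALSE)
  t <- cumsum(nn) / 1000 # seconds
  if (length(nn) < 4L || (t[length(t)] - t[1L]) < 60)
    stop("recording too short: need at least 60 s of intervals",
         call. = FALSE)
  grid <- seq(t[1L], t[length(t)], by = 1 / resample_hz)
  x <- stats::approx(t, nn, xout = grid)$y
  x <- x - mean(x)
  N <- length(x)
  f <- (seq_len(N) - 1L) * resample_hz / N
  psd <- Mod(stats::fft(x))^2 / (N * resample_hz) # two-sided density
  df <- resample_hz / N
  band_power <- function(flo, fhi) {
    sel <- f > flo & f <= fhi & f <= resample_hz / 2
    2 * sum(psd[sel]) * df # one-sided
  }
  vlf <- band_power(0, 0.04)
  lf <- band_power(0.04, 0.15)
  hf <- band_power(0.15, hf_upper)
  totpwr <- band_power(0, hf_upper)
  rr_var <- mean(x^2)
  denom <- rr_var - vlf
  list(vlf = vlf, lf = lf, hf = hf, totpwr = totpwr,
       lf_nu = if (denom > 0) 100 * lf / denom else NA_real_,
       hf_nu = if (denom > 0) 100 * hf / denom else NA_real_,
       lf_hf = if (hf > 0) lf / hf else NA_real_,
       rr_variance = rr_var)
}

#' Windowed RMS envelope of an EMG trace
#'
#' Root-mean-square rectification of a raw electromyography signal over
#' consecutive non-overlapping windows, yielding an amplitude envelope.
#'
#' @param signal Numeric sampled trace.
#' @param window Window length in samples (1 <= window <= length(signal)).
#' @return Numeric vector of per-window RMS values.
#' @export
emg_rms <- function(signal, window) {
  stopifnot_scalar(window, "window", lower = 1, integer = TRUE)
  if (window > length(signal))
    stop("`window` must not exceed the signal length", call. = FALSE)
  n_win <- floor(length(signal) / window)
  vapply(seq_len(n_win), function(w) {
    seg <- signal[((w - 1L) * window + 1L):(w * window)]
    sqrt(mean(seg^2))
  }, numeric(1))
}

#' Respiration depth, period and rate from a respiratory trace
#'
#' Depth is the point of maximum inspiration minus the point of maximum
#' expiration per breath cycle (peak minus following trough), averaged;
#' the period comes from peak-to-peak spacing and the rate is `60/period`
#' breaths per minute.
#'
#' @param signal Respiratory trace.
#' @param fs Sampling rate in Hz.
#' @return A list with `depth`, `period` (s), `rate` (breaths/min).
#' @export
respiration_features <- function(signal, fs) {
  stopifnot_scalar(fs, "fs", lower = 1e-9)
  d <- diff(signal)
  peaks <- which(diff(sign(d)) == -2) + 1L
  troughs <- which(diff(sign(d)) == 2) + 1L
  if (length(peaks) < 2L)
    stop("no detectable breath cycles: rate undefined", call. = FALSE)
  period <- mean(diff(peaks)) / fs
  depths <- vapply(seq_len(length(peaks) - 1L), function(i) {
    cyc <- signal[peaks[i]:peaks[i + 1L]]
    max(cyc) - min(cyc)
  }, numeric(1))
  list(depth = mean(depths), period = period, rate = 60 / period)
}

#' Frontal EEG alpha asymmetry index
#'
#' Prevalence of alpha-band power in the right hemisphere,
#' `(right - left) / (right + left)`, in \[-1, 1\].  Greater relative right
#' frontal activity (lower right alpha, hence a more negative index under
#' stress) is associated with negative mood.
#'
#' @param alpha_right,alpha_left Alpha-band powers (>= 0, not both 0).
#' @return The asymmetry index.
#' @export
eeg_asymmetry <- function(alpha_right, alpha_left) {
  if (alpha_right < 0 || alpha_left < 0)
    stop("powers must be non-negative", call. = FALSE)
  if (alpha_right + alpha_left == 0)
    stop("both powers are zero: asymmetry undefined", call. = FALSE)
  (alpha_right - alpha_left) / (alpha_right + alpha_left)
}

#' Baseline-relative index changes
#'
#' For each (subject, non-baseline condition, index) computes the signed
#' change relative to the subject's baseline:
#' `delta = (value - baseline) / |baseline|` for physiological indexes
#' (zero baselines are flagged missing, never propagated as triggers), and
#' raw differences for the self-report scales (`SUS`, `PMQ_Anxiety`,
#' `PMQ_Relax`).  A self-report row with no baseline is taken as an
#' already-differenced Post-Pre (or Post-Baseline) score.
#'
#' @param records Data frame with columns `subject`, `group`, `condition`,
#'   `index`, `value` (one value per subject x condition x index; every
#'   subject needs a `Baseline` row per physiological index).
#' @return A data frame with columns `subject`, `group`, `condition`,
#'   `index`, `delta`, `missing`.
#' @export
compute_deltas <- function(records) {
  need <- c("subject", "group", "condition", "index", "value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("`records` must have columns subject, group, condition, index, value",
         call. = FALSE)
  base <- records[records$condition == "Baseline", ]
  post <- records[records$condition != "Baseline", ]
  key <- function(d) paste(d$subject, d$index, sep = "\r")
  bmap <- base$value[match(key(post), key(base))]
  sr <- post$index %in% selfreport_indexes()
  phys_missing <- !sr & (is.na(bmap) | bmap == 0)
  delta <- ifelse(sr,
                  ifelse(is.na(bmap), post$value, post$value - bmap),
                  (post$value - bmap) / abs(bmap))
  delta[phys_missing] <- NA_real_
  missing <- phys_missing | is.na(post$value)
  out <- data.frame(subject = post$subject, group = post$group,
                    condition = post$condition, index = post$index,
                    delta = delta, missing = missing,
                    stringsAsFactors = FALSE)
  if (!any(records$condition == "Baseline") &&
      any(!(records$index %in% selfreport_indexes())))
    stop("no Baseline rows found for physiological indexes", call. = FALSE)
  out
}

#' Default stress directions of the calibration indexes
#'
#' +1 means the index increases under stress (a trigger is
#' `delta > ST`), -1 that it decreases (`delta < -ST`).
#'
#' @return A named numeric vector of +1/-1 per index code.
#' @export
default_stress_directions <- function() {
  c("EMG-Z" = -1, "EMG-CS" = 1, SC_Mean = 1,
    RSA = -1, LFbyHF = 1, HF = -1, LF = 1, TOTPWR = 1,
    pNN50 = -1, rMSSD = -1, SDNN = -1, AVNN = -1,
    Alpha = -1, Beta = 1, EEG_Asym = -1,
    RSP_Amp = -1, RSP_Period = -1)
}

#' Configuration of the stress-threshold rule
#'
#' @param st Stress threshold ST, a relative-change magnitude in \[0, 1\].
#' @param ntuple_min Minimum number of simultaneously satisfied sub-rules
#'   in the combination block (>= 2; the rule names couples, triples, ...).
#' @param include_sus Keep the presence clause `delta(SUS) > 0` (default
#'   TRUE, as printed; note it ignores ST).
#' @param directions Named direction vector, as in
#'   [default_stress_directions()].
#' @return An object of class `stress_rule_config`.
#' @export
stress_rule_config <- function(st, ntuple_min = 2, include_sus = TRUE,
                               directions = default_stress_directions()) {
  stopifnot_scalar(st, "st", 0, 1)
  stopifnot_scalar(ntuple_min, "ntuple_min", lower = 2, integer = TRUE)
  structure(list(st = st, ntuple_min = ntuple_min,
                 include_sus = isTRUE(include_sus),
                 directions = directions),
            class = "stress_rule_config")
}

#' Apply the stress-threshold rule to an index delta table
#'
#' A subject is flagged as stressed in a condition when any clause fires:
#' (i) facial/electrodermal block: (zygomatic EMG down OR corrugator EMG
#' up) AND skin conductance up; (ii) autonomic block: any of the nine HRV/
#' RSA sub-rules; (iii) combination block: at least `ntuple_min` of the
#' autonomic plus EEG sub-rules simultaneously; (iv) presence clause
#' `delta(SUS) > 0` (if enabled); (v) self-report block:
#' `delta(PMQ_Anxiety) > ST` OR `delta(PMQ_Relax) < -ST`.  "Up"/"down"
#' means a relative change beyond +-ST in the index's stress direction.
#' Missing indexes never trigger.
#'
#' @param deltas A delta table from [compute_deltas()].
#' @param cfg A [stress_rule_config()].
#' @return A data frame with one row per (subject, condition): `flagged`
#'   plus a logical trace column per clause (`clause_facial`,
#'   `clause_autonomic`, `clause_combination`, `clause_sus`,
#'   `clause_selfreport`).
#' @export
apply_stress_rule <- function(deltas, cfg) {
  stopifnot(inherits(cfg, "stress_rule_config"))
  st <- cfg$st
  dirs <- cfg$directions
  dir_of <- unname(dirs[deltas$index])
  trig <- !deltas$missing & !is.na(deltas$delta) & !is.na(dir_of) &
    ifelse(!is.na(dir_of) & dir_of > 0,
           deltas$delta > st, deltas$delta < -st)
  trig[is.na(trig)] <- FALSE
  cell <- paste(deltas$subject, deltas$condition, sep = "\r")
  cells <- unique(cell)
  get_trig <- function(idx) {
    m <- match(paste(cells, idx, sep = "\r"),
               paste(cell, deltas$index, sep = "\r"))
    out <- trig[m]
    out[is.na(out)] <- FALSE
    out
  }
  get_delta <- function(idx) {
    m <- match(paste(cells, idx, sep = "\r"),
               paste(cell, deltas$index, sep = "\r"))
    deltas$delta[m]
  }
  facial <- (get_trig("EMG-Z") | get_trig("EMG-CS")) & get_trig("SC_Mean")
  trig_mat <- function(idx_names) {
    matrix(vapply(idx_names, get_trig, logical(length(cells))),
           nrow = length(cells), dimnames = list(NULL, idx_names))
  }
  auto_mat <- trig_mat(autonomic_indexes())
  autonomic <- rowSums(auto_mat) > 0
  comb_mat <- cbind(auto_mat, trig_mat(eeg_indexes()))
  combination <- rowSums(comb_mat) >= cfg$ntuple_min
  sus_delta <- get_delta("SUS")
  sus <- cfg$include_sus & !is.na(sus_delta) & sus_delta > 0
  anx <- get_delta("PMQ_Anxiety")
  rel <- get_delta("PMQ_Relax")
  selfrep <- (!is.na(anx) & anx > st) | (!is.na(rel) & rel < -st)
  first <- match(cells, cell)
  data.frame(subject = deltas$subject[first],
             group = deltas$group[first],
             condition = deltas$condition[first],
             flagged = facial | autonomic | combination | sus | selfrep,
             clause_facial = facial,
             clause_autonomic = autonomic,
             clause_combination = combination,
             clause_sus = sus,
             clause_selfreport = selfrep,
             stringsAsFactors = FALSE)
}

#' Estimate adoption and imitation parameters from stress flags
#'
#' Per group: `adoption_fraction` is the proportion of subjects flagged in
#' the cognitive-task condition; `imitation_effectiveness` is the mean over
#' the four media conditions of the proportion of subjects flagged.  Both
#' lie in \[0, 1\] by construction.
#'
#' @param flags Output of [apply_stress_rule()], covering the media and
#'   cognitive-task conditions.
#' @return A data frame with one row per group: `group`, `n_subjects`,
#'   `adoption_fraction`, `imitation_effectiveness`; per-condition flagged
#'   counts are attached as attribute `flag_counts`.
#' @export
estimate_parameters <- function(flags) {
  if (!is.data.frame(flags) || nrow(flags) == 0L)
    stop("`flags` must be a non-empty data frame", call. = FALSE)
  groups <- unique(flags$group)
  rows <- lapply(groups, function(g) {
    fg <- flags[flags$group == g, ]
    subjects <- unique(fg$subject)
    if (length(subjects) == 0L) stop("empty group", call. = FALSE)
    prop <- function(cond) {
      fc <- fg[fg$condition == cond, ]
      if (nrow(fc) == 0L) return(NA_real_)
      mean(fc$flagged)
    }
    data.frame(group = g, n_subjects = length(subjects),
               adoption_fraction = prop("COGNITIVE_TASK"),
               imitation_effectiveness =
                 mean(vapply(media_conditions(), prop, numeric(1))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  counts <- stats::aggregate(flagged ~ group + condition, data = flags, sum)
  attr(out, "flag_counts") <- counts
  out
}

#' Calibrate a cohort table in one call
#'
#' Convenience wrapper: [compute_deltas()], [apply_stress_rule()],
#' [estimate_parameters()].
#'
#' @param records Index record table (see [compute_deltas()]).
#' @param cfg A [stress_rule_config()].
#' @return As [estimate_parameters()].
#' @export
calibrate_cohort <- function(records, cfg) {
  estimate_parameters(apply_stress_rule(compute_deltas(records), cfg))
}

#' Parameter curves over a stress-threshold grid
#'
#' Evaluates both parameters at each ST on the grid.  Raising the threshold
#' can only unflag subjects, so the curves are non-increasing in ST (the
#' presence clause ignores ST and only adds a constant set).
#'
#' @param records Index record table.
#' @param st_grid Thresholds in \[0, 1\] (non-empty).
#' @param ntuple_min,include_sus,directions Passed to
#'   [stress_rule_config()].
#' @return A data frame with columns `st`, `group`, `adoption_fraction`,
#'   `imitation_effectiveness`.
#' @export
threshold_sweep <- function(records, st_grid, ntuple_min = 2,
                            include_sus = TRUE,
                            directions = default_stress_directions()) {
  if (length(st_grid) == 0L)
    stop("`st_grid` must be non-empty", call. = FALSE)
  deltas <- compute_deltas(records)
  do.call(rbind, lapply(st_grid, function(st) {
    cfg <- stress_rule_config(st, ntuple_min, include_sus, directions)
    est <- estimate_parameters(apply_stress_rule(deltas, cfg))
    cbind(st = st, est)
  }))
}
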