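#' Plausible baseline profiles of the calibration indexes
#'
#' Index-level constants used by the synthetic cohort generator: a
#' plausible baseline magnitude and between-subject coefficient of
#' variation per physiological index, the stress direction (sign of the
#' relative change a stress responder shows), and the self-report scale
#' parameters.  These are the generator's fixed study conditions; the
#' magnitudes are ordinary resting values for young adults (for example an
#' 850 ms mean NN interval, SDNN around 50 ms, LF/HF around 1.5).
#'
#' @return A data frame with columns `index`, `type` (`physio` or
#'   `selfreport`), `baseline_mean`, `baseline_cv`, `direction`,
#'   `sr_shift` (responder shift on the self-report scale), `sr_mean0` and
#'   `sr_sd` (non-responder drift and noise).
#' @export
default_index_profiles <- function() {
  ph <- data.frame(
    index = c("EMG-Z", "EMG-CS", "SC_Mean", "RSP_Amp", "RSP_Period",
              "RSA", "LFbyHF", "HF", "LF", "TOTPWR", "pNN50", "rMSSD",
              "SDNN", "AVNN", "Alpha", "Beta", "EEG_Asym"),
    type = "physio",
    baseline_mean = c(6, 4, 8, 1.2, 4, 35, 1.5, 900, 1100, 3200, 18, 42,
                      50, 850, 20, 14, 0.12),
    baseline_cv = 0.15,
    stringsAsFactors = FALSE)
  ph$direction <- default_stress_directions()[ph$index]
  ph$sr_shift <- NA_real_; ph$sr_mean0 <- NA_real_; ph$sr_sd <- NA_real_
  sr <- data.frame(
    index = c("SUS", "PMQ_Anxiety", "PMQ_Relax"),
    type = "selfreport",
    baseline_mean = NA_real_, baseline_cv = NA_real_,
    direction = c(1, 1, -1),
    sr_shift = c(1.5, 2, -2),
    sr_mean0 = c(-0.5, -1, 1),
    sr_sd = c(0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
  rbind(ph, sr)
}

#' Specification of a synthetic stress cohort
#'
#' Defines a cohort of subjects in groups, a known share of "stress
#' responders" per group and condition, and the effect and noise scales of
#' the index shifts.  The defaults mirror the reference study conditions:
#' 26 female and 16 male undergraduates, responder probabilities 0.8
#' (female) and 0.4 (male) in every condition, responder effect size 0.25
#' (relative change in the stress direction) over index noise of sd 0.05
#' (effects five times the noise).
#'
#' @param n_subjects Named integer vector of subjects per group.
#' @param responder_prob Per-group responder probability: a named vector
#'   (applied to every condition) or a matrix with group rows and the five
#'   non-baseline conditions as columns.
#' @param effect_size Responder shift as a baseline-relative change.
#' @param noise_sd Within-subject index noise (relative change units).
#' @param profiles Index profile table, see [default_index_profiles()].
#' @param seed RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = c(female = 26, male = 16),
                        responder_prob = c(female = 0.8, male = 0.4),
                        effect_size = 0.25, noise_sd = 0.05,
                        profiles = default_index_profiles(),
                        seed = NULL) {
  if (is.null(names(n_subjects)))
    stop("`n_subjects` must be a named vector of group sizes",
         call. = FALSE)
  conds <- setdiff(behavdyn_conditions(), "Baseline")
  if (is.matrix(responder_prob)) {
    if (!all(rownames(responder_prob) %in% names(n_subjects)) ||
        !all(conds %in% colnames(responder_prob)))
      stop("`responder_prob` matrix must be groups x conditions",
           call. = FALSE)
    pr <- responder_prob[names(n_subjects), conds, drop = FALSE]
  } else {
    if (is.null(names(responder_prob)))
      responder_prob <- stats::setNames(
        rep_len(responder_prob, length(n_subjects)), names(n_subjects))
    pr <- matrix(responder_prob[names(n_subjects)],
                 nrow = length(n_subjects), ncol = length(conds),
                 dimnames = list(names(n_subjects), conds))
  }
  if (any(pr < 0) || any(pr > 1))
    stop("responder probabilities must be in [0, 1]", call. = FALSE)
  stopifnot_scalar(effect_size, "effect_size", lower = 0)
  stopifnot_scalar(noise_sd, "noise_sd", lower = 0)
  structure(list(n_subjects = n_subjects, responder_prob = pr,
                 effect_size = effect_size, noise_sd = noise_sd,
                 profiles = profiles, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic NN-interval series
#'
#' Builds an inter-beat series with sinusoidal modulation at the centers of
#' the LF (0.10 Hz) and HF (0.30 Hz) bands plus Gaussian noise:
#' `NN_i = mean_ibi + lf_amp sin(2 pi 0.10 t_i) + hf_amp sin(2 pi 0.30 t_i)
#' + noise`, with a 200 ms physiological floor.  Parameters that would
#' truncate more than 1% of intervals are rejected.
#'
#' @param duration Recording length in seconds (> 0).
#' @param mean_ibi Mean inter-beat interval in ms (> 0).
#' @param lf_amp,hf_amp Modulation amplitudes in ms.
#' @param noise_sd Gaussian noise sd in ms.
#' @param seed Optional RNG seed.
#' @return Numeric vector of NN intervals in ms.
#' @export
generate_nn_series <- function(duration, mean_ibi = 850, lf_amp = 20,
                               hf_amp = 20, noise_sd = 5, seed = NULL) {
  stopifnot_scalar(duration, "duration", lower = 1e-9)
  stopifnot_scalar(mean_ibi, "mean_ibi", lower = 1e-9)
  with_seed(seed, {
    n_max <- ceiling(duration * 1000 / max(mean_ibi - lf_amp - hf_amp, 200)) + 2L
    nn <- numeric(n_max)
    t <- 0
    i <- 0L
    truncated <- 0L
    while (t < duration) {
      i <- i + 1L
      raw <- mean_ibi + lf_amp * sin(2 * pi * 0.10 * t) +
        hf_amp * sin(2 * pi * 0.30 * t) +
        if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0
      if (raw < 200) truncated <- truncated + 1L
      nn[i] <- max(raw, 200)
      t <- t + nn[i] / 1000
    }
    nn <- nn[seq_len(i)]
    if (truncated / i > 0.01)
      stop("parameters yield non-positive intervals at > 1% rate",
           call. = FALSE)
    nn
  })
}

#' Generate a synthetic index table with known ground truth
#'
#' Draws subject baselines around the plausible magnitudes of
#' [default_index_profiles()], samples a responder indicator per subject
#' and non-baseline condition with the group's responder probability, and
#' shifts responders' physiological indexes by `effect_size` times the
#' baseline in the stress direction (plus relative noise for everyone).
#' Self-report scales are generated on their own scales as already-
#' differenced Post-Pre scores: responders shift in the stress direction,
#' non-responders drift mildly the other way (habituation across a
#' session); the presence scale (SUS) is emitted only for the four media
#' conditions, where a presence questionnaire applies.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `records` (an index table for [compute_deltas()])
#'   and `truth` (per subject x condition responder indicators plus the
#'   implied expected `adoption_fraction` and `imitation_effectiveness`
#'   per group as attribute `expected`).
#' @export
generate_index_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  prof <- spec$profiles
  ph <- prof[prof$type == "physio", ]
  sr <- prof[prof$type == "selfreport", ]
  conds <- setdiff(behavdyn_conditions(), "Baseline")
  with_seed(spec$seed, {
    rec <- list(); tru <- list()
    sid <- 0L
    for (g in names(spec$n_subjects)) {
      for (s in seq_len(spec$n_subjects[[g]])) {
        sid <- sid + 1L
        subj <- sprintf("S%03d", sid)
        base <- pmax(ph$baseline_mean *
                       (1 + stats::rnorm(nrow(ph), 0, ph$baseline_cv)),
                     0.1 * ph$baseline_mean)
        rec[[length(rec) + 1L]] <- data.frame(
          subject = subj, group = g, condition = "Baseline",
          index = ph$index, value = base, stringsAsFactors = FALSE)
        responder <- stats::runif(length(conds)) <
          spec$responder_prob[g, conds]
        tru[[length(tru) + 1L]] <- data.frame(
          subject = subj, group = g, condition = conds,
          responder = responder, stringsAsFactors = FALSE)
        for (ci in seq_along(conds)) {
          rel <- ph$direction * spec$effect_size * responder[ci] +
            stats::rnorm(nrow(ph), 0, spec$noise_sd)
          rec[[length(rec) + 1L]] <- data.frame(
            subject = subj, group = g, condition = conds[ci],
            index = ph$index, value = base * (1 + rel),
            stringsAsFactors = FALSE)
          sr_here <- if (conds[ci] %in% media_conditions()) sr
                     else sr[sr$index != "SUS", ]
          sr_val <- sr_here$sr_shift * responder[ci] +
            sr_here$sr_mean0 * (!responder[ci]) +
            stats::rnorm(nrow(sr_here), 0, sr_here$sr_sd)
          rec[[length(rec) + 1L]] <- data.frame(
            subject = subj, group = g, condition = conds[ci],
            index = sr_here$index, value = sr_val,
            stringsAsFactors = FALSE)
        }
      }
    }
    records <- do.call(rbind, rec)
    truth <- do.call(rbind, tru)
    expected <- data.frame(
      group = rownames(spec$responder_prob),
      adoption_fraction = spec$responder_prob[, "COGNITIVE_TASK"],
      imitation_effectiveness =
        rowMeans(spec$responder_prob[, media_conditions(), drop = FALSE]),
      stringsAsFactors = FALSE)
    attr(truth, "expected") <- expected
    list(records = records, truth = truth)
  })
}

#' Map calibration results to system-dynamics adoption scenarios
#'
#' Converts per-group estimates into [sd_adoption_params()]: the estimated
#' adoption fraction becomes `AdoptionFraction` and the estimated imitation
#' effectiveness becomes `ImitationEffectiveness`, with the supplied
#' population constants shared across groups.
#'
#' @param result A calibration result from [estimate_parameters()] (or any
#'   data frame with `group`, `adoption_fraction`,
#'   `imitation_effectiveness`).
#' @param total_population Population size for the scenario (default 1e6).
#' @param contact_rate Contacts per person per unit time (default 100).
#' @return A named list of [sd_adoption_params()], one per group.
#' @export
scenario_from_calibration <- function(result, total_population = 1e6,
                                      contact_rate = 100) {
  stopifnot(is.data.frame(result),
            all(c("group", "adoption_fraction",
                  "imitation_effectiveness") %in% names(result)))
  out <- lapply(seq_len(nrow(result)), function(i)
    sd_adoption_params(total_population, contact_rate,
                       result$adoption_fraction[i],
                       result$imitation_effectiveness[i]))
  stats::setNames(out, result$group)
}
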