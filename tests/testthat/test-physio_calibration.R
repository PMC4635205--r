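test_that("time-domain HRV indexes match hand counts and a loop oracle", {
  flat <- hrv_time_domain(c(800, 800, 800, 800))
  expect_equal(flat, list(avnn = 800, sdnn = 0, rmssd = 0, pnn50 = 0))
  alt <- hrv_time_domain(c(800, 860, 800, 860))
  expect_equal(alt$pnn50, 100)
  expect_equal(alt$rmssd, 60)
  set.seed(17)
  for (rep in 1:200) {
    nn <- stats::rnorm(sample(2:120, 1), 850, 60)
    nn <- pmax(nn, 300)
    expect_equal(hrv_time_domain(nn), oracle_hrv(nn))
  }
  expect_error(hrv_time_domain(800), "at least 2")
  expect_error(hrv_time_domain(c(800, -5)), "positive")
})

test_that("spectral HRV powers land in the band that was modulated", {
  lf_only <- generate_nn_series(300, 850, lf_amp = 50, hf_amp = 0,
                                noise_sd = 0, seed = 1)
  sp <- hrv_frequency_domain(lf_only)
  expect_gt(sp$lf_hf, 10)
  hf_only <- generate_nn_series(300, 850, lf_amp = 0, hf_amp = 50,
                                noise_sd = 0, seed = 1)
  sp2 <- hrv_frequency_domain(hf_only)
  expect_lt(sp2$lf_hf, 0.1)
  both <- hrv_frequency_domain(generate_nn_series(300, 850, 40, 40, 2,
                                                  seed = 2))
  expect_lt(abs(both$lf_nu + both$hf_nu - 100), 5)
  expect_equal(both$totpwr, both$vlf + both$lf + both$hf, tolerance = 1e-9)
  expect_error(hrv_frequency_domain(rep(800, 10)), "60 s")
})

test_that("EMG RMS rectifies window by window", {
  expect_equal(emg_rms(rep(0, 100), 10), rep(0, 10))
  expect_equal(emg_rms(rep(3, 64), 16), rep(3, 4))
  t <- seq(0, 10, by = 1e-3)
  s <- sin(2 * pi * 5 * t)
  env <- emg_rms(s, 2000) # whole periods per window
  expect_true(all(abs(env - 1 / sqrt(2)) / (1 / sqrt(2)) < 0.01))
  expect_error(emg_rms(1:5, 10), "window")
})

test_that("respiration features recover depth, period and rate of a tone", {
  fs <- 25
  t <- seq(0, 60, by = 1 / fs)
  breath <- sin(2 * pi * 0.25 * t)
  f <- respiration_features(breath, fs)
  expect_equal(f$depth, 2, tolerance = 0.01)
  expect_equal(f$rate, 15, tolerance = 0.05)
  slow <- respiration_features(sin(2 * pi * 0.2 * t), fs)
  expect_equal(slow$period, 5, tolerance = 0.05)
  expect_error(respiration_features(rep(1, 500), fs), "undefined")
})

test_that("EEG alpha asymmetry is the normalised right-left contrast", {
  expect_equal(eeg_asymmetry(10, 10), 0)
  expect_equal(eeg_asymmetry(20, 10), 1 / 3)
  expect_equal(eeg_asymmetry(5, 0), 1)
  expect_error(eeg_asymmetry(0, 0), "undefined")
})

test_that("baseline deltas are relative for physiology and raw for self-report", {
  rec <- data.frame(
    subject = "S1", group = "g",
    condition = c("Baseline", "VR", "Baseline", "VR", "VR", "Baseline", "VR"),
    index = c("SDNN", "SDNN", "HF", "HF", "PMQ_Anxiety", "LF", "LF"),
    value = c(10, 15, 900, 900, 2.5, 0, 100),
    stringsAsFactors = FALSE)
  d <- compute_deltas(rec)
  expect_equal(d$delta[d$index == "SDNN"], 0.5)
  expect_equal(d$delta[d$index == "HF"], 0)
  expect_equal(d$delta[d$index == "PMQ_Anxiety"], 2.5) # already post-pre
  lf <- d[d$index == "LF", ]
  expect_true(lf$missing)       # zero baseline flagged, not propagated
  expect_true(is.na(lf$delta))
  expect_error(compute_deltas(data.frame(subject = 1, value = 2)),
               "columns")
})

test_that("stress rule clauses fire exactly as specified", {
  cfg <- stress_rule_config(st = 0.2)
  none <- apply_stress_rule(delta_table_with(), cfg)
  expect_false(none$flagged)
  pmq <- apply_stress_rule(delta_table_with(PMQ_Anxiety = 0.3), cfg)
  expect_true(pmq$flagged)
  expect_true(pmq$clause_selfreport)
  expect_false(pmq$clause_facial || pmq$clause_autonomic)
  # facial block needs the electrodermal gate
  fa <- apply_stress_rule(delta_table_with(`EMG-CS` = 0.3, SC_Mean = 0.5),
                          cfg)
  expect_true(fa$clause_facial)
  fa2 <- apply_stress_rule(delta_table_with(`EMG-CS` = 0.3, SC_Mean = 0.1),
                           cfg)
  expect_false(fa2$clause_facial)
  expect_false(fa2$flagged)
  # single autonomic index suffices for block (ii)
  au <- apply_stress_rule(delta_table_with(rMSSD = -0.4), cfg)
  expect_true(au$clause_autonomic)
  # EEG indexes count only toward the combination block
  eeg1 <- apply_stress_rule(delta_table_with(Alpha = -0.5), cfg)
  expect_false(eeg1$flagged)
  eeg2 <- apply_stress_rule(delta_table_with(Alpha = -0.5, Beta = 0.4), cfg)
  expect_true(eeg2$clause_combination)
  expect_false(eeg2$clause_autonomic)
  # SUS ignores ST and is switchable
  sus <- apply_stress_rule(delta_table_with(SUS = 0.05), cfg)
  expect_true(sus$clause_sus)
  sus_off <- apply_stress_rule(delta_table_with(SUS = 0.05),
                               stress_rule_config(0.2, include_sus = FALSE))
  expect_false(sus_off$flagged)
})

test_that("missing indexes never trigger the rule", {
  d <- delta_table_with(rMSSD = -0.9)
  d$missing[d$index == "rMSSD"] <- TRUE
  out <- apply_stress_rule(d, stress_rule_config(0.2))
  expect_false(out$flagged)
  d2 <- delta_table_with()
  d2 <- d2[d2$index %in% c("SDNN", "AVNN"), ] # sparse table, no crash
  expect_false(apply_stress_rule(d2, stress_rule_config(0.2))$flagged)
})

test_that("parameter estimation is the flagged-subject proportion per condition block", {
  flags <- expand.grid(subject = sprintf("S%02d", 1:10),
                       condition = c(media_conditions(), "COGNITIVE_TASK"),
                       stringsAsFactors = FALSE)
  flags$group <- "g"
  flags$flagged <- FALSE
  est0 <- estimate_parameters(flags)
  expect_equal(est0$adoption_fraction, 0)
  expect_equal(est0$imitation_effectiveness, 0)
  flags$flagged <- TRUE
  est1 <- estimate_parameters(flags)
  expect_equal(est1$adoption_fraction, 1)
  expect_equal(est1$imitation_effectiveness, 1)
  flags$flagged <- flags$condition == "COGNITIVE_TASK" &
    flags$subject %in% sprintf("S%02d", 1:4)
  est <- estimate_parameters(flags)
  expect_equal(est$adoption_fraction, 0.4)
  expect_equal(est$imitation_effectiveness, 0)
})

test_that("flagged sets shrink as the threshold rises", {
  spec <- cohort_spec(n_subjects = c(a = 15), responder_prob = c(a = 0.6),
                      seed = 31)
  gen <- generate_index_table(spec)
  deltas <- compute_deltas(gen$records)
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  prev <- NULL
  for (st in grid) {
    cfg <- stress_rule_config(st, include_sus = FALSE)
    fl <- apply_stress_rule(deltas, cfg)
    cur <- paste(fl$subject, fl$condition)[fl$flagged]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  sweep <- threshold_sweep(gen$records, grid, include_sus = FALSE)
  for (g in unique(sweep$group)) {
    sg <- sweep[sweep$group == g, ]
    expect_true(all(diff(sg$adoption_fraction) <= 1e-12))
    expect_true(all(diff(sg$imitation_effectiveness) <= 1e-12))
    expect_true(all(sg$adoption_fraction >= 0 & sg$adoption_fraction <= 1))
  }
  expect_error(threshold_sweep(gen$records, numeric(0)), "non-empty")
})

test_that("calibration is deterministic given the same table and config", {
  gen <- generate_index_table(cohort_spec(seed = 77))
  a <- calibrate_cohort(gen$records, stress_rule_config(0.2))
  b <- calibrate_cohort(gen$records, stress_rule_config(0.2))
  expect_identical(a, b)
})
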