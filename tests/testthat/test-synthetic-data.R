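test_that("event streams have the exact oddball split and ITI bounds", {
  cfg <- sim_config(seed = 3, duration_per_condition = 1000)
  ev_low <- generate_events(cfg, "low")
  ev_high <- generate_events(cfg, "high")
  # a full two-condition session carries 320 stimuli, 80 of them targets
  expect_equal(nrow(ev_low) + nrow(ev_high), 320)
  expect_equal(sum(ev_low$stimulus == "target") +
                 sum(ev_high$stimulus == "target"), 80)
  expect_equal(sum(ev_low$stimulus == "standard"), 120)
  # degenerate target fraction
  ev0 <- generate_events(sim_config(target_fraction = 0), "low")
  expect_equal(sum(ev0$stimulus == "target"), 0)
  # ITI bounds and grand mean over seeds
  itis <- unlist(lapply(1:20, function(s)
    diff(generate_events(cfg, "low", n = 320, seed = s)$onset)))
  expect_gte(min(itis), 1.0)
  expect_lte(max(itis), 3.0)
  expect_lt(abs(mean(itis) - 2.0), 0.02)
  # events that cannot fit raise a configuration error
  expect_error(generate_events(sim_config(duration_per_condition = 60), "low"),
               "duration")
})

test_that("the P300 kernel peaks at its latency with the Gaussian integral", {
  expect_true(all(erp_kernel(0, 0.45, 0.06, 500) == 0))
  k <- erp_kernel(5, 0.45, 0.06, 500)
  expect_equal(which.max(k) - 1L, round(0.45 * 500))
  expect_equal(max(k), 5)
  # numerical integral vs closed form amplitude * width * sqrt(2*pi)
  expect_lt(abs(sum(k) / 500 - 5 * 0.06 * sqrt(2 * pi)) /
              (5 * 0.06 * sqrt(2 * pi)), 0.01)
})

test_that("recordings have the configured geometry and are seed-deterministic", {
  cfg <- small_config(seed = 9)
  ev <- generate_events(cfg, "low")
  r1 <- generate_recording(cfg, ev, "low")
  r2 <- generate_recording(cfg, ev, "low")
  expect_identical(r1$recording$data, r2$recording$data)
  expect_equal(nrow(r1$recording$data), 6)
  expect_equal(r1$recording$fs, 500)
  expect_gte(recording_duration(r1$recording), 100)
  full <- sim_config(seed = 2)
  rec <- generate_recording(full, generate_events(full, "low"), "low")
  expect_gte(recording_duration(rec$recording), 500)
})

test_that("configured alpha amplitude ratio appears as the squared power ratio", {
  bpm <- default_band_power_map()
  bpm[] <- 0
  bpm["alpha", "Pz", "low"] <- 2
  bpm["alpha", "Pz", "high"] <- 1
  cfg <- sim_config(n_stimuli = 0, duration_per_condition = 60,
                    band_power_map = bpm, noise_rms = 0,
                    artifact_rates = c(blink = 0, burst = 0), seed = 4)
  lo <- generate_recording(cfg, NULL, "low")$recording
  hi <- generate_recording(cfg, NULL, "high")$recording
  p_lo <- welch_band_power(lo$data["Pz", ], 500, c(8, 12))
  p_hi <- welch_band_power(hi$data["Pz", ], 500, c(8, 12))
  expect_lt(abs(p_lo / p_hi - 4), 0.2)
})

test_that("the P300 contrast is recoverable at the generator's SNR", {
  hits <- 0
  for (s in 1:12) {
    cfg <- sim_config(seed = 600 + s, n_stimuli = 80,
                      duration_per_condition = 140,
                      artifact_rates = c(blink = 0, burst = 0))
    amp <- sapply(c("low", "high"), function(cond) {
      ev <- generate_events(cfg, cond)
      rec <- generate_recording(cfg, ev, cond)$recording
      ep <- baseline_correct(extract_epochs(rec, ev, -0.2, 1), c(-0.2, 0))
      tt <- epoch_times(ep)
      sel <- tt >= 0.35 & tt < 0.6
      tgt <- ep$metadata$stimulus == "target"
      mean(ep$data[tgt, 3, sel]) - mean(ep$data[!tgt, 3, sel])
    })
    hits <- hits + (amp["low"] > amp["high"])
  }
  expect_gte(hits, 11)
})

test_that("the calibration lead-in is artifact-free with bounded kurtosis", {
  cfg <- sim_config(seed = 5, duration_per_condition = 120)
  out <- generate_recording(cfg, NULL, "low")
  expect_gt(nrow(out$artifacts), 0)
  expect_true(all(out$artifacts$onset >= cfg$calibration_duration))
  calib <- crop_recording(out$recording, 0, 30)
  kurt <- apply(calib$data, 1, function(v)
    mean((v - mean(v))^4) / stats::sd(v)^4)
  expect_true(all(kurt < 5))
})

test_that("artifact injection is logged, frontal-dominant, and optional", {
  cfg <- small_config(seed = 6)
  rec <- generate_recording(cfg, NULL, "low")$clean
  # zero rates leave the recording untouched
  out0 <- inject_artifacts(rec, cfg)
  expect_identical(out0$recording$data, rec$data)
  expect_equal(nrow(out0$artifacts), 0)
  # blinks dominate Fz relative to the background
  cfgb <- small_config(seed = 6, artifact_rates = c(blink = 10, burst = 0))
  set.seed(1)
  outb <- inject_artifacts(rec, cfgb)
  blinks <- outb$artifacts[outb$artifacts$kind == "blink", ]
  expect_gt(nrow(blinks), 0)
  pre_rms <- rms(rec$data["Fz", ])
  for (i in seq_len(nrow(blinks))) {
    idx <- round(blinks$onset[i] * 500):round((blinks$onset[i] +
                                                 blinks$duration[i]) * 500)
    expect_gte(max(abs(outb$recording$data["Fz", idx])), 10 * pre_rms)
    fz_peak <- max(abs(outb$recording$data["Fz", idx] - rec$data["Fz", idx]))
    pz_peak <- max(abs(outb$recording$data["Pz", idx] - rec$data["Pz", idx]))
    expect_gt(fz_peak, 3 * pz_peak)
  }
})

test_that("YAML configs override defaults and reject unknown fields", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("fs: 250", "n_stimuli: 100",
               "band_power_map:", "  alpha:", "    Pz: {low: 5, high: 1}"),
             path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$fs, 250)
  expect_equal(cfg$band_power_map["alpha", "Pz", "low"], 5)
  expect_equal(cfg$band_power_map["theta", "Oz", "low"], 3)
  writeLines("not_a_field: 1", path)
  expect_error(read_sim_config(path), "unknown config field")
})
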