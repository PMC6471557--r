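test_that("the Riemannian mean satisfies its closed-form fixed points", {
  C <- crossprod(matrix(rnorm(36), 6)) + diag(6)
  expect_equal(riemannian_mean(list(C, C, C)), C, tolerance = 1e-8)
  D <- diag(c(4, 9, 16))
  expect_lt(max(abs(riemannian_mean(list(D, solve(D))) - diag(3))), 1e-6)
  # geometric mean of two commuting matrices is the entrywise geometric mean
  A <- diag(c(1, 2, 3)); B <- diag(c(4, 2, 12))
  expect_equal(diag(riemannian_mean(list(A, B))), sqrt(diag(A) * diag(B)),
               tolerance = 1e-6)
})

test_that("calibration on independent noise yields near-identity mixing", {
  set.seed(41)
  x <- matrix(rnorm(6 * 15000), 6)
  rec <- new_recording(x, 500, paste0("ch", 1:6))
  m <- asr_calibrate(rec, variant = "classic")
  mix <- m$mixing / mean(diag(m$mixing))
  expect_lt(max(abs(mix - diag(6))), 0.1)
  expect_lt(diff(range(m$thresholds)) / mean(m$thresholds), 0.35)
})

test_that("classic and Riemannian calibrations agree on stationary Gaussian data", {
  set.seed(42)
  L <- matrix(rnorm(36), 6)
  x <- t(chol(crossprod(L) + diag(6))) %*% matrix(rnorm(6 * 15000), 6)
  rec <- new_recording(x, 500, paste0("ch", 1:6))
  mc <- asr_calibrate(rec, variant = "classic")
  mr <- asr_calibrate(rec, variant = "riemannian")
  expect_lt(max(abs(sort(mc$thresholds) - sort(mr$thresholds)) /
                  sort(mc$thresholds)), 0.05)
})

test_that("ASR is the identity on its own calibration data at k = 70", {
  cfg <- small_config(seed = 43)
  rec <- generate_recording(cfg, NULL, "low")$recording
  calib <- crop_recording(rec, 0, 30)
  m <- asr_calibrate(calib)
  out <- asr_process(calib, m)
  expect_false(any(out$flags))
  expect_lt(max(abs(out$cleaned$data - calib$data)), 1e-9)
  # and idempotent on clean data
  out2 <- asr_process(out$cleaned, m)
  expect_lt(rms(out2$cleaned$data - out$cleaned$data), 1e-6)
})

test_that("ASR suppresses logged bursts and spares the rest of the signal", {
  cfg <- sim_config(seed = 44, duration_per_condition = 120,
                    artifact_rates = c(blink = 0, burst = 4),
                    burst_amplitude = 500)
  g <- generate_recording(cfg, NULL, "low")
  expect_gt(nrow(g$artifacts), 0)
  m <- asr_calibrate(crop_recording(g$recording, 0, 30))
  out <- asr_process(g$recording, m)
  n <- ncol(g$recording$data)
  inside <- artifact_mask(g$artifacts, n, 500)
  art_before <- g$recording$data[, inside] - g$clean$data[, inside]
  art_after <- out$cleaned$data[, inside] - g$clean$data[, inside]
  expect_lt(rms(art_after), 0.2 * rms(art_before))
  # distortion outside the corrected windows (one window guard) is small
  guard <- artifact_mask(g$artifacts, n, 500, guard_s = m$window_len)
  far <- !guard & seq_len(n) > 30 * 500
  expect_lt(rms(out$cleaned$data[, far] - g$recording$data[, far]),
            0.05 * rms(g$recording$data[, far]))
})

test_that("calibration-level oscillations pass through ASR unchanged", {
  cfg <- small_config(seed = 45)
  rec <- generate_recording(cfg, NULL, "low")$recording
  t <- (seq_len(ncol(rec$data)) - 1) / 500
  rec$data["Pz", ] <- rec$data["Pz", ] + 8 * sin(2 * pi * 10 * t)
  m <- asr_calibrate(crop_recording(rec, 0, 30))
  out <- asr_process(rec, m)
  p_in <- welch_band_power(rec$data["Pz", ], 500, c(9, 11))
  p_out <- welch_band_power(out$cleaned$data["Pz", ], 500, c(9, 11))
  expect_lt(abs(p_out / p_in - 1), 0.05)
})

test_that("flatline channels are detected with the 5-s run criterion", {
  cfg <- small_config(seed = 46)
  rec <- generate_recording(cfg, NULL, "low")$recording
  # zero-variance channel removed
  r0 <- rec; r0$data["Cz", ] <- 2.5
  expect_identical(remove_flatlines(r0)$removed, "Cz")
  # 4.9-s run retained at criterion 5
  r1 <- rec; r1$data["Fz", 1000:(1000 + round(4.9 * 500))] <- 0
  expect_length(remove_flatlines(r1, 5)$removed, 0)
  # 6-s run on Fz removes exactly Fz
  r2 <- rec; r2$data["Fz", 1000:(1000 + 6 * 500)] <- 0
  res <- remove_flatlines(r2, 5)
  expect_identical(res$removed, "Fz")
  expect_identical(res$recording$channel_names,
                   c("Cz", "Pz", "Oz", "P3", "P4"))
  r3 <- rec; r3$data[] <- 1
  expect_error(remove_flatlines(r3), "all channels")
})

test_that("window rejection flags decorrelated channels, not clean data", {
  cfg <- small_config(seed = 47)
  rec <- generate_recording(cfg, NULL, "low")$recording
  qc <- reject_bad_windows(rec)
  expect_lt(mean(!qc$retained), 0.02)
  # replace Oz by independent noise for 3 s
  bad <- rec
  span <- (20 * 500 + 1):(23 * 500)
  bad$data["Oz", span] <- rnorm(length(span), sd = sd(rec$data["Oz", ]))
  qc2 <- reject_bad_windows(bad)
  oz <- match("Oz", rec$channel_names)
  expect_true(all(qc2$flagged[oz, 21:23]))
  expect_false(any(qc2$retained[21:23]))
  # a vacuous window threshold never drops windows
  qc3 <- reject_bad_windows(bad, clean_raw_params(window_bad_fraction = 1))
  expect_true(all(qc3$retained))
})
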