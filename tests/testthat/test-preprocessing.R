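test_that("FIR design: DC null, passband gain, stopband, symmetry", {
  hp <- design_fir(c(0.5, NA), 250, 500)
  expect_lt(abs(sum(hp$coefficients)), 1e-6)   # high-pass null at DC
  bp <- design_fir(c(8, 12), 250, 500)
  expect_equal(length(bp$coefficients), 251)
  expect_equal(bp$coefficients, rev(bp$coefficients))
  expect_gt(filter_response(bp, 10), 0.94)
  expect_lt(filter_response(bp, 10), 1.06)
  # stopband value from the kernel's own FFT at 20 Hz
  expect_lt(filter_response(bp, 20), 0.01)
  lp <- design_fir(c(NA, 30), 250, 500)
  expect_lt(filter_response(lp, 60), 0.01)
  expect_error(design_fir(c(12, 8), 250, 500), "invalid band")
  expect_error(design_fir(c(8, 12), 251, 500), "even")
})

test_that("filtering is zero-lag, linear, and identity under a unit impulse", {
  fs <- 500
  t <- (0:4999) / fs
  x <- matrix(sin(2 * pi * 10 * t), 1)
  bp <- design_fir(c(8, 12), 250, fs)
  y <- apply_filter(x, bp)
  expect_equal(ncol(y), ncol(x))
  mid <- 1000:4000
  expect_lt(abs(max(abs(y[1, mid])) - 1), 0.05)
  cc <- stats::ccf(y[1, mid], x[1, mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # all-zero input stays zero; unit impulse kernel is the identity
  expect_true(all(apply_filter(matrix(0, 2, 2000), bp) == 0))
  ident <- structure(list(coefficients = 1, order = 0, band = c(NA, NA),
                          fs = fs), class = "FilterKernel")
  z <- matrix(rnorm(1000), 2)
  expect_equal(apply_filter(z, ident), z)
  # linearity
  set.seed(8)
  a <- matrix(rnorm(4000), 2); b <- matrix(rnorm(4000), 2)
  lhs <- apply_filter(3 * a + 2 * b, bp)
  rhs <- 3 * apply_filter(a, bp) + 2 * apply_filter(b, bp)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("epoch extraction follows the half-open convention and drops boundary events", {
  cfg <- small_config(seed = 31)
  ev <- generate_events(cfg, "low")
  rec <- generate_recording(cfg, ev, "low")$recording
  ep <- extract_epochs(rec, ev, -0.2, 1.0)
  expect_equal(dim(ep$data)[3], 600)
  expect_equal(n_epochs(ep), nrow(ev))
  expect_equal(attr(ep, "n_dropped"), 0)
  # an event too close to the start is dropped, not fatal
  ev_bad <- new_event_stream(c(0.1, ev$onset), c("standard", ev$stimulus),
                             "low")
  ep2 <- extract_epochs(rec, ev_bad, -0.2, 1.0)
  expect_equal(attr(ep2, "n_dropped"), 1)
  expect_equal(n_epochs(ep2), nrow(ev))
})

test_that("baseline correction zeroes the baseline and is exact on closed forms", {
  cfg <- small_config(seed = 32)
  ev <- generate_events(cfg, "low")
  rec <- generate_recording(cfg, ev, "low")$recording
  ep <- baseline_correct(extract_epochs(rec, ev, -0.2, 1.0), c(-0.2, 0))
  tt <- epoch_times(ep)
  bl <- apply(ep$data[, , tt >= -0.2 & tt < 0, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(bl)), 1e-10)
  # constant epoch becomes zero; a ramp keeps its centred form
  n_s <- 600
  const <- new_epochset(array(7, c(1, 1, n_s)), -0.2, 500, "Pz",
                        data.frame(stimulus = "target", condition = "low"))
  expect_true(all(abs(baseline_correct(const)$data) < 1e-12))
  tt1 <- -0.2 + (0:(n_s - 1)) / 500
  ramp <- new_epochset(array(3 * tt1, c(1, 1, n_s)), -0.2, 500, "Pz",
                       data.frame(stimulus = "target", condition = "low"))
  corr <- baseline_correct(ramp)
  expect_equal(as.vector(corr$data[1, 1, ]),
               3 * (tt1 - mean(tt1[tt1 >= -0.2 & tt1 < 0])))
  expect_error(baseline_correct(ramp, c(-2, -1)), "outside")
})

test_that("decimation keeps every k-th sample and preserves band-limited content", {
  arr <- array(rnorm(10 * 6 * 600), c(10, 6, 600))
  md <- data.frame(stimulus = "target", condition = "low")[rep(1, 10), ]
  ep <- new_epochset(arr, -0.2, 500, paste0("ch", 1:6), md)
  dn <- downsample_epochs(ep, 50)
  expect_equal(dim(dn$data)[3], 60)
  expect_equal(dn$fs, 50)
  expect_equal(dn$data[3, 2, ], arr[3, 2, seq(1, 600, by = 10)])
  expect_error(downsample_epochs(ep, 71), "integer multiple")
  # a band-limited 10 Hz tone keeps its spectral peak after decimation
  t500 <- (0:599) / 500
  tone <- new_epochset(array(rep(sin(2 * pi * 10 * t500), each = 1),
                             c(1, 1, 600)), 0, 500, "Pz", md[1, ])
  dt <- downsample_epochs(tone, 50)
  spec <- Mod(stats::fft(as.vector(dt$data[1, 1, ])))[1:30]
  expect_equal(which.max(spec[-1]), round(10 * 60 / 50))
})

test_that("continuous segmentation partitions the covered span losslessly", {
  cfg <- small_config(seed = 33)
  rec <- generate_recording(cfg, NULL, "low")$recording
  seg <- segment_continuous(rec, 2.0)
  expect_equal(n_epochs(seg), 50)
  expect_equal(dim(seg$data)[3], 1000)
  # concatenation reproduces the first floor(d/2)*2 s exactly
  recon <- do.call(cbind, lapply(seq_len(n_epochs(seg)), function(i)
    matrix(seg$data[i, , ], 6, 1000)))
  expect_equal(recon, unname(rec$data[, 1:50000, drop = FALSE]))
  # remainder discarded
  short <- crop_recording(rec, 0, 3.9)
  expect_equal(n_epochs(segment_continuous(short, 2.0)), 1)
})
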