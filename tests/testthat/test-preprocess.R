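test_that("common average reference matches the explicit per-sample loop", {
  const <- raw_recording(matrix(5, nrow = 3, ncol = 100), 128)
  expect_true(all(apply_car(const)$signal == 0))

  v <- sin(2 * pi * 3 * (0:999) / 128)
  pm <- raw_recording(rbind(v, -v), 128)
  expect_equal(apply_car(pm)$signal, pm$signal, tolerance = 1e-12)

  set.seed(3)
  x <- matrix(rnorm(4000), nrow = 4)
  ref <- x
  for (t in seq_len(ncol(x))) ref[, t] <- x[, t] - mean(x[, t])
  got <- apply_car(raw_recording(x, 128))$signal
  expect_equal(got, ref, tolerance = 1e-12)

  # idempotence and the residual-mean invariant
  expect_equal(apply_car(apply_car(pm))$signal, apply_car(pm)$signal,
               tolerance = 1e-10)
  expect_lt(max(abs(colMeans(got))), 1e-10)

  expect_error(apply_car(raw_recording(matrix(1, 1, 10), 128)), "2 channels")
})

test_that("band-pass keeps the passband and rejects the stopband (FFT oracle)", {
  fs <- 512
  t <- (0:(fs * 10 - 1)) / fs
  z <- raw_recording(matrix(0, 2, length(t)), fs)
  expect_true(all(bandpass(z, 8, 13)$signal == 0))

  fft_amp <- function(x, f) {
    n <- length(x)
    2 * Mod(fft(x)[round(f * n / fs) + 1]) / n
  }
  s10 <- raw_recording(matrix(sin(2 * pi * 10 * t), 1, length(t),
                              byrow = TRUE), fs)
  r10 <- fft_amp(bandpass(s10, 8, 13)$signal[1, ], 10) /
    fft_amp(s10$signal[1, ], 10)
  expect_gt(r10, 0.95); expect_lt(r10, 1.05)

  s50 <- raw_recording(matrix(sin(2 * pi * 50 * t), 1, length(t),
                              byrow = TRUE), fs)
  r50 <- fft_amp(bandpass(s50, 8, 13)$signal[1, ], 50) /
    fft_amp(s50$signal[1, ], 50)
  expect_lt(r50, 0.1)

  expect_error(bandpass(s10, 8, 300), "Nyquist")
})

test_that("hypnogram curation reproduces hand-computed kept sets", {
  hyp <- function(...) synth_hypnogram(list(...))
  cases <- list(
    list(h = hyp(c("N2", 10)), kept = 2:9),
    list(h = hyp(c("N2", 5), c("W", 1), c("N2", 5)), kept = integer(0)),
    list(h = hyp(c("N3", 4)), kept = integer(0)),
    list(h = hyp(c("N2", 8), c("W", 1), c("N2", 8)), kept = c(2:6, 12:16)),
    list(h = hyp(c("N2", 6)), kept = 2:5),
    list(h = hyp(c("W", 10), c("N2", 10)), kept = 12:19),
    list(h = hyp(c("N2", 10), c("W", 3), c("N2", 10)),
         kept = c(2:9, 15:22)),
    list(h = hyp(c("N2", 10), c("W", 2), c("N2", 10)),
         kept = c(2:8, 15:21)),
    list(h = hyp(c("N1", 8), c("N2", 10)), kept = 10:17),
    list(h = hyp(c("N2", 7), c("N3", 7)), kept = c(2:6, 9:13)),
    list(h = hyp(c("N2", 6), c("W", 1), c("N3", 6)), kept = integer(0)),
    list(h = hyp(c("REM", 12)), kept = 2:11),
    list(h = hyp(c("N2", 3), c("N3", 8)), kept = 5:10),
    list(h = hyp(c("N2", 8), c("W", 1), c("N3", 8)), kept = c(2:6, 12:16)),
    list(h = hyp(c("W", 1), c("N2", 8)), kept = 3:8)
  )
  for (i in seq_along(cases)) {
    expect_identical(curate_hypnogram(cases[[i]]$h), cases[[i]]$kept,
                     info = paste("case", i))
  }

  # configurable thresholds
  expect_identical(curate_hypnogram(hyp(c("N2", 12)), min_run_epochs = 4),
                   2:11)
  expect_identical(
    curate_hypnogram(hyp(c("N2", 4), c("W", 1), c("N2", 4)),
                     min_run_epochs = 4),
    integer(0)
  )
  expect_error(curate_hypnogram(character(0)), "empty")
})

test_that("curation output is a subset and never contains W or N1", {
  set.seed(17)
  for (rep in 1:25) {
    n_runs <- sample(3:10, 1)
    h <- synth_hypnogram(data.frame(
      stage = sample(c("W", "N1", "N2", "N3", "REM"), n_runs, replace = TRUE),
      n = sample(1:12, n_runs, replace = TRUE)
    ))
    kept <- curate_hypnogram(h)
    expect_true(all(kept %in% seq_along(h)))
    expect_true(all(h[kept] %in% c("REM", "N2", "N3")))
    expect_identical(kept, sort(kept))
  }
})

test_that("segmentation slices exact half-open 30 s windows", {
  fs <- 512L
  spe <- 30L * fs
  expect_identical(spe, 15360L)
  ramp <- raw_recording(matrix(seq_len(3 * spe), 1, 3 * spe, byrow = TRUE),
                        fs)
  hyp <- c("N2", "N2", "N3")
  es <- segment_epochs(ramp, hyp, kept = 3)
  expect_identical(dim(es$data), c(1L, 1L, 15360L))
  expect_equal(as.numeric(es$data[1, 1, ]),
               as.numeric((2 * spe + 1):(3 * spe)))
  expect_identical(es$labels, "N3")

  empty <- segment_epochs(ramp, hyp, kept = integer(0))
  expect_identical(length(empty), 0L)
  expect_error(segment_epochs(ramp, hyp, kept = 4), "beyond")

  # concatenating epochs recovers the raw slices exactly
  es_all <- segment_epochs(ramp, hyp, kept = 1:3)
  expect_equal(as.numeric(aperm(es_all$data, c(3, 2, 1))),
               as.numeric(ramp$signal))
})

test_that("the filter bank isolates band energy and is linear", {
  fs <- 128
  t <- (0:(fs * 30 - 1)) / fs
  x <- array(0, c(1, 2, length(t)))
  x[1, 1, ] <- sin(2 * pi * 10 * t)
  x[1, 2, ] <- sin(2 * pi * 10 * t + 1)
  es <- epoch_set(x, "N2", fs)
  fb <- filter_bank(es)
  expect_identical(names(fb), band_order())
  rms <- vapply(fb, function(b) sqrt(mean(b$data[1, 1, ]^2)), 0)
  expect_identical(names(which.max(rms)), "alpha")
  expect_true(all(rms[setdiff(band_order(), "alpha")] <= 0.1 * rms["alpha"]))

  # linearity: filter_bank(a * x) = a * filter_bank(x)
  es3 <- epoch_set(3 * x, "N2", fs)
  fb3 <- filter_bank(es3, eeg_bands()[3, ])
  expect_equal(fb3$alpha$data, 3 * fb$alpha$data, tolerance = 1e-9)

  # zero epochs pass through as zero
  z <- epoch_set(array(0, c(2, 2, fs * 30)), c("N2", "N3"), fs)
  expect_true(all(filter_bank(z, eeg_bands()[1, ])$delta$data == 0))
})

test_that("amplitude rejection flags only epochs over threshold", {
  x <- array(1, c(3, 2, 50))
  x[2, 1, 10] <- 500
  es <- epoch_set(x, c("N2", "N2", "N3"), 128)
  expect_identical(reject_amplitude(es, 100), c(TRUE, FALSE, TRUE))
  expect_identical(reject_amplitude(es), rep(TRUE, 3))
})

test_that("hypnogram files parse in both dialects with R&K mapping", {
  f1 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("W", "S2", "S3", "S4", "R", "N2"), f1)
  expect_identical(read_hypnogram(f1),
                   c("W", "N2", "N3", "N3", "REM", "N2"))

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 W", "60 N3", "30 N2"), f2)
  expect_identical(read_hypnogram(f2), c("W", "N2", "N3"))

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("XX"), f3)
  expect_error(read_hypnogram(f3), "unknown stage")
  expect_error(read_hypnogram("/nonexistent/h.txt"), "no such file")
})
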