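epo <- generateEdEpoch(nChannels = 8, preDur = 4, postDur = 4, seed = 50)

test_that("epoch boundaries match the configured structure", {
  expect_s4_class(epo, "EdEpoch")
  expect_equal(epo@edStart, 4)
  dur <- epo@edEnd - epo@edStart
  expect_gte(dur, 2 - 1 / 200)
  expect_lte(dur, 6 + 1 / 200)
  expect_equal(samplingInterval(epo@signal), 1 / 200)
  expect_identical(values(generateEdEpoch(nChannels = 8, preDur = 4,
                                          postDur = 4, seed = 50)@signal),
                   values(epo@signal))
})

test_that("discharge segments carry excess variance", {
  fs <- 200
  X <- values(epo@signal)
  pre <- X[seq_len(epo@edStart * fs - 30), ]
  ed <- X[(epo@edStart * fs + 30):(epo@edEnd * fs - 30), ]
  ratio <- apply(ed, 2, var) / apply(pre, 2, var)
  expect_true(all(ratio > 2))
})

test_that("preprocessing is a linear band-pass plus decimation chain", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  hum <- sin(2 * pi * 95 * t)                  # above the pass band
  keep <- sin(2 * pi * 10 * t)
  X <- cbind(hum + keep + 2, keep)             # channel 1 carries DC offset
  ts <- new("MultiTS", values = X, samplingInterval = 1 / fs, space = "sensor")
  out <- preprocessTS(ts, band = c(0.5, 70), fsTarget = 200)
  expect_equal(samplingInterval(out), 1 / 200)
  Y <- values(out)
  n <- nrow(Y)
  core <- 100:(n - 100)                         # ignore filter edges
  tc <- core / 200
  amp <- function(x, f) {
    fit <- lm(x ~ sin(2 * pi * f * tc) + cos(2 * pi * f * tc))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(amp(Y[core, 1], 95), 0.1)           # > 20 dB attenuation
  expect_gt(amp(Y[core, 1], 10), 0.8)           # pass band preserved
  # DC removed
  expect_lt(abs(mean(Y[core, 1])), 0.05)
  # linearity
  ts3 <- new("MultiTS", values = 3 * X, samplingInterval = 1 / fs, space = "sensor")
  expect_equal(values(preprocessTS(ts3, band = c(0.5, 70), fsTarget = 200)),
               3 * Y, tolerance = 1e-10)
  expect_error(preprocessTS(ts, band = c(0.5, 600), fsTarget = 200), "Nyquist")
})

test_that("sliding windows tile the epoch and are labelled by majority", {
  ws <- makeWindows(epo, width = 2, step = 0.5)
  w <- ws@windows
  dur <- nrow(values(epo@signal)) / 200
  expect_equal(nrow(w), floor((dur - 2) / 0.5) + 1)
  expect_true(all(w$end <= dur + 1e-9))
  expect_setequal(unique(w$label), c("preED", "ED", "postED"))
  # pre-ED windows fully inside [0, 4): starts 0 .. 2.0 seconds
  expect_equal(sum(w$end <= 4), 5)
  # majority labelling: a window centred on the onset goes to the later period
  on <- which(abs(w$start + 1 - 4) < 1e-9)     # straddles onset 50/50
  if (length(on) == 1) expect_equal(w$label[on], "ED")
  # a 10 s pre-ED period yields 17 fully contained windows at 2 s / 0.5 s
  epo10 <- generateEdEpoch(nChannels = 4, preDur = 10, postDur = 10, seed = 51)
  w10 <- makeWindows(epo10, 2, 0.5)@windows
  expect_equal(sum(w10$end <= epo10@edStart), 17)
})

test_that("time series round-trip through CSV with sidecar metadata", {
  dir <- withr::local_tempdir()
  ts <- epo@signal
  writeTimeSeries(ts, file.path(dir, "ep"), meta = list(origin = "synthetic"))
  back <- readTimeSeries(file.path(dir, "ep"))
  expect_equal(values(back), values(ts), tolerance = 1e-12)
  expect_equal(samplingInterval(back), 1 / 200)
  expect_identical(spaceTag(back), "sensor")
})
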