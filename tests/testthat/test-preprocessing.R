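test_that("despike leaves clean signals untouched and is idempotent", {
    # constant signal: IQR 0, strict threshold flags nothing
    const <- NeuralRecording(matrix(5, 1, 100), 100)
    expect_identical(signalMatrix(despike(const)), signalMatrix(const))

    set.seed(1)
    sig <- matrix(rnorm(2 * 2000), 2, 2000)
    sig[1, c(300, 1200)] <- c(40, -35)       # planted spikes
    rec <- NeuralRecording(sig, 256)
    out <- despike(rec)
    # independent re-implementation of the threshold rule
    flagged <- abs(sig[1, ] - median(sig[1, ])) >
        4 * IQR(sig[1, ])
    expect_true(all(flagged[c(300, 1200)]))
    expect_equal(signalMatrix(out)[1, !flagged], sig[1, !flagged])
    expect_false(any(signalMatrix(out)[1, c(300, 1200)] ==
                     sig[1, c(300, 1200)]))
    # idempotence: a second pass changes nothing
    expect_equal(signalMatrix(despike(out)), signalMatrix(out))
})

test_that("despike corrects a single spike in a smooth signal", {
    t <- seq(0, 4, length.out = 1000)
    x <- sin(2 * pi * t)
    x[500] <- 50
    rec <- NeuralRecording(matrix(x, 1), 250)
    out <- signalMatrix(despike(rec))[1, ]
    expect_lt(abs(out[500] - sin(2 * pi * t[500])), 0.05)
    expect_equal(out[-500], x[-500])
})

test_that("despike flags mostly-imputed electrodes as suspect", {
    # with a tight threshold most of a heavy-tailed signal is flagged
    set.seed(2)
    x <- runif(400, -1, 1)
    rec <- NeuralRecording(rbind(x, rep(0.5, 400)), 100)
    expect_warning(out <- despike(rec, k = 0.1), "suspect")
    expect_true(out@suspect[1])
    expect_false(out@suspect[2])
})

test_that("common average referencing zeroes the electrode mean", {
    rec <- tinyRecording(4)
    out <- rereferenceCAR(rec)
    expect_lt(max(abs(colMeans(signalMatrix(out)))), 1e-12)
    # identical electrodes become all-zero
    same <- NeuralRecording(rbind(sin(1:100), sin(1:100)), 100)
    expect_equal(signalMatrix(rereferenceCAR(same)),
                 matrix(0, 2, 100), ignore_attr = TRUE)
    # adding a constant to all electrodes leaves the output unchanged
    shifted <- rec
    shifted@signal <- signalMatrix(rec) + 7
    expect_equal(signalMatrix(rereferenceCAR(shifted)),
                 signalMatrix(out))
    expect_error(rereferenceCAR(NeuralRecording(matrix(1., 1, 50), 100)),
                 "2 electrodes")
})

test_that("high-gamma power is band-selective and excludes line noise", {
    fs <- 512
    t <- seq_len(4 * fs) / fs
    tone <- function(f) sin(2 * pi * f * t)
    rec <- NeuralRecording(rbind(tone(100), tone(30), tone(120),
                                 tone(110), 0 * t), fs)
    pow <- signalMatrix(highGammaPower(rec))
    core <- (fs):(3 * fs)                        # avoid edges
    m <- rowMeans(pow[, core])
    expect_gt(m[1] / m[2], 1000)                 # in-band vs out-of-band
    # 6-cycle wavelets are spectrally broad, so line exclusion only
    # attenuates a 120 Hz tone relative to a neighboring 110 Hz tone
    expect_gt(m[4], m[3])
    # with a fine grid and narrowband wavelets the excluded line is
    # suppressed to near zero relative to the neighboring tone
    mNarrow <- rowMeans(signalMatrix(
        highGammaPower(rec, nCycles = 60, nFreqs = 40))[, core])
    expect_gt(mNarrow[4] / mNarrow[3], 20)
    expect_equal(m[5], 0)                        # zero signal, zero power
    # invariance to DC offset (away from the recording edges)
    recDC <- rec; recDC@signal <- rec@signal + 5
    expect_equal(signalMatrix(highGammaPower(recDC))[, core],
                 pow[, core], tolerance = 1e-8)
    expect_error(highGammaPower(NeuralRecording(matrix(rnorm(300), 1),
                                                300)),
                 "samplingRateTooLow")
})

test_that("Hamming smoothing is normalized, local and variance-reducing", {
    fs <- 200
    const <- NeuralRecording(matrix(3, 1, 400), fs)
    expect_equal(signalMatrix(smoothHamming(const)),
                 signalMatrix(const), tolerance = 1e-12)
    # unit impulse reproduces the normalized kernel
    x <- numeric(401); x[201] <- 1
    out <- signalMatrix(smoothHamming(NeuralRecording(matrix(x, 1), fs),
                                      kernelMs = 50))[1, ]
    m <- round(50 / 1000 * fs)
    k <- 0.54 - 0.46 * cos(2 * pi * seq(0, m - 1) / (m - 1))
    k <- k / sum(k)
    half <- (m - 1) %/% 2
    expect_equal(out[(201 - half):(201 - half + m - 1)], k,
                 tolerance = 1e-12)
    expect_equal(sum(out), 1, tolerance = 1e-12)
    # white noise contracts in variance
    set.seed(3)
    noise <- NeuralRecording(matrix(rnorm(4000), 1), fs)
    expect_lt(var(signalMatrix(smoothHamming(noise))[1, ]),
              var(signalMatrix(noise)[1, ]))
    expect_error(smoothHamming(noise, kernelMs = 0), "positive")
})
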