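test_that("orthogonalization removes the reference per word", {
    set.seed(20)
    X <- matrix(rnorm(30 * 8), 30, 8)
    M <- matrix(rnorm(30 * 8), 30, 8)
    out <- orthogonalizeLayer(X, M)
    expect_lt(max(abs(rowSums(out * M))), 1e-10)
    # projecting the reference from itself leaves zero rows
    self <- orthogonalizeLayer(M, M)
    expect_lt(max(abs(self)), 1e-10)
    # an already-orthogonal layer passes through unchanged
    ortho <- out
    expect_equal(orthogonalizeLayer(ortho, M), ortho, tolerance = 1e-10)
    # zero-norm reference rows pass the input through with a warning
    M0 <- M; M0[3, ] <- 0
    expect_warning(out0 <- orthogonalizeLayer(X, M0), "zero-norm")
    expect_equal(out0[3, ], X[3, ])
})

test_that("phase randomization preserves the amplitude spectrum", {
    set.seed(21)
    x <- as.numeric(arima.sim(list(ar = 0.8), 512))
    y <- phaseRandomize(x, seed = 1)
    expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-8)
    expect_true(is.numeric(y) && !is.complex(y))
    # Wiener-Khinchin: autocorrelation is preserved with the spectrum
    acfX <- acf(x, lag.max = 20, plot = FALSE)$acf
    acfY <- acf(y, lag.max = 20, plot = FALSE)$acf
    expect_lt(max(abs(acfX - acfY)), 0.15)
    # constant signal: only the DC component, unchanged
    cst <- rep(3, 64)
    expect_equal(phaseRandomize(cst, seed = 2), cst, tolerance = 1e-12)
    expect_error(phaseRandomize(1:4), "8 samples")
    # seeded reproducibility
    expect_identical(phaseRandomize(x, seed = 9),
                     phaseRandomize(x, seed = 9))
})

test_that("electrode selection finds planted electrodes and spares noise", {
    # electrodes 1-2 driven by the embedding, 3-6 pure noise
    cfg <- SyntheticConfig(nWords = 150, nLayers = 2, embedDim = 16,
                           nElectrodes = 2, samplingRate = 128,
                           wordSpacing = 350, lagMap = c(100, 100),
                           snr = 3, padding = 800, seed = 23)
    ds <- generateNeuralDataset(cfg)
    rec <- syntheticRecording(ds)
    set.seed(24)
    noise <- matrix(rnorm(4 * nSamples(rec), sd = sd(signalMatrix(rec))),
                    4)
    rec2 <- NeuralRecording(rbind(signalMatrix(rec), noise), 128)
    static <- layerMatrix(syntheticEmbeddings(ds), 1)
    sel <- selectElectrodes(rec2, syntheticEvents(ds), static,
                            EncodingConfig(-300, 300, 50, pcaK = 10,
                                           nFolds = 5),
                            nPerm = 500, qThreshold = 0.01, seed = 25)
    expect_true(all(selectedElectrodes(sel)[1:2]))
    expect_false(any(selectedElectrodes(sel)[3:6]))
    expect_length(nullDistribution(sel), 500)
    # identical electrodes get identical p-values
    rec3 <- NeuralRecording(rbind(signalMatrix(rec)[1, ],
                                  signalMatrix(rec)[1, ]), 128)
    sel3 <- selectElectrodes(rec3, syntheticEvents(ds), static,
                             EncodingConfig(-300, 300, 100, pcaK = 10,
                                            nFolds = 5),
                             nPerm = 120, seed = 26)
    expect_equal(selectionPValues(sel3)[1], selectionPValues(sel3)[2])
})

test_that("interpolation control separates chain from interpolated data", {
    mkData <- function(regime, seed) {
        cfg <- SyntheticConfig(nWords = 300, nLayers = 12, embedDim = 24,
                               nElectrodes = 2, samplingRate = 256,
                               snr = 2, lagMap = function(l) 50 * (l - 1),
                               nonlinearity = regime, padding = 1300,
                               seed = seed)
        generateNeuralDataset(cfg)
    }
    ec <- EncodingConfig(-700, 700, 50, pcaK = 16)
    dsChain <- mkData("chain_nonlinear", 27)
    ctlChain <- interpolationControl(syntheticRecording(dsChain),
                                     syntheticEvents(dsChain),
                                     syntheticEmbeddings(dsChain), ec,
                                     nPool = 120, iterations = 400,
                                     seed = 28)
    expect_lte(ctlChain$p, 0.01)
    # under genuinely interpolated data the observed correlation is
    # typical of the null
    ps <- vapply(c(29, 30), function(s) {
        dsI <- mkData("linear_interp", s)
        interpolationControl(syntheticRecording(dsI),
                             syntheticEvents(dsI),
                             syntheticEmbeddings(dsI), ec,
                             nPool = 120, iterations = 200,
                             seed = s + 100)$p
    }, numeric(1))
    expect_gt(max(ps), 0.05)
    expect_gt(min(ps), 0.01)
})

test_that("interpolation control edge cases behave", {
    cfg <- quickConfig(seed = 31)
    ds <- generateNeuralDataset(cfg)
    ec <- EncodingConfig(-300, 300, 100, pcaK = 10)
    expect_error(interpolationControl(syntheticRecording(ds),
                                      syntheticEvents(ds),
                                      syntheticEmbeddings(ds), ec,
                                      nPool = 3, nPseudo = 6),
                 "smaller than")
    one <- interpolationControl(syntheticRecording(ds),
                                syntheticEvents(ds),
                                syntheticEmbeddings(ds), ec,
                                nPool = 10, nPseudo = 6, iterations = 1,
                                seed = 32)
    expect_true(one$p %in% c(0.5, 1))
})
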