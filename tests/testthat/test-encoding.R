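test_that("lag grid is the inclusive arithmetic sequence", {
    expect_length(buildLagGrid(EncodingConfig()), 161)
    expect_equal(buildLagGrid(EncodingConfig(0, 0, 25)), 0)
    expect_equal(buildLagGrid(EncodingConfig(-100, 100, 50)),
                 c(-100, -50, 0, 50, 100))
    expect_error(EncodingConfig(-100, 100, 30), "divisible")
})

test_that("lagged responses average the right window", {
    fs <- 200
    ev <- WordEventTable(onset = c(500, 1000, 1500))
    const <- NeuralRecording(matrix(2.5, 1, 2000), fs)
    expect_equal(laggedResponse(const, ev, 1, 100), rep(2.5, 3))
    # ramp a*t: windowed mean = a*(onset + lag) within half a sample
    a <- 0.01
    t_ms <- (seq_len(4000) - 1) / fs * 1000
    ramp <- NeuralRecording(matrix(a * t_ms, 1), fs)
    for (lag in c(-200, 0, 375)) {
        got <- laggedResponse(ramp, ev, 1, lag)
        expect_equal(got, a * (onsets(ev) + lag),
                     tolerance = a * (1000 / fs) / 2)
    }
    # a lag beyond the recording end flags the word missing; with half
    # the words missing that exceeds the 5% budget and errors
    evEdge <- WordEventTable(onset = c(500, 19900))
    expect_error(laggedResponse(ramp, evEdge, 1, 300), "outside")
})

test_that("batch response cube agrees with the single-lag operation", {
    rec <- tinyRecording(3, 3000, 256)
    ev <- WordEventTable(onset = seq(1000, 9000, by = 400))
    lags <- c(-500, -100, 0, 250)
    cube <- lagLayer:::.laggedResponseCube(rec, ev, lags, 200)
    for (e in 1:3) for (j in seq_along(lags)) {
        expect_equal(cube[, e, j],
                     laggedResponse(rec, ev, e, lags[j], 200),
                     tolerance = 1e-12)
    }
})

test_that("cross-validated OLS recovers realizable targets", {
    set.seed(10)
    X <- matrix(rnorm(200 * 5), 200, 5)
    beta <- rnorm(5)
    y <- drop(X %*% beta) + 2
    folds <- makeFolds(200, 10)
    fit <- fitEncodingCV(X, y, folds)
    expect_equal(fit$correlation, 1, tolerance = 1e-8)
    expect_false(anyNA(fit$predictions))
})

test_that("cross-validated correlation is near zero for unrelated noise", {
    hits <- vapply(1:20, function(s) {
        set.seed(s)
        X <- matrix(rnorm(1000 * 5), 1000, 5)
        y <- rnorm(1000)
        abs(fitEncodingCV(X, y, makeFolds(1000, 10))$correlation) < 0.1
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("pooled CV correlation matches a normal-equation oracle", {
    set.seed(11)
    X <- matrix(rnorm(45 * 3), 45, 3)
    y <- X[, 1] + rnorm(45, sd = 0.5)
    folds <- makeFolds(45, 5)
    fit <- fitEncodingCV(X, y, folds)
    # independent oracle: explicit normal equations per fold
    pred <- numeric(45)
    for (f in unique(folds)) {
        tr <- folds != f
        Xtr <- cbind(1, X[tr, ]); Xte <- cbind(1, X[!tr, ])
        beta <- solve(t(Xtr) %*% Xtr, t(Xtr) %*% y[tr])
        pred[!tr] <- Xte %*% beta
    }
    expect_equal(fit$correlation, cor(pred, y), tolerance = 1e-10)
    expect_equal(fit$predictions, pred, tolerance = 1e-10)
})

test_that("fold structure never leaks test words into training", {
    folds <- makeFolds(100, 10)
    expect_equal(sort(unique(folds)), 0:9)
    expect_true(all(table(folds) == 10))
    # every word predicted exactly once
    set.seed(12)
    fit <- fitEncodingCV(matrix(rnorm(300), 100, 3), rnorm(100), folds)
    expect_equal(sum(!is.na(fit$predictions)), 100)
    # random folds partition too
    rf <- makeFolds(100, 10, method = "random", seed = 3)
    expect_equal(sort(table(rf)), sort(table(folds)), ignore_attr = TRUE)
})

test_that("rank-deficient designs fall back to minimum norm with warning", {
    set.seed(13)
    X <- matrix(rnorm(60 * 2), 60, 2)
    X <- cbind(X, X[, 1] + X[, 2])               # exact collinearity
    y <- rnorm(60)
    w <- capture_warnings(fit <- fitEncodingCV(X, y, makeFolds(60, 5)))
    expect_true(length(w) >= 1 && all(grepl("rank-deficient", w)))
    expect_true(is.finite(fit$correlation))
})

test_that("the encoding tensor has the right shape and symmetry", {
    cfg <- quickConfig(seed = 31)
    ds <- generateNeuralDataset(cfg)
    rec <- syntheticRecording(ds)
    # duplicate an electrode: identical slices must come out
    sig <- signalMatrix(rec)
    rec2 <- NeuralRecording(rbind(sig, sig[1, ]), samplingRate(rec),
                            roiLabels = c(roiLabels(rec), "DUP"))
    ec <- EncodingConfig(lagMin = -300, lagMax = 300, lagStep = 100,
                         pcaK = 10)
    tens <- encodeLayerwise(rec2, syntheticEvents(ds),
                            syntheticEmbeddings(ds), ec)
    expect_equal(dim(tensorValues(tens)), c(3L, 8L, 7L))
    expect_equal(tensorValues(tens)[3, , ], tensorValues(tens)[1, , ],
                 tolerance = 1e-12)
    expect_true(all(abs(tensorValues(tens)) <= 1 + 1e-12))
})

test_that("planted peak lags are recovered within one lag step", {
    # each electrode carries one designated layer: its peak must sit at
    # the planted lag (+/- one 25 ms step) for at least 90% of layers
    L <- 8
    cfg <- SyntheticConfig(nWords = 250, nLayers = L, embedDim = 24,
                           nElectrodes = L, samplingRate = 256, snr = 2,
                           lagMap = function(l) 75 * (l - 1),
                           designatedLayers = as.list(seq_len(L)),
                           padding = 1300, seed = 11)
    ds <- generateNeuralDataset(cfg)
    tens <- encodeLayerwise(syntheticRecording(ds), syntheticEvents(ds),
                            syntheticEmbeddings(ds),
                            EncodingConfig(-750, 750, 25, pcaK = 20))
    v <- tensorValues(tens); lags <- lagGrid(tens)
    err <- vapply(seq_len(L), function(l)
        abs(lags[which.max(v[l, l, ])] - syntheticTruth(ds)$lagMap[l]),
        numeric(1))
    expect_gte(mean(err <= 25), 0.9)
})

test_that("ROI averaging matches a brute-force loop", {
    set.seed(14)
    v <- array(runif(4 * 3 * 5, -1, 1), c(4, 3, 5))
    tens <- new("EncodingTensor", values = v, lags = seq(-50, 50, 25),
                layerIds = 1:3, electrodeIds = paste0("e", 1:4),
                roiLabels = c("A", "B", "A", "A"))
    got <- averageOverElectrodes(tens, "A")
    want <- matrix(0, 3, 5)
    for (l in 1:3) for (g in 1:5)
        want[l, g] <- mean(v[c(1, 3, 4), l, g])
    expect_equal(got, want, ignore_attr = TRUE)
    # single-electrode ROI returns the slice unchanged
    expect_equal(averageOverElectrodes(tens, "B"), v[2, , ],
                 ignore_attr = TRUE)
    # opposite values cancel
    tens2 <- tens
    tens2@values[1, , ] <- 1; tens2@values[3, , ] <- -1
    tens2@values[4, , ] <- 0
    expect_equal(averageOverElectrodes(tens2, "A"),
                 matrix(0, 3, 5), ignore_attr = TRUE)
    expect_error(averageOverElectrodes(tens, "Z"), "no electrodes")
})

test_that("row scaling normalizes peaks to 1 and preserves argmax", {
    m <- rbind(c(0.1, 0.2, 0.4), c(0.5, 1, 0.25))
    s <- scaleRows(m)
    expect_equal(s[1, ], c(0.25, 0.5, 1), ignore_attr = TRUE)
    expect_equal(s[2, ], c(0.5, 1, 0.25), ignore_attr = TRUE)
    set.seed(15)
    r <- matrix(runif(60, 0.01, 1), 6, 10)
    expect_equal(apply(scaleRows(r), 1, which.max),
                 apply(r, 1, which.max))
    expect_true(all(apply(scaleRows(r), 1, max) == 1))
    # non-positive rows are flagged and excluded
    expect_warning(s2 <- scaleRows(rbind(c(-1, -2, -0.5), c(1, 2, 4))),
                   "non-positive")
    expect_true(all(is.na(s2[1, ])))
    expect_equal(attr(s2, "excludedRows"), 1L)
})
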