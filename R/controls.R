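#' @include AllClasses.R encoding.R stats.R
NULL

#' Remove a reference layer's information from another layer
#'
#' For each word, projects the layer embedding onto the reference
#' (best-performing) layer's embedding for the same word and subtracts
#' the projection, leaving a per-word component orthogonal to the
#' reference. Projecting the reference onto itself yields zero rows,
#' which verifies the removal.
#'
#' @param layerEmbs Numeric words x dims matrix.
#' @param referenceEmbs Numeric words x dims matrix over the same words.
#' @return Numeric words x dims matrix; every row has zero inner product
#'   with the corresponding reference row. Zero-norm reference rows pass
#'   the input row through with a warning.
#' @export
orthogonalizeLayer <- function(layerEmbs, referenceEmbs) {
    layerEmbs <- as.matrix(layerEmbs)
    referenceEmbs <- as.matrix(referenceEmbs)
    if (!all(dim(layerEmbs) == dim(referenceEmbs)))
        stop("layer and reference must have matching words x dims")
    nrm <- rowSums(referenceEmbs^2)
    zero <- nrm == 0
    if (any(zero)) {
        warning(sum(zero), " zero-norm reference row(s); passed through")
        nrm[zero] <- 1
    }
    coef <- rowSums(layerEmbs * referenceEmbs) / nrm
    coef[zero] <- 0
    layerEmbs - coef * referenceEmbs
}

#' Phase-randomized surrogate signal
#'
#' Replaces the phases of the independent Fourier components with
#' Uniform(0, 2*pi) draws (conjugate-symmetric, DC and Nyquist
#' untouched), preserving the amplitude spectrum — and hence the
#' autocorrelation — while destroying the temporal alignment to events.
#'
#' @param x Numeric vector with at least 8 samples.
#' @param seed Optional RNG seed.
#' @return Real-valued surrogate of the same length.
#' @export
phaseRandomize <- function(x, seed = NULL) {
    n <- length(x)
    if (n < 8L) stop("need at least 8 samples")
    if (!is.null(seed)) set.seed(seed)
    X <- fft(x)
    half <- (n - 1L) %/% 2L                  # independent components
    if (half > 0L) {
        ph <- runif(half, 0, 2 * pi)
        idx <- 2L:(half + 1L)
        X[idx] <- Mod(X[idx]) * exp(1i * ph)
        X[n + 2L - idx] <- Conj(X[idx])
    }
    Re(fft(X, inverse = TRUE)) / n
}

#' Select task-responsive electrodes by phase-randomization
#'
#' Observed statistic per electrode: the encoding model's maximal
#' correlation across all lags, using static (single-layer) embeddings.
#' Null: on each permutation every electrode's signal is
#' phase-randomized, the max-over-lags statistic is recomputed, and the
#' maximum across electrodes retained, yielding one null value per
#' permutation (a familywise-style null). Per-electrode p-values are
#' add-one percentiles of the observed statistic in that null;
#' Benjamini-Hochberg q-values below `qThreshold` mark selected
#' electrodes.
#'
#' @param recording A [NeuralRecording-class].
#' @param events A [WordEventTable-class].
#' @param staticEmb Numeric words x dims matrix of static embeddings.
#' @param config An [EncodingConfig-class]; its `pcaK` is applied to
#'   `staticEmb` only when the embedding has more columns than `pcaK`.
#' @param nPerm Number of permutations (default 5000; fewer than 100
#'   triggers a warning).
#' @param qThreshold FDR threshold (default 0.01).
#' @param seed Optional RNG seed.
#' @return An [ElectrodeSelectionResult-class].
#' @export
selectElectrodes <- function(recording, events, staticEmb,
                             config = EncodingConfig(), nPerm = 5000,
                             qThreshold = 0.01, seed = NULL) {
    stopifnot(is(recording, "NeuralRecording"),
              is(events, "WordEventTable"))
    validObject(config)
    if (nPerm < 100) warning("fewer than 100 permutations")
    if (!is.null(seed)) set.seed(seed)
    staticEmb <- as.matrix(staticEmb)
    n <- nWords(events)
    stopifnot(nrow(staticEmb) == n)
    lags <- lagGrid(config)
    E <- nElectrodes(recording)
    folds <- foldIds(events)
    if (all(is.na(folds)))
        folds <- makeFolds(n, config@nFolds, config@foldMethod)

    ## the design does not depend on lag, electrode or permutation:
    ## prefactor one QR per fold and reuse it for every response column
    k <- min(config@pcaK, ncol(staticEmb))
    designs <- lapply(sort(unique(folds)), function(f) {
        te <- which(folds == f); tr <- which(folds != f)
        if (ncol(staticEmb) > config@pcaK) {
            pr <- .pcaProject(staticEmb[tr, , drop = FALSE],
                              list(staticEmb[tr, , drop = FALSE],
                                   staticEmb[te, , drop = FALSE]), k)
            Xtr <- cbind(1, pr[[1L]]); Xte <- cbind(1, pr[[2L]])
        } else {
            Xtr <- cbind(1, staticEmb[tr, , drop = FALSE])
            Xte <- cbind(1, staticEmb[te, , drop = FALSE])
        }
        if (length(tr) <= ncol(Xtr)) stop("training fold too small")
        list(tr = tr, te = te, qr = qr(Xtr), Xte = Xte)
    })
    maxOverLags <- function(rec) {
        Y <- .laggedResponseCube(rec, events, lags, config@window)
        dim(Y) <- c(n, E * length(lags))
        pred <- matrix(NA_real_, n, ncol(Y))
        for (d in designs)
            pred[d$te, ] <- d$Xte %*% qr.coef(d$qr, Y[d$tr, , drop = FALSE])
        r <- .colCor(pred, Y)
        apply(matrix(r, E, length(lags)), 1L, max, na.rm = TRUE)
    }
    observed <- maxOverLags(recording)
    sig <- signalMatrix(recording)
    nullMax <- vapply(seq_len(nPerm), function(b) {
        surro <- recording
        surro@signal <- t(apply(sig, 1L, phaseRandomize))
        max(maxOverLags(surro))
    }, numeric(1))
    p <- vapply(observed, function(o) (1 + sum(nullMax >= o)) / (nPerm + 1),
                numeric(1))
    fdr <- bhFdr(p, qThreshold)
    new("ElectrodeSelectionResult", observed = observed, nullMax = nullMax,
        pValues = p, qValues = fdr$qValues, selected = fdr$reject,
        qThreshold = qThreshold, electrodeIds = electrodeIds(recording))
}

#' Interpolation control for the lag-layer correlation
#'
#' Tests whether the observed lag-layer correlation could be produced by
#' mere linear interpolation between the first and last layers'
#' embeddings. A pool of `nPool` interpolated embedding sets (uniform
#' random weights between the first and last layer) is encoded once;
#' then, per iteration, `nPseudo` pool members are sampled without
#' replacement, sorted by interpolation weight, framed by the real first
#' and last layers, and the lag-layer Pearson correlation of this
#' pseudo-layer stack is computed. The add-one fraction of iterations
#' whose correlation reaches the observed one is the p-value.
#'
#' @param recording A [NeuralRecording-class].
#' @param events A [WordEventTable-class].
#' @param embeddings The full [LayeredEmbeddingSet-class] (its first and
#'   last layers anchor the interpolation; its observed lag-layer
#'   correlation is the test statistic).
#' @param config An [EncodingConfig-class].
#' @param nPool Size of the interpolation pool (default 1000); must be
#'   at least `nPseudo`.
#' @param nPseudo Number of intermediate pseudo-layers per iteration
#'   (default `nLayers(embeddings) - 2`, mirroring the real layer
#'   count).
#' @param iterations Number of resampling iterations (default 10000).
#' @param seed Optional RNG seed.
#' @param roi Optional ROI restriction for electrode averaging.
#' @param chunkSize Pool members encoded per block (memory knob).
#' @return List with `p`, `observed` (the real stack's lag-layer
#'   Pearson r), `nullR` (per-iteration correlations), `poolPeakLags`
#'   and `poolWeights`.
#' @export
interpolationControl <- function(recording, events, embeddings,
                                 config = EncodingConfig(), nPool = 1000,
                                 nPseudo = nLayers(embeddings) - 2L,
                                 iterations = 10000, seed = NULL,
                                 roi = NULL, chunkSize = 50L) {
    stopifnot(is(embeddings, "LayeredEmbeddingSet"))
    validObject(config)
    if (nPool < nPseudo)
        stop("interpolation pool (", nPool, ") smaller than nPseudo (",
             nPseudo, ")")
    if (iterations < 1) stop("iterations must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    n <- nWords(events)
    lags <- lagGrid(config)
    E <- nElectrodes(recording)
    folds <- foldIds(events)
    if (all(is.na(folds)))
        folds <- makeFolds(n, config@nFolds, config@foldMethod)
    roiSel <- if (is.null(roi)) seq_len(E) else
        which(roiLabels(recording) == roi)
    if (!length(roiSel)) stop("no electrodes carry ROI label '", roi, "'")

    ## observed statistic from the real layer stack
    tens <- encodeLayerwise(recording, events, embeddings, config)
    obsMat <- averageOverElectrodes(tens, roi)
    obsPeaks <- peakLags(obsMat, lags)
    obs <- lagLayerCorrelation(obsPeaks)$pearson

    ## encode the interpolation pool once; peak lag per pool member
    first <- layerMatrix(embeddings, layerIds(embeddings)[1L])
    last <- layerMatrix(embeddings,
                        layerIds(embeddings)[nLayers(embeddings)])
    w <- runif(nPool)
    Y <- .laggedResponseCube(recording, events, lags, config@window)
    dim(Y) <- c(n, E * length(lags))
    poolPeaks <- numeric(nPool)
    for (start in seq(1L, nPool, by = chunkSize)) {
        idx <- start:min(start + chunkSize - 1L, nPool)
        mats <- lapply(w[idx], function(wi) (1 - wi) * first + wi * last)
        vals <- .encodeCore(Y, folds, mats, config, E, length(lags))
        avg <- colMeans(vals[roiSel, , , drop = FALSE], dims = 1L)
        poolPeaks[idx] <- peakLags(avg, lags)
    }

    firstPeak <- obsPeaks[1L]
    lastPeak <- obsPeaks[length(obsPeaks)]
    idxStack <- seq_len(nPseudo + 2L)
    nullR <- vapply(seq_len(iterations), function(i) {
        pick <- sample.int(nPool, nPseudo)
        ord <- pick[order(w[pick])]       # sorted by interpolation weight
        stack <- c(firstPeak, poolPeaks[ord], lastPeak)
        if (sd(stack) == 0) return(0)
        cor(idxStack, stack)
    }, numeric(1))
    p <- (1 + sum(nullR >= obs - 1e-12)) / (iterations + 1)
    list(p = p, observed = obs, nullR = nullR, poolPeakLags = poolPeaks,
         poolWeights = w)
}
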