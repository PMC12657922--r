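#' @include AllClasses.R
NULL

#' Build the lag grid
#'
#' Inclusive arithmetic sequence from `lagMin` to `lagMax` in `lagStep`
#' increments; the default configuration (-2000..2000 ms, 25 ms steps)
#' yields 161 lags.
#'
#' @param config An [EncodingConfig-class].
#' @return Numeric vector of lags in ms.
#' @export
buildLagGrid <- function(config) {
    stopifnot(is(config, "EncodingConfig"))
    validObject(config)
    lagGrid(config)
}

## Sample-index window [lo, hi] (0-based, inclusive) for each word at one
## lag: samples whose center times fall in the closed window
## [onset + lag - w/2, onset + lag + w/2].
.windowBounds <- function(onset, lag, window, fs) {
    lo <- ceiling((onset + lag - window / 2) * fs / 1000 - 1e-9)
    hi <- floor((onset + lag + window / 2) * fs / 1000 + 1e-9)
    list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Windowed neural response per word at one lag
#'
#' For each word, the mean of the samples whose center times fall in the
#' closed window `[onset + lag - window/2, onset + lag + window/2]`.
#' Words whose window falls outside the recording are flagged missing
#' (NA); more than 5% missing is an error.
#'
#' @param recording A [NeuralRecording-class].
#' @param events A [WordEventTable-class].
#' @param electrode Electrode index or id.
#' @param lag Lag in ms (positive = after word onset; 0 = onset).
#' @param window Window width in ms (default 200).
#' @return Numeric vector, one response per word (NA = missing).
#' @export
laggedResponse <- function(recording, events, electrode, lag,
                           window = 200) {
    stopifnot(is(recording, "NeuralRecording"),
              is(events, "WordEventTable"))
    if (is.character(electrode))
        electrode <- match(electrode, electrodeIds(recording))
    x <- signalMatrix(recording)[electrode, ]
    fs <- samplingRate(recording)
    b <- .windowBounds(onsets(events), lag, window, fs)
    n <- nWords(events)
    out <- rep(NA_real_, n)
    ok <- b$lo >= 0L & b$hi <= length(x) - 1L & b$hi >= b$lo
    for (i in which(ok))
        out[i] <- mean(x[(b$lo[i] + 1L):(b$hi[i] + 1L)])
    if (mean(!ok) > 0.05)
        stop("more than 5% of word windows fall outside the recording ",
             "at lag ", lag, " ms")
    out
}

## All (word x electrode x lag) windowed responses at once, via per-
## electrode cumulative sums. Returns list(values = 3-d array, any NA
## where missing).
.laggedResponseCube <- function(recording, events, lags, window) {
    sig <- signalMatrix(recording)
    fs <- samplingRate(recording)
    ns <- ncol(sig)
    E <- nrow(sig)
    onset <- onsets(events)
    n <- length(onset)
    cs <- apply(sig, 1L, cumsum)                  # samples x electrodes
    cs <- rbind(0, cs)                            # prepend zero row
    out <- array(NA_real_, c(n, E, length(lags)))
    for (j in seq_along(lags)) {
        b <- .windowBounds(onset, lags[j], window, fs)
        ok <- b$lo >= 0L & b$hi <= ns - 1L & b$hi >= b$lo
        if (mean(!ok) > 0.05)
            stop("more than 5% of word windows fall outside the ",
                 "recording at lag ", lags[j], " ms")
        m <- b$hi - b$lo + 1L
        sums <- cs[b$hi[ok] + 2L, , drop = FALSE] -
                cs[b$lo[ok] + 1L, , drop = FALSE]
        out[ok, , j] <- sums / m[ok]
    }
    out
}

#' Assign cross-validation folds
#'
#' @param n Number of words.
#' @param nFolds Number of folds (default 10).
#' @param method `"contiguous"` blocks (default; reduces temporal
#'   leakage between neighboring words) or `"random"`.
#' @param seed Optional seed for `method = "random"`.
#' @return Integer vector of fold ids `0:(nFolds - 1)`, one per word.
#' @export
makeFolds <- function(n, nFolds = 10, method = c("contiguous", "random"),
                      seed = NULL) {
    method <- match.arg(method)
    if (nFolds < 2L) stop("nFolds must be >= 2")
    if (nFolds > n) stop("more folds than words")
    ids <- as.integer(cut(seq_len(n), breaks = nFolds, labels = FALSE)) - 1L
    if (method == "random") {
        if (!is.null(seed)) set.seed(seed)
        ids <- sample(ids)
    }
    ids
}

## least-squares coefficients with a minimum-norm fallback for rank-
## deficient designs (warning). X includes the intercept column.
.lsFit <- function(X, Y) {
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
        warning("rank-deficient design; using minimum-norm solution")
        sv <- svd(X)
        pos <- sv$d > max(sv$d) * 1e-10
        return(sv$v[, pos, drop = FALSE] %*%
               ((crossprod(sv$u[, pos, drop = FALSE], Y)) / sv$d[pos]))
    }
    qr.coef(qx, Y)
}

#' Cross-validated ordinary-least-squares encoding fit
#'
#' For each fold, an OLS model with intercept is estimated on the
#' training rows and its predictions written for the held-out rows;
#' after all folds, performance is the single Pearson correlation
#' between the pooled out-of-fold predictions and the observed
#' responses (not an average of per-fold correlations).
#'
#' @param X Numeric design matrix, words x predictors (no intercept
#'   column; one is added).
#' @param y Numeric response vector.
#' @param folds Integer fold ids (0-based, as from [makeFolds()]), one
#'   per word.
#' @return List with `correlation` (scalar) and `predictions`
#'   (out-of-fold prediction per word).
#' @export
fitEncodingCV <- function(X, y, folds) {
    X <- as.matrix(X)
    y <- as.numeric(y)
    n <- nrow(X)
    stopifnot(length(y) == n, length(folds) == n)
    pred <- rep(NA_real_, n)
    for (f in unique(folds)) {
        te <- which(folds == f)
        tr <- which(folds != f)
        if (length(tr) <= ncol(X) + 1L)
            stop("training fold too small: ", length(tr), " words for ",
                 ncol(X), " predictors")
        beta <- .lsFit(cbind(1, X[tr, , drop = FALSE]), y[tr])
        pred[te] <- cbind(1, X[te, , drop = FALSE]) %*% beta
    }
    list(correlation = cor(pred, y), predictions = pred)
}

## Pearson correlation of each column of A with matching column of B.
.colCor <- function(A, B) {
    A <- sweep(A, 2L, colMeans(A), "-")
    B <- sweep(B, 2L, colMeans(B), "-")
    num <- colSums(A * B)
    den <- sqrt(colSums(A^2) * colSums(B^2))
    r <- num / den
    r[den == 0] <- NA_real_
    r
}

## Shared inner loop of the lag-resolved encoding analysis: for each
## words x dims design in `layers`, cross-validated OLS against every
## column of Y (words x (E * nLags) responses), pooled out-of-fold
## correlation per column. Returns an E x length(layers) x nLags array.
.encodeCore <- function(Y, folds, layers, config, E, nLags) {
    n <- nrow(Y)
    anyMissing <- anyNA(Y)
    k <- config@pcaK
    vals <- array(NA_real_, c(E, length(layers), nLags))
    pred <- matrix(NA_real_, n, ncol(Y))
    ufolds <- unique(folds)
    for (l in seq_along(layers)) {
        emb <- layers[[l]]
        if (config@pcaDialect == "pooled")
            embPooled <- .pcaProject(emb, list(emb), k)[[1L]]
        for (f in ufolds) {
            te <- which(folds == f)
            tr <- which(folds != f)
            if (config@pcaDialect == "fold_safe") {
                pr <- .pcaProject(emb[tr, , drop = FALSE],
                                  list(emb[tr, , drop = FALSE],
                                       emb[te, , drop = FALSE]), k)
                Xtr <- cbind(1, pr[[1L]])
                Xte <- cbind(1, pr[[2L]])
            } else {
                Xtr <- cbind(1, embPooled[tr, , drop = FALSE])
                Xte <- cbind(1, embPooled[te, , drop = FALSE])
            }
            if (length(tr) <= ncol(Xtr))
                stop("training fold too small for pcaK = ", k)
            if (!anyMissing) {
                beta <- .lsFit(Xtr, Y[tr, , drop = FALSE])
                pred[te, ] <- Xte %*% beta
            } else {
                for (cc in seq_len(ncol(Y))) {
                    okTr <- tr[!is.na(Y[tr, cc])]
                    okTe <- te[!is.na(Y[te, cc])]
                    if (!length(okTr) || !length(okTe)) next
                    beta <- .lsFit(Xtr[match(okTr, tr), , drop = FALSE],
                                   Y[okTr, cc])
                    pred[okTe, cc] <- Xte[match(okTe, te), ,
                                          drop = FALSE] %*% beta
                }
            }
        }
        r <- if (!anyMissing) .colCor(pred, Y) else
            vapply(seq_len(ncol(Y)), function(cc) {
                ok <- !is.na(Y[, cc]) & !is.na(pred[, cc])
                if (sum(ok) < 3L) return(NA_real_)
                cor(pred[ok, cc], Y[ok, cc])
            }, numeric(1))
        vals[, l, ] <- matrix(r, E, nLags)
    }
    vals
}

#' Layer-wise lag-resolved encoding analysis
#'
#' The central computation: for every combination of electrode, layer
#' and lag, a separate cross-validated linear encoding model predicts
#' the windowed neural response from that layer's (per-layer, per-fold
#' PCA-reduced) embeddings; its pooled out-of-fold correlation fills
#' the electrodes x layers x lags tensor.
#'
#' Folds come from `foldIds(events)` when set, otherwise from
#' [makeFolds()] using `config`. Words whose window is out of bounds at
#' a given lag are dropped from both design and response for that lag
#' only.
#'
#' @param recording A [NeuralRecording-class].
#' @param events A [WordEventTable-class] (same word count as
#'   `embeddings`).
#' @param embeddings A [LayeredEmbeddingSet-class].
#' @param config An [EncodingConfig-class].
#' @return An [EncodingTensor-class].
#' @export
encodeLayerwise <- function(recording, events, embeddings,
                            config = EncodingConfig()) {
    stopifnot(is(recording, "NeuralRecording"),
              is(events, "WordEventTable"),
              is(embeddings, "LayeredEmbeddingSet"))
    validObject(config)
    n <- nWords(events)
    if (nWords(embeddings) != n)
        stop("events and embeddings disagree on word count")
    lags <- lagGrid(config)
    E <- nElectrodes(recording)
    L <- nLayers(embeddings)
    folds <- foldIds(events)
    if (all(is.na(folds)))
        folds <- makeFolds(n, config@nFolds, config@foldMethod)

    Y <- .laggedResponseCube(recording, events, lags, config@window)
    dim(Y) <- c(n, E * length(lags))                  # words x (E*lags)

    layers <- lapply(layerIds(embeddings), function(id)
        layerMatrix(embeddings, id))
    vals <- .encodeCore(Y, folds, layers, config, E, length(lags))
    new("EncodingTensor", values = vals, lags = lags,
        layerIds = layerIds(embeddings),
        electrodeIds = electrodeIds(recording),
        roiLabels = roiLabels(recording))
}

#' Average an encoding tensor over an ROI's electrodes
#'
#' @param tensor An [EncodingTensor-class].
#' @param roi ROI label to average within, or `NULL` (default) for all
#'   electrodes. At least one electrode must carry the label.
#' @return Numeric matrix, layers x lags, with layer ids as rownames
#'   and lags as colnames.
#' @export
averageOverElectrodes <- function(tensor, roi = NULL) {
    stopifnot(is(tensor, "EncodingTensor"))
    sel <- if (is.null(roi)) seq_len(nElectrodes(tensor)) else
        which(roiLabels(tensor) == roi)
    if (!length(sel)) stop("no electrodes carry ROI label '", roi, "'")
    v <- tensor@values[sel, , , drop = FALSE]
    m <- colMeans(v, dims = 1L)                 # layers x lags
    dimnames(m) <- list(layer = layerIds(tensor), lag = lagGrid(tensor))
    m
}

#' Scale each layer's encoding curve to peak at 1
#'
#' Divides every row by its own maximum so each layer's encoding-vs-lag
#' curve peaks at 1, making the temporal order of peaks directly
#' comparable across layers. Rows whose maximum is not positive cannot
#' be scaled; they are set to NA and reported in the `"excludedRows"`
#' attribute.
#'
#' @param m Numeric matrix, layers x lags.
#' @return Matrix of the same shape; every retained row has maximum 1.
#' @export
scaleRows <- function(m) {
    m <- as.matrix(m)
    mx <- apply(m, 1L, max, na.rm = TRUE)
    bad <- !is.finite(mx) | mx <= 0
    out <- m / mx
    if (any(bad)) {
        warning(sum(bad), " row(s) with non-positive maximum excluded ",
                "from scaling")
        out[bad, ] <- NA_real_
    }
    structure(out, excludedRows = which(bad))
}
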