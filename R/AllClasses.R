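#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## WordEventTable
## ---------------------------------------------------------------------------

#' Word events: the temporal skeleton joining stimulus to signal
#'
#' Per-word onset times, identities, optional next-word probability ranks
#' and optional cross-validation fold assignments.
#'
#' @slot word Character vector of word tokens.
#' @slot onset Numeric vector of onset times (ms), strictly increasing.
#' @slot rank Integer vector of next-word probability ranks (>= 1, NA when
#'   unavailable). Rank 1 means the model assigned the word the highest
#'   probability of coming next.
#' @slot foldId Integer vector of fold ids in `0:(n_folds - 1)` (NA when
#'   folds have not been assigned).
#' @export
setClass("WordEventTable",
    representation(word = "character", onset = "numeric",
                   rank = "integer", foldId = "integer"))

setValidity("WordEventTable", function(object) {
    n <- length(object@word)
    msg <- character()
    if (length(object@onset) != n)
        msg <- c(msg, "'onset' and 'word' lengths differ")
    if (length(object@rank) != n)
        msg <- c(msg, "'rank' and 'word' lengths differ")
    if (length(object@foldId) != n)
        msg <- c(msg, "'foldId' and 'word' lengths differ")
    if (any(!is.finite(object@onset)))
        msg <- c(msg, "onsets must be finite")
    if (n > 1L && any(diff(object@onset) <= 0))
        msg <- c(msg, "onsets must be strictly increasing")
    if (any(object@rank < 1L, na.rm = TRUE))
        msg <- c(msg, "ranks must be >= 1")
    if (any(object@foldId < 0L, na.rm = TRUE))
        msg <- c(msg, "fold ids must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a WordEventTable
#'
#' @param word Character vector of tokens. Defaults to `w1, w2, ...`.
#' @param onset Numeric vector of onsets in ms, strictly increasing.
#' @param rank Optional integer vector of next-word probability ranks.
#' @param foldId Optional integer vector of fold ids (0-based).
#' @return A [WordEventTable-class].
#' @examples
#' ev <- WordEventTable(onset = c(0, 350, 700), rank = c(1L, 3L, 10L))
#' nWords(ev)
#' @export
WordEventTable <- function(word = NULL, onset, rank = NULL, foldId = NULL) {
    n <- length(onset)
    if (is.null(word)) word <- paste0("w", seq_len(n))
    if (is.null(rank)) rank <- rep(NA_integer_, n)
    if (is.null(foldId)) foldId <- rep(NA_integer_, n)
    new("WordEventTable", word = as.character(word),
        onset = as.numeric(onset),
        rank = as.integer(rank), foldId = as.integer(foldId))
}

#' @rdname nWords
#' @export
setMethod("nWords", "WordEventTable", function(x) length(x@word))

#' @rdname onsets
#' @export
setMethod("onsets", "WordEventTable", function(x) x@onset)

#' @rdname ranks
#' @export
setMethod("ranks", "WordEventTable", function(x) x@rank)

#' @rdname foldIds
#' @export
setMethod("foldIds", "WordEventTable", function(x) x@foldId)

setMethod("show", "WordEventTable", function(object) {
    cat("WordEventTable with", nWords(object), "words\n")
    if (nWords(object)) {
        cat("  onsets (ms):", format(object@onset[1]), "...",
            format(object@onset[nWords(object)]), "\n")
        cat("  ranks:", if (all(is.na(object@rank))) "absent" else "present",
            "| folds:", if (all(is.na(object@foldId))) "unset" else
                paste0(length(unique(object@foldId)), " folds"), "\n")
    }
})

#' Subset a WordEventTable
#'
#' @param x A [WordEventTable-class].
#' @param i Index vector of words to keep (order-preserving; the result
#'   must keep onsets strictly increasing).
#' @param j,...,drop Ignored.
#' @return A [WordEventTable-class].
#' @export
setMethod("[", "WordEventTable", function(x, i, j, ..., drop = TRUE) {
    new("WordEventTable", word = x@word[i], onset = x@onset[i],
        rank = x@rank[i], foldId = x@foldId[i])
})

## ---------------------------------------------------------------------------
## LayeredEmbeddingSet
## ---------------------------------------------------------------------------

#' Layered per-word embeddings
#'
#' A words x layers x dims array of embeddings together with 1-based layer
#' indices and a word index joining rows to a [WordEventTable-class].
#'
#' @slot values Numeric array, words x layers x dims; all entries finite.
#' @slot layerIds Integer vector of layer indices, strictly increasing.
#' @slot wordIndex Integer vector joining rows to the event table.
#' @export
setClass("LayeredEmbeddingSet",
    representation(values = "array", layerIds = "integer",
                   wordIndex = "integer"))

setValidity("LayeredEmbeddingSet", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L)
        return("'values' must be a 3-d array (words x layers x dims)")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "embedding values must be finite")
    if (length(object@layerIds) != d[2L])
        msg <- c(msg, "length(layerIds) must equal dim(values)[2]")
    if (length(object@layerIds) > 1L && any(diff(object@layerIds) <= 0))
        msg <- c(msg, "layerIds must be strictly increasing")
    if (length(object@wordIndex) != d[1L])
        msg <- c(msg, "length(wordIndex) must equal dim(values)[1]")
    if (length(msg)) msg else TRUE
})

#' Construct a LayeredEmbeddingSet
#'
#' @param values Numeric array, words x layers x dims.
#' @param layerIds Integer layer indices (default `1:n_layers`).
#' @param wordIndex Integer join key to the event table (default row order).
#' @return A [LayeredEmbeddingSet-class].
#' @export
LayeredEmbeddingSet <- function(values, layerIds = NULL, wordIndex = NULL) {
    d <- dim(values)
    if (is.null(layerIds)) layerIds <- seq_len(d[2L])
    if (is.null(wordIndex)) wordIndex <- seq_len(d[1L])
    new("LayeredEmbeddingSet", values = values,
        layerIds = as.integer(layerIds), wordIndex = as.integer(wordIndex))
}

#' @rdname nWords
#' @export
setMethod("nWords", "LayeredEmbeddingSet", function(x) dim(x@values)[1L])

#' @rdname nLayers
#' @export
setMethod("nLayers", "LayeredEmbeddingSet", function(x) dim(x@values)[2L])

#' @rdname layerIds
#' @export
setMethod("layerIds", "LayeredEmbeddingSet", function(x) x@layerIds)

#' @rdname embeddingArray
#' @export
setMethod("embeddingArray", "LayeredEmbeddingSet", function(x) x@values)

#' Embedding dimensionality
#'
#' @param x A [LayeredEmbeddingSet-class].
#' @return Integer scalar.
#' @export
embeddingDim <- function(x) dim(embeddingArray(x))[3L]

#' Extract one layer's words x dims matrix
#'
#' @param x A [LayeredEmbeddingSet-class].
#' @param layer A layer id (matched against `layerIds(x)`).
#' @return Numeric matrix, words x dims.
#' @export
layerMatrix <- function(x, layer) {
    j <- match(layer, layerIds(x))
    if (is.na(j)) stop("unknown layer id: ", layer)
    m <- embeddingArray(x)[, j, , drop = FALSE]
    dim(m) <- dim(m)[c(1L, 3L)]
    m
}

setMethod("show", "LayeredEmbeddingSet", function(object) {
    d <- dim(object@values)
    cat("LayeredEmbeddingSet:", d[1L], "words x", d[2L], "layers x",
        d[3L], "dims\n")
    cat("  layer ids:", object@layerIds[1L], "...",
        object@layerIds[length(object@layerIds)], "\n")
})

## ---------------------------------------------------------------------------
## NeuralRecording
## ---------------------------------------------------------------------------

#' Multi-electrode continuous neural recording
#'
#' @slot signal Numeric matrix, electrodes x samples.
#' @slot samplingRate Sampling rate in Hz (> 0).
#' @slot electrodeIds Character labels, one per electrode.
#' @slot roiLabels Character ROI tags (e.g. mSTG/aSTG/IFG/TP or a
#'   synthetic group), one per electrode.
#' @slot suspect Logical flags set by quality control (e.g. [despike()]
#'   when more than half of an electrode's samples were imputed).
#' @export
setClass("NeuralRecording",
    representation(signal = "matrix", samplingRate = "numeric",
                   electrodeIds = "character", roiLabels = "character",
                   suspect = "logical"))

setValidity("NeuralRecording", function(object) {
    msg <- character()
    ne <- nrow(object@signal)
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a single positive number")
    if (length(object@electrodeIds) != ne)
        msg <- c(msg, "electrodeIds length must equal nrow(signal)")
    if (length(object@roiLabels) != ne)
        msg <- c(msg, "roiLabels length must equal nrow(signal)")
    if (length(object@suspect) != ne)
        msg <- c(msg, "suspect length must equal nrow(signal)")
    if (length(msg)) msg else TRUE
})

#' Construct a NeuralRecording
#'
#' @param signal Numeric matrix, electrodes x samples.
#' @param samplingRate Sampling rate in Hz.
#' @param electrodeIds Optional electrode labels (default `e1, e2, ...`).
#' @param roiLabels Optional per-electrode ROI tags (default `"ROI"`).
#' @return A [NeuralRecording-class].
#' @export
NeuralRecording <- function(signal, samplingRate, electrodeIds = NULL,
                            roiLabels = NULL) {
    signal <- as.matrix(signal)
    ne <- nrow(signal)
    if (is.null(electrodeIds)) electrodeIds <- paste0("e", seq_len(ne))
    if (is.null(roiLabels)) roiLabels <- rep("ROI", ne)
    new("NeuralRecording", signal = signal,
        samplingRate = as.numeric(samplingRate),
        electrodeIds = as.character(electrodeIds),
        roiLabels = as.character(roiLabels),
        suspect = rep(FALSE, ne))
}

#' @rdname nElectrodes
#' @export
setMethod("nElectrodes", "NeuralRecording", function(x) nrow(x@signal))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "NeuralRecording", function(x) x@signal)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "NeuralRecording", function(x) x@samplingRate)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "NeuralRecording", function(x) x@roiLabels)

#' @rdname electrodeIds
#' @export
setMethod("electrodeIds", "NeuralRecording", function(x) x@electrodeIds)

#' Number of samples per electrode
#'
#' @param x A [NeuralRecording-class].
#' @return Integer scalar.
#' @export
nSamples <- function(x) ncol(signalMatrix(x))

#' Recording duration in ms
#'
#' @param x A [NeuralRecording-class].
#' @return Numeric scalar (ms).
#' @export
recordingDuration <- function(x) nSamples(x) / samplingRate(x) * 1000

setMethod("show", "NeuralRecording", function(object) {
    cat("NeuralRecording:", nElectrodes(object), "electrodes x",
        nSamples(object), "samples @", object@samplingRate, "Hz (",
        round(recordingDuration(object) / 1000, 1), "s )\n")
    cat("  ROIs:", paste(unique(object@roiLabels), collapse = ", "), "\n")
    if (any(object@suspect))
        cat("  suspect electrodes:",
            paste(object@electrodeIds[object@suspect], collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Encoding analysis configuration
#'
#' @slot lagMin,lagMax Lag grid endpoints in ms (defaults -2000, 2000).
#' @slot lagStep Lag increment in ms (default 25); `lagMax - lagMin` must
#'   be divisible by it.
#' @slot window Width of the averaging window around each lag, in ms
#'   (default 200, i.e. +/- 100 ms around the lag).
#' @slot nFolds Number of cross-validation folds (default 10).
#' @slot pcaK Number of principal components retained per layer (default
#'   50).
#' @slot pcaDialect Either `"fold_safe"` (projection learned from the
#'   training folds only; the default) or `"pooled"` (learned from
#'   train and test jointly).
#' @slot foldMethod `"contiguous"` blocks of words (default) or
#'   `"random"`.
#' @export
setClass("EncodingConfig",
    representation(lagMin = "numeric", lagMax = "numeric",
                   lagStep = "numeric", window = "numeric",
                   nFolds = "integer", pcaK = "integer",
                   pcaDialect = "character", foldMethod = "character"))

setValidity("EncodingConfig", function(object) {
    msg <- character()
    if (object@lagStep <= 0) msg <- c(msg, "lagStep must be > 0")
    if (object@window <= 0) msg <- c(msg, "window must be > 0")
    if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
    if (object@lagMax < object@lagMin) msg <- c(msg, "lagMax < lagMin")
    span <- object@lagMax - object@lagMin
    if (abs(span / object@lagStep - round(span / object@lagStep)) > 1e-8)
        msg <- c(msg, "(lagMax - lagMin) must be divisible by lagStep")
    if (!object@pcaDialect %in% c("fold_safe", "pooled"))
        msg <- c(msg, "pcaDialect must be 'fold_safe' or 'pooled'")
    if (!object@foldMethod %in% c("contiguous", "random"))
        msg <- c(msg, "foldMethod must be 'contiguous' or 'random'")
    if (object@pcaK < 1L) msg <- c(msg, "pcaK must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct an EncodingConfig
#'
#' @param lagMin,lagMax,lagStep Lag grid in ms; the analysis default is
#'   -2000..2000 ms in 25 ms increments (161 lags).
#' @param window Averaging window in ms (default 200).
#' @param nFolds Number of cross-validation folds (default 10).
#' @param pcaK Principal components retained per layer (default 50).
#' @param pcaDialect `"fold_safe"` (default) or `"pooled"`.
#' @param foldMethod `"contiguous"` (default) or `"random"`.
#' @return An [EncodingConfig-class].
#' @examples
#' length(buildLagGrid(EncodingConfig()))  # 161
#' @export
EncodingConfig <- function(lagMin = -2000, lagMax = 2000, lagStep = 25,
                           window = 200, nFolds = 10, pcaK = 50,
                           pcaDialect = c("fold_safe", "pooled"),
                           foldMethod = c("contiguous", "random")) {
    new("EncodingConfig", lagMin = as.numeric(lagMin),
        lagMax = as.numeric(lagMax), lagStep = as.numeric(lagStep),
        window = as.numeric(window), nFolds = as.integer(nFolds),
        pcaK = as.integer(pcaK), pcaDialect = match.arg(pcaDialect),
        foldMethod = match.arg(foldMethod))
}

#' @rdname lagGrid
#' @export
setMethod("lagGrid", "EncodingConfig", function(x)
    seq(x@lagMin, x@lagMax, by = x@lagStep))

setMethod("show", "EncodingConfig", function(object) {
    cat("EncodingConfig: lags", object@lagMin, "..", object@lagMax, "by",
        object@lagStep, "ms (", length(lagGrid(object)), "lags ),",
        object@window, "ms window,", object@nFolds, "folds, PCA k =",
        object@pcaK, paste0("(", object@pcaDialect, ")"), "\n")
})

#' Synthetic dataset configuration
#'
#' Describes a synthetic study: word-onset event train, a chain of
#' layer embeddings, and electrode signals in which each layer's
#' information drives the signal at a planted, layer-dependent lag.
#'
#' @slot nWords Number of words (default 800).
#' @slot nLayers Number of embedding layers (>= 2; default 24).
#' @slot embedDim Embedding dimensionality (>= 2; default 64).
#' @slot nElectrodes Number of electrodes (default 8).
#' @slot samplingRate Sampling rate in Hz (default 512).
#' @slot wordSpacing Mean inter-onset interval in ms (default 350).
#' @slot lagMap Planted peak lag per layer: a numeric vector of length
#'   `nLayers` (ms) or a function mapping layer index to lag.
#' @slot snr Ratio of signal variance to noise variance measured on the
#'   lagged-window scale (>= 0; `Inf` = noise-free; default 1).
#' @slot nonlinearity One of `"chain_nonlinear"`, `"linear_interp"`,
#'   `"null"`.
#' @slot designatedLayers `NULL` (every electrode carries every layer's
#'   information, the default) or a list with one integer vector of
#'   layer indices per electrode.
#' @slot padding Silence added before the first and after the last word
#'   (ms), sized to keep all analysis windows in-bounds (default 2300).
#' @slot seed Integer RNG seed.
#' @export
setClass("SyntheticConfig",
    representation(nWords = "integer", nLayers = "integer",
                   embedDim = "integer", nElectrodes = "integer",
                   samplingRate = "numeric", wordSpacing = "numeric",
                   lagMap = "ANY", snr = "numeric",
                   nonlinearity = "character",
                   designatedLayers = "ANY", padding = "numeric",
                   seed = "integer"))

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nLayers < 2L) msg <- c(msg, "nLayers must be >= 2")
    if (object@embedDim < 2L) msg <- c(msg, "embedDim must be >= 2")
    if (object@nWords < 2L) msg <- c(msg, "nWords must be >= 2")
    if (object@nElectrodes < 1L) msg <- c(msg, "nElectrodes must be >= 1")
    if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
    if (object@wordSpacing <= 0) msg <- c(msg, "wordSpacing must be > 0")
    if (!is.na(object@snr) && object@snr < 0)
        msg <- c(msg, "snr must be >= 0")
    if (!object@nonlinearity %in%
        c("chain_nonlinear", "linear_interp", "null"))
        msg <- c(msg, paste0("unknown nonlinearity '", object@nonlinearity,
                             "'; must be chain_nonlinear, linear_interp or null"))
    if (!(is.function(object@lagMap) || is.numeric(object@lagMap)))
        msg <- c(msg, "lagMap must be a numeric vector or a function")
    if (is.numeric(object@lagMap) && length(object@lagMap) != object@nLayers)
        msg <- c(msg, "numeric lagMap must have one lag per layer")
    dl <- object@designatedLayers
    if (!is.null(dl)) {
        if (!is.list(dl) || length(dl) != object@nElectrodes)
            msg <- c(msg, "designatedLayers must be NULL or a list with ",
                     "one entry per electrode")
        else if (any(!unlist(dl) %in% seq_len(object@nLayers)))
            msg <- c(msg, "designatedLayers entries must be layer indices")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults emulate a desk-scale version of a ~30-minute naturalistic
#' listening session: ~800 words at 350 ms mean spacing with a linearly
#' increasing planted lag map (0..575 ms in 25 ms steps across 24
#' layers).
#'
#' @param nWords,nLayers,embedDim,nElectrodes,samplingRate,wordSpacing
#'   See [SyntheticConfig-class].
#' @param lagMap Numeric vector (ms per layer) or function of the layer
#'   index; default `25 * (layer - 1)`.
#' @param snr Signal-to-noise variance ratio on the lagged-window scale.
#' @param nonlinearity Embedding chain regime.
#' @param designatedLayers `NULL` (default: all layers drive every
#'   electrode) or a list of per-electrode layer-index vectors.
#' @param padding Head/tail padding in ms.
#' @param seed RNG seed.
#' @return A [SyntheticConfig-class].
#' @export
SyntheticConfig <- function(nWords = 800, nLayers = 24, embedDim = 64,
                            nElectrodes = 8, samplingRate = 512,
                            wordSpacing = 350,
                            lagMap = function(layer) 25 * (layer - 1),
                            snr = 1,
                            nonlinearity = c("chain_nonlinear",
                                             "linear_interp", "null"),
                            designatedLayers = NULL,
                            padding = 2300, seed = 1) {
    nonlinearity <- as.character(nonlinearity)[1L]
    new("SyntheticConfig", nWords = as.integer(nWords),
        nLayers = as.integer(nLayers), embedDim = as.integer(embedDim),
        nElectrodes = as.integer(nElectrodes),
        samplingRate = as.numeric(samplingRate),
        wordSpacing = as.numeric(wordSpacing), lagMap = lagMap,
        snr = as.numeric(snr), nonlinearity = nonlinearity,
        designatedLayers = designatedLayers,
        padding = as.numeric(padding), seed = as.integer(seed))
}

setMethod("show", "SyntheticConfig", function(object) {
    cat("SyntheticConfig:", object@nWords, "words,", object@nLayers,
        "layers x", object@embedDim, "dims,", object@nElectrodes,
        "electrodes @", object@samplingRate, "Hz\n")
    cat("  regime:", object@nonlinearity, "| snr:", object@snr,
        "| spacing:", object@wordSpacing, "ms | seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SyntheticDataset
## ---------------------------------------------------------------------------

#' A generated dataset with planted ground truth
#'
#' @slot events A [WordEventTable-class].
#' @slot embeddings A [LayeredEmbeddingSet-class].
#' @slot recording A [NeuralRecording-class].
#' @slot truth List with the lag map actually used (`lagMap`, ms per
#'   layer), the per-electrode readout weights (`readout`, dims x layers
#'   x electrodes), the response kernel and the noise SD.
#' @slot config The [SyntheticConfig-class] used.
#' @export
setClass("SyntheticDataset",
    representation(events = "WordEventTable",
                   embeddings = "LayeredEmbeddingSet",
                   recording = "NeuralRecording",
                   truth = "list", config = "SyntheticConfig"))

setValidity("SyntheticDataset", function(object) {
    msg <- character()
    if (nWords(object@events) != nWords(object@embeddings))
        msg <- c(msg, "events and embeddings disagree on word count")
    dur <- recordingDuration(object@recording)
    if (max(onsets(object@events)) >= dur)
        msg <- c(msg, "onsets extend beyond the recording")
    if (length(msg)) msg else TRUE
})

#' @rdname nWords
#' @export
setMethod("nWords", "SyntheticDataset", function(x) nWords(x@events))

#' Components of a SyntheticDataset
#'
#' @param x A [SyntheticDataset-class].
#' @return The respective component.
#' @export
syntheticEvents <- function(x) x@events

#' @rdname syntheticEvents
#' @export
syntheticEmbeddings <- function(x) x@embeddings

#' @rdname syntheticEvents
#' @export
syntheticRecording <- function(x) x@recording

#' @rdname syntheticEvents
#' @export
syntheticTruth <- function(x) x@truth

setMethod("show", "SyntheticDataset", function(object) {
    cat("SyntheticDataset (", object@config@nonlinearity, ", snr ",
        object@config@snr, ")\n", sep = "")
    show(object@events); show(object@embeddings); show(object@recording)
})

## ---------------------------------------------------------------------------
## EncodingTensor
## ---------------------------------------------------------------------------

#' Electrode x layer x lag encoding performance
#'
#' The central intermediate result: for every combination of electrode,
#' layer and lag, the pooled cross-validated correlation between
#' predicted and observed responses.
#'
#' @slot values Numeric array, electrodes x layers x lags; correlations
#'   in \[-1, 1\] (NA where flagged missing).
#' @slot lags Numeric lag grid (ms).
#' @slot layerIds Integer layer indices.
#' @slot electrodeIds Character electrode labels.
#' @slot roiLabels Character ROI labels, one per electrode.
#' @export
setClass("EncodingTensor",
    representation(values = "array", lags = "numeric",
                   layerIds = "integer", electrodeIds = "character",
                   roiLabels = "character"))

setValidity("EncodingTensor", function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L)
        return("'values' must be electrodes x layers x lags")
    if (length(object@lags) != d[3L])
        msg <- c(msg, "length(lags) must equal dim(values)[3]")
    if (length(object@layerIds) != d[2L])
        msg <- c(msg, "length(layerIds) must equal dim(values)[2]")
    if (length(object@electrodeIds) != d[1L])
        msg <- c(msg, "length(electrodeIds) must equal dim(values)[1]")
    if (length(object@roiLabels) != d[1L])
        msg <- c(msg, "length(roiLabels) must equal dim(values)[1]")
    v <- object@values[is.finite(object@values)]
    if (length(v) && (min(v) < -1 - 1e-8 || max(v) > 1 + 1e-8))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname nElectrodes
#' @export
setMethod("nElectrodes", "EncodingTensor", function(x) dim(x@values)[1L])

#' @rdname nLayers
#' @export
setMethod("nLayers", "EncodingTensor", function(x) dim(x@values)[2L])

#' @rdname layerIds
#' @export
setMethod("layerIds", "EncodingTensor", function(x) x@layerIds)

#' @rdname lagGrid
#' @export
setMethod("lagGrid", "EncodingTensor", function(x) x@lags)

#' @rdname roiLabels
#' @export
setMethod("roiLabels", "EncodingTensor", function(x) x@roiLabels)

#' @rdname electrodeIds
#' @export
setMethod("electrodeIds", "EncodingTensor", function(x) x@electrodeIds)

#' Raw values of an EncodingTensor
#'
#' @param x An [EncodingTensor-class].
#' @return Numeric array, electrodes x layers x lags.
#' @export
tensorValues <- function(x) x@values

setMethod("show", "EncodingTensor", function(object) {
    d <- dim(object@values)
    cat("EncodingTensor:", d[1L], "electrodes x", d[2L], "layers x",
        d[3L], "lags\n")
    cat("  lags:", object@lags[1L], "..", object@lags[d[3L]], "ms\n")
    cat("  max correlation:",
        format(max(object@values, na.rm = TRUE), digits = 3), "\n")
})

## ---------------------------------------------------------------------------
## LagLayerResult
## ---------------------------------------------------------------------------

#' Headline lag-layer statistics
#'
#' Per-layer peak lags together with the correlation between layer index
#' and peak lag, its exact parametric p-value and the layer-index
#' permutation p-value.
#'
#' @slot peakLags Numeric vector of per-layer peak lags (ms).
#' @slot layerIds Integer layer indices.
#' @slot rPearson,rSpearman Correlation between layer index and peak lag.
#' @slot pExact Two-sided p from the exact distribution of the Pearson r.
#' @slot pPermutation Add-one permutation p from shuffling layer indices.
#' @slot nLayers Number of layers entering the statistic.
#' @export
setClass("LagLayerResult",
    representation(peakLags = "numeric", layerIds = "integer",
                   rPearson = "numeric", rSpearman = "numeric",
                   pExact = "numeric", pPermutation = "numeric",
                   nLayers = "integer"))

setValidity("LagLayerResult", function(object) {
    msg <- character()
    if (length(object@peakLags) != object@nLayers)
        msg <- c(msg, "peakLags length must equal nLayers")
    for (s in c("rPearson", "rSpearman")) {
        v <- slot(object, s)
        if (length(v) == 1L && is.finite(v) && abs(v) > 1 + 1e-8)
            msg <- c(msg, paste(s, "must lie in [-1, 1]"))
    }
    for (s in c("pExact", "pPermutation")) {
        v <- slot(object, s)
        if (length(v) == 1L && is.finite(v) && (v <= 0 || v > 1))
            msg <- c(msg, paste(s, "must lie in (0, 1]"))
    }
    if (length(msg)) msg else TRUE
})

#' @rdname peakLags
#' @export
setMethod("peakLags", "LagLayerResult",
          function(x, lags, ...) x@peakLags)

#' @rdname nLayers
#' @export
setMethod("nLayers", "LagLayerResult", function(x) x@nLayers)

#' @rdname layerIds
#' @export
setMethod("layerIds", "LagLayerResult", function(x) x@layerIds)

#' Correlation and p-value accessors for LagLayerResult
#'
#' @param x A [LagLayerResult-class].
#' @return Numeric scalar.
#' @export
rPearson <- function(x) x@rPearson

#' @rdname rPearson
#' @export
rSpearman <- function(x) x@rSpearman

#' @rdname rPearson
#' @export
pExact <- function(x) x@pExact

#' @rdname rPearson
#' @export
pPermutation <- function(x) x@pPermutation

setMethod("show", "LagLayerResult", function(object) {
    cat("LagLayerResult over", object@nLayers, "layers\n")
    cat("  peak lags:", min(object@peakLags), "..", max(object@peakLags),
        "ms\n")
    cat(sprintf("  lag-layer correlation: Pearson r = %.3f (exact p = %.3g)\n",
                object@rPearson, object@pExact))
    cat(sprintf("  Spearman r = %.3f | permutation p = %.3g\n",
                object@rSpearman, object@pPermutation))
})

## ---------------------------------------------------------------------------
## ElectrodeSelectionResult
## ---------------------------------------------------------------------------

#' Result of phase-randomization electrode selection
#'
#' @slot observed Per-electrode observed statistic: the encoding model's
#'   maximal correlation across all lags.
#' @slot nullMax Null distribution: per permutation, the maximum across
#'   electrodes of the max-over-lags statistic on phase-randomized
#'   signals.
#' @slot pValues Per-electrode add-one percentile p-values.
#' @slot qValues Benjamini-Hochberg q-values.
#' @slot selected Logical; `TRUE` where `qValues < qThreshold`.
#' @slot qThreshold The significance threshold used.
#' @slot electrodeIds Electrode labels.
#' @export
setClass("ElectrodeSelectionResult",
    representation(observed = "numeric", nullMax = "numeric",
                   pValues = "numeric", qValues = "numeric",
                   selected = "logical", qThreshold = "numeric",
                   electrodeIds = "character"))

setValidity("ElectrodeSelectionResult", function(object) {
    msg <- character()
    n <- length(object@observed)
    if (length(object@pValues) != n || length(object@qValues) != n ||
        length(object@selected) != n || length(object@electrodeIds) != n)
        msg <- c(msg, "per-electrode slots must have equal length")
    if (!identical(object@selected,
                   as.logical(object@qValues < object@qThreshold)))
        msg <- c(msg, "selected must equal qValues < qThreshold")
    if (length(msg)) msg else TRUE
})

#' @rdname electrodeIds
#' @export
setMethod("electrodeIds", "ElectrodeSelectionResult",
          function(x) x@electrodeIds)

#' Accessors for ElectrodeSelectionResult
#'
#' @param x An [ElectrodeSelectionResult-class].
#' @return Numeric or logical vector, one entry per electrode (the null
#'   distribution for [nullDistribution()]).
#' @export
selectedElectrodes <- function(x) x@selected

#' @rdname selectedElectrodes
#' @export
selectionPValues <- function(x) x@pValues

#' @rdname selectedElectrodes
#' @export
selectionQValues <- function(x) x@qValues

#' @rdname selectedElectrodes
#' @export
nullDistribution <- function(x) x@nullMax

setMethod("show", "ElectrodeSelectionResult", function(object) {
    cat("ElectrodeSelectionResult:", sum(object@selected), "of",
        length(object@selected), "electrodes selected at q <",
        object@qThreshold, "\n")
    cat("  null permutations:", length(object@nullMax), "\n")
})
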