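#' @include lagLayer-package.R
NULL

#' Number of words represented by an object
#'
#' @param x A [WordEventTable-class], [LayeredEmbeddingSet-class] or
#'   [SyntheticDataset-class].
#' @return Integer scalar.
#' @export
setGeneric("nWords", function(x) standardGeneric("nWords"))

#' Number of layers represented by an object
#'
#' @param x A [LayeredEmbeddingSet-class], [EncodingTensor-class] or
#'   [LagLayerResult-class].
#' @return Integer scalar.
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' Number of electrodes in an object
#'
#' @param x A [NeuralRecording-class] or [EncodingTensor-class].
#' @return Integer scalar.
#' @export
setGeneric("nElectrodes", function(x) standardGeneric("nElectrodes"))

#' Word onset times
#'
#' @param x A [WordEventTable-class].
#' @return Numeric vector of onsets in ms, strictly increasing.
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' Next-word probability ranks
#'
#' @param x A [WordEventTable-class].
#' @return Integer vector (NA where no rank is available).
#' @export
setGeneric("ranks", function(x) standardGeneric("ranks"))

#' Cross-validation fold assignment
#'
#' @param x A [WordEventTable-class].
#' @return Integer vector of fold ids in `0:(n_folds - 1)` (NA if unset).
#' @export
setGeneric("foldIds", function(x) standardGeneric("foldIds"))

#' Layer indices carried by an object
#'
#' @param x A [LayeredEmbeddingSet-class], [EncodingTensor-class] or
#'   [LagLayerResult-class].
#' @return Integer vector, strictly increasing.
#' @export
setGeneric("layerIds", function(x) standardGeneric("layerIds"))

#' Embedding array
#'
#' @param x A [LayeredEmbeddingSet-class].
#' @return Numeric array, words x layers x dims.
#' @export
setGeneric("embeddingArray", function(x) standardGeneric("embeddingArray"))

#' Signal matrix of a recording
#'
#' @param x A [NeuralRecording-class].
#' @return Numeric matrix, electrodes x samples.
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' Sampling rate in Hz
#'
#' @param x A [NeuralRecording-class].
#' @return Numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Region-of-interest labels
#'
#' @param x A [NeuralRecording-class] or [EncodingTensor-class].
#' @return Character vector, one label per electrode.
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' Electrode identifiers
#'
#' @param x A [NeuralRecording-class], [EncodingTensor-class] or
#'   [ElectrodeSelectionResult-class].
#' @return Character vector.
#' @export
setGeneric("electrodeIds", function(x) standardGeneric("electrodeIds"))

#' Lag grid of an object
#'
#' @param x An [EncodingConfig-class] or [EncodingTensor-class].
#' @return Numeric vector of lags in ms.
#' @export
setGeneric("lagGrid", function(x) standardGeneric("lagGrid"))

#' Per-layer peak lags
#'
#' For a layers x lags matrix this computes, for each layer, the lag at
#' which the encoding performance is maximal (ties broken toward the
#' earliest lag). For a [LagLayerResult-class] it retrieves the stored
#' values.
#'
#' @param x A layers x lags numeric matrix, an [EncodingTensor-class]
#'   (averaged over electrodes first) or a [LagLayerResult-class].
#' @param lags Numeric vector of lags (ms), one per matrix column.
#'   Ignored for objects that carry their own lag grid.
#' @param ... Passed on to methods (e.g. `roi` for tensors).
#' @return Numeric vector of lags (ms), one per layer.
#' @export
setGeneric("peakLags", function(x, lags, ...) standardGeneric("peakLags"))
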