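#' @include AllClasses.R
NULL

#' Align hidden states causally to words
#'
#' The embedding assigned to word *i* is the hidden state produced at
#' position *i - offset*: each word's embedding is conditioned only on
#' preceding words, and the first `offset` words are dropped because
#' they have no prior context. With the default `offset = 1` and 101
#' words over 48 layers this retains 100 words, i.e. 4800 stored
#' vectors.
#'
#' @param hiddenStates Numeric array, words x layers x dims, or a
#'   [LayeredEmbeddingSet-class].
#' @param offset Causal shift in words (default 1; 0 gives the identity
#'   alignment and drops nothing).
#' @return A [LayeredEmbeddingSet-class] with `nWords - offset` words;
#'   `wordIndex` records which original words were retained.
#' @export
extractCausalEmbeddings <- function(hiddenStates, offset = 1) {
    if (is(hiddenStates, "LayeredEmbeddingSet"))
        hiddenStates <- embeddingArray(hiddenStates)
    stopifnot(length(dim(hiddenStates)) == 3L)
    offset <- as.integer(offset)
    n <- dim(hiddenStates)[1L]
    if (n - offset < 1L)
        stop("need at least ", offset + 1L, " words for offset ", offset)
    if (offset == 0L)
        return(LayeredEmbeddingSet(hiddenStates))
    keep <- (offset + 1L):n
    LayeredEmbeddingSet(hiddenStates[keep - offset, , , drop = FALSE],
                        wordIndex = keep)
}

## PCA projection (center + rotation) fit on `fit`, applied to `apply2`.
.pcaProject <- function(fit, apply2, k) {
    if (k > ncol(fit))
        stop("k (", k, ") exceeds the embedding dimension (", ncol(fit), ")")
    if (k > nrow(fit))
        stop("k (", k, ") exceeds the number of fitting words (",
             nrow(fit), ")")
    pc <- prcomp(fit, center = TRUE, scale. = FALSE, rank. = k)
    lapply(apply2, function(m)
        sweep(m, 2L, pc$center, "-") %*% pc$rotation)
}

#' Per-layer dimensionality reduction
#'
#' Reduces each layer to `k` principal components *independently* (never
#' pooling words across layers, which would mix layer information). Two
#' dialects: `"fold_safe"` learns the projection from the training rows
#' only and applies it to both sets (no test-set leakage); `"pooled"`
#' learns it from the union of train and test rows. Centering always
#' uses the fitting set's mean.
#'
#' @param train,test [LayeredEmbeddingSet-class] objects with identical
#'   layers and dimensionality.
#' @param k Number of components retained (default 50); must not exceed
#'   the embedding dimension or the number of fitting rows.
#' @param dialect `"fold_safe"` (default) or `"pooled"`.
#' @return List with elements `train` and `test`, each a
#'   [LayeredEmbeddingSet-class] with `dims = k`.
#' @export
pcaPerLayer <- function(train, test, k = 50,
                        dialect = c("fold_safe", "pooled")) {
    dialect <- match.arg(dialect)
    stopifnot(is(train, "LayeredEmbeddingSet"),
              is(test, "LayeredEmbeddingSet"))
    if (!identical(layerIds(train), layerIds(test)))
        stop("train and test must share layer ids")
    if (embeddingDim(train) != embeddingDim(test))
        stop("train and test must share embedding dimension")
    L <- nLayers(train)
    outTr <- array(NA_real_, c(nWords(train), L, k))
    outTe <- array(NA_real_, c(nWords(test), L, k))
    for (l in seq_len(L)) {
        tr <- layerMatrix(train, layerIds(train)[l])
        te <- layerMatrix(test, layerIds(test)[l])
        fit <- if (dialect == "fold_safe") tr else rbind(tr, te)
        pr <- .pcaProject(fit, list(tr, te), k)
        outTr[, l, ] <- pr[[1L]]
        outTe[, l, ] <- pr[[2L]]
    }
    list(train = LayeredEmbeddingSet(outTr, layerIds = layerIds(train),
                                     wordIndex = train@wordIndex),
         test = LayeredEmbeddingSet(outTe, layerIds = layerIds(test),
                                    wordIndex = test@wordIndex))
}

#' Split words by model predictability
#'
#' Predicted words are those the language model ranked first
#' (`rank <= topPredictedK`); not-predicted words are those outside the
#' top `notPredictedK` ranks. Words in between belong to neither subset,
#' which matches statistical power across the two analyses.
#'
#' @param events A [WordEventTable-class] whose ranks are present.
#' @param topPredictedK Rank cutoff for "predicted" (default 1).
#' @param notPredictedK Rank cutoff for "not predicted" (default 5).
#' @return List with integer index vectors `predicted` and
#'   `notPredicted`.
#' @examples
#' ev <- WordEventTable(onset = c(0, 350, 700), rank = c(1L, 3L, 10L))
#' splitByPredictability(ev)
#' @export
splitByPredictability <- function(events, topPredictedK = 1,
                                  notPredictedK = 5) {
    stopifnot(is(events, "WordEventTable"))
    r <- ranks(events)
    if (all(is.na(r)))
        stop("predictability ranks are missing from the event table")
    list(predicted = which(!is.na(r) & r <= topPredictedK),
         notPredicted = which(!is.na(r) & r > notPredictedK))
}
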