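# Shared fixtures, all generated in code.

# Small deterministic recording: sinusoids + seeded noise.
tinyRecording <- function(nElectrodes = 3, nSamples = 1000, fs = 256,
                          seed = 42) {
    set.seed(seed)
    t <- seq_len(nSamples) / fs
    sig <- t(vapply(seq_len(nElectrodes), function(e)
        sin(2 * pi * e * t) + rnorm(nSamples, sd = 0.3),
        numeric(nSamples)))
    NeuralRecording(sig, samplingRate = fs)
}

# Desk-scale-but-small synthetic config for pipeline-level tests.
quickConfig <- function(..., seed = 1) {
    defaults <- list(nWords = 200, nLayers = 8, embedDim = 24,
                     nElectrodes = 2, samplingRate = 256,
                     wordSpacing = 350,
                     lagMap = function(l) 50 * (l - 1),
                     snr = 2, padding = 1300, seed = seed)
    args <- utils::modifyList(defaults, list(...))
    do.call(SyntheticConfig, args)
}

quickEncodingConfig <- function(...) {
    EncodingConfig(lagMin = -600, lagMax = 600, lagStep = 25,
                   window = 200, nFolds = 10, pcaK = 16, ...)
}

# Symbolic annotation fixture: 6 phonemes x 33 binary features, a small
# morpheme inventory, syntax and token vectors for a couple of words.
makeAnnotation <- function(nFeatures = 33, inventorySize = 8) {
    set.seed(7)
    phon <- c("AA", "B", "K", "S", "T", "IY")
    feats <- matrix(rbinom(length(phon) * nFeatures, 1, 0.4),
                    length(phon), nFeatures,
                    dimnames = list(phon, paste0("f", seq_len(nFeatures))))
    inv <- paste0("m", seq_len(inventorySize))
    pos <- universalPOSTags(); tag <- pennTreebankTags()
    tok <- function(p, tg) c(pos = p, tag = tg, headPos = "VERB",
                             headTag = "VB", leftPos = "DET",
                             leftTag = "DT", rightPos = "NOUN",
                             rightTag = "NN")
    SymbolicAnnotation(
        phonemes = list(cat = c("K", "AA", "T"), see = c("S", "IY"),
                        a = "AA",
                        long = c("K", "AA", "T", "S", "IY", "B", "K")),
        phonemeFeatures = feats,
        morphemes = list(cat = "m3", cats = c("m3", "m5"),
                         big = c("m1", "m2")),
        morphemeInventory = inv,
        syntax = list(cat = list(tok("NOUN", "NN")),
                      gonna = list(tok("VERB", "VBG"), tok("PART", "TO")),
                      same2 = list(tok("NOUN", "NN"), tok("NOUN", "NN"))),
        tokenVectors = list(cat = matrix(1:96, 1, 96),
                            anti = rbind(rep(2, 96), rep(-2, 96)),
                            tri = rbind(1:96, 96:1, rep(3, 96))))
}
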