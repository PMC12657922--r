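#' @include AllClasses.R
NULL

#' Universal part-of-speech tag set (17 elements)
#'
#' @return Character vector of the 17 universal POS labels.
#' @export
universalPOSTags <- function() {
    c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN", "NUM",
      "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM", "VERB", "X")
}

#' Penn Treebank fine-grained tag set (36 elements)
#'
#' @return Character vector of the 36 refined TAG labels.
#' @export
pennTreebankTags <- function() {
    c("CC", "CD", "DT", "EX", "FW", "IN", "JJ", "JJR", "JJS", "LS", "MD",
      "NN", "NNP", "NNPS", "NNS", "PDT", "POS", "PRP", "PRP$", "RB",
      "RBR", "RBS", "RP", "SYM", "TO", "UH", "VB", "VBD", "VBG", "VBN",
      "VBP", "VBZ", "WDT", "WP", "WP$", "WRB")
}

#' Per-word symbolic linguistic annotation
#'
#' Container for the four symbolic embedding builders. All components
#' are optional; each builder checks for the one it needs.
#'
#' @slot phonemes Named list, one character vector of phoneme symbols
#'   per word.
#' @slot phonemeFeatures Numeric matrix, phonemes x binary features
#'   (rownames are phoneme symbols; 33 features in the standard setup).
#' @slot morphemes Named list, one ordered character vector of morphemes
#'   per word.
#' @slot morphemeInventory Ordered character vector of all morphemes.
#' @slot syntax Named list; per word, a list of tokens, each a named
#'   character vector with entries `pos`/`tag`/`headPos`/`headTag`/
#'   `leftPos`/`leftTag`/`rightPos`/`rightTag` (POS from the 17-element
#'   universal set, TAG from the 36-element Penn set).
#' @slot tokenVectors Named list; per word, a numeric matrix of token
#'   vectors (tokens x 96 in the standard setup).
#' @export
setClass("SymbolicAnnotation",
    representation(phonemes = "list", phonemeFeatures = "matrix",
                   morphemes = "list", morphemeInventory = "character",
                   syntax = "list", tokenVectors = "list"))

#' Construct a SymbolicAnnotation
#'
#' @param phonemes,phonemeFeatures,morphemes,morphemeInventory,syntax,tokenVectors
#'   See [SymbolicAnnotation-class]; all optional.
#' @return A [SymbolicAnnotation-class].
#' @export
SymbolicAnnotation <- function(phonemes = list(),
                               phonemeFeatures = matrix(0, 0, 0),
                               morphemes = list(),
                               morphemeInventory = character(),
                               syntax = list(),
                               tokenVectors = list()) {
    new("SymbolicAnnotation", phonemes = phonemes,
        phonemeFeatures = phonemeFeatures, morphemes = morphemes,
        morphemeInventory = morphemeInventory, syntax = syntax,
        tokenVectors = tokenVectors)
}

.getWordComponent <- function(lst, word, what) {
    if (!word %in% names(lst))
        stop("no ", what, " annotation for word '", word, "'")
    lst[[word]]
}

#' Phonemic feature embedding of a word
#'
#' Concatenates the per-phoneme binary feature vectors of a word in
#' order into a fixed-length vector of `maxPhonemes * n_features`
#' entries (561 in the standard setup: 17 phoneme slots x 33 features),
#' zero-padding unused slots. `pad = "tail"` fills slots from the front;
#' `pad = "centered"` places the middle phoneme in the middle slot and
#' the first/last phonemes at the end slots.
#'
#' @param annotation A [SymbolicAnnotation-class] with `phonemes` and
#'   `phonemeFeatures`.
#' @param word The word token to embed.
#' @param maxPhonemes Number of phoneme slots (default 17).
#' @param pad `"centered"` (default) or `"tail"`.
#' @return Numeric vector of length `maxPhonemes * ncol(phonemeFeatures)`.
#' @export
buildPhonemeEmbedding <- function(annotation, word, maxPhonemes = 17,
                                  pad = c("centered", "tail")) {
    pad <- match.arg(pad)
    stopifnot(is(annotation, "SymbolicAnnotation"))
    ph <- .getWordComponent(annotation@phonemes, word, "phoneme")
    feats <- annotation@phonemeFeatures
    unknown <- setdiff(ph, rownames(feats))
    if (length(unknown))
        stop("unknown phoneme(s): ", paste(unknown, collapse = ", "))
    np <- length(ph)
    if (np > maxPhonemes)
        stop("word '", word, "' has ", np, " phonemes; max is ", maxPhonemes)
    nf <- ncol(feats)
    out <- matrix(0, maxPhonemes, nf)
    slots <- if (pad == "tail" || np == maxPhonemes) {
        seq_len(np)
    } else if (np == 1L) {
        ## a single phoneme is its own middle
        (maxPhonemes + 1L) %/% 2L
    } else {
        ## first/last at the ends, middle phoneme at the middle slot
        round(seq(1L, maxPhonemes, length.out = np))
    }
    out[slots, ] <- feats[ph, , drop = FALSE]
    as.numeric(t(out))
}

#' Morphemic one-hot embedding of a word
#'
#' Concatenates, in order, the one-hot encodings (over the morpheme
#' inventory) of the word's morphemes, zero-padded at the tail up to
#' `maxMorphemes` slots. With the standard inventory of 1042 morphemes
#' and 6 slots the embedding length is 6252.
#'
#' @param annotation A [SymbolicAnnotation-class] with `morphemes` and
#'   `morphemeInventory`.
#' @param word The word token to embed.
#' @param maxMorphemes Number of morpheme slots (default 6).
#' @return Numeric vector of length
#'   `length(morphemeInventory) * maxMorphemes`.
#' @export
buildMorphemeEmbedding <- function(annotation, word, maxMorphemes = 6) {
    stopifnot(is(annotation, "SymbolicAnnotation"))
    mo <- .getWordComponent(annotation@morphemes, word, "morpheme")
    inv <- annotation@morphemeInventory
    pos <- match(mo, inv)
    if (anyNA(pos))
        stop("unknown morpheme(s): ", paste(mo[is.na(pos)], collapse = ", "))
    if (length(mo) > maxMorphemes)
        stop("word '", word, "' has ", length(mo), " morphemes; max is ",
             maxMorphemes)
    out <- numeric(length(inv) * maxMorphemes)
    out[(seq_along(pos) - 1L) * length(inv) + pos] <- 1
    out
}

.oneHot <- function(label, levels, what) {
    i <- match(label, levels)
    if (is.na(i))
        stop("label '", label, "' is not in the ", what, " set")
    v <- numeric(length(levels))
    v[i] <- 1
    v
}

#' Syntactic one-hot embedding of a word
#'
#' Per token, the POS (17-way) and TAG (36-way) one-hot encodings of the
#' token itself, its head, and its leftmost and rightmost descendants
#' are concatenated: 4 x (17 + 36) = 212 entries. Words tokenized into
#' several tokens are averaged elementwise.
#'
#' @param annotation A [SymbolicAnnotation-class] with `syntax`.
#' @param word The word token to embed.
#' @return Numeric vector of length 212.
#' @export
buildSyntacticEmbedding <- function(annotation, word) {
    stopifnot(is(annotation, "SymbolicAnnotation"))
    toks <- .getWordComponent(annotation@syntax, word, "syntax")
    pos <- universalPOSTags()
    tag <- pennTreebankTags()
    roles <- list(c("pos", "tag"), c("headPos", "headTag"),
                  c("leftPos", "leftTag"), c("rightPos", "rightTag"))
    embs <- vapply(toks, function(tk) {
        unlist(lapply(roles, function(r)
            c(.oneHot(tk[[r[1L]]], pos, "universal POS"),
              .oneHot(tk[[r[2L]]], tag, "Penn TAG"))))
    }, numeric(4L * (length(pos) + length(tag))))
    rowMeans(embs)
}

#' Semantic embedding of a word
#'
#' The elementwise mean of the word's token vectors (96-dimensional in
#' the standard setup); single-token words return their vector
#' unchanged.
#'
#' @param annotation A [SymbolicAnnotation-class] with `tokenVectors`.
#' @param word The word token to embed.
#' @return Numeric vector of length `ncol(tokenVectors[[word]])`.
#' @export
buildSemanticEmbedding <- function(annotation, word) {
    stopifnot(is(annotation, "SymbolicAnnotation"))
    tv <- .getWordComponent(annotation@tokenVectors, word, "token-vector")
    tv <- as.matrix(tv)
    if (!nrow(tv)) stop("word '", word, "' has no token vectors")
    colMeans(tv)
}
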