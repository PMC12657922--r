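#' @include AllClasses.R
NULL

## Resolve a lag map (function or numeric) to one lag (ms) per layer.
.resolveLagMap <- function(config) {
    lm <- config@lagMap
    lags <- if (is.function(lm)) lm(seq_len(config@nLayers)) else as.numeric(lm)
    if (length(lags) != config@nLayers)
        stop("lagMap must yield one lag per layer")
    if (any(!is.finite(lags))) stop("lagMap produced non-finite lags")
    lags
}

## Embedding chain, drawn from the *current* RNG stream (callers seed).
.generateEmbeddings <- function(config) {
    n <- config@nWords; L <- config@nLayers; d <- config@embedDim
    vals <- array(NA_real_, dim = c(n, L, d))
    switch(config@nonlinearity,
        chain_nonlinear = {
            ## One fixed random affine map + saturating nonlinearity per
            ## layer step, shared across words. The gain keeps the chain
            ## near unit variance under tanh so successive layers stay
            ## related but steadily decorrelate.
            gain <- 1.8
            vals[, 1L, ] <- matrix(rnorm(n * d), n, d)
            x <- vals[, 1L, ]
            for (k in seq_len(L - 1L)) {
                A <- matrix(rnorm(d * d, sd = gain / sqrt(d)), d, d)
                b <- rnorm(d, sd = 0.1)
                x <- tanh(sweep(x %*% A, 2L, b, "+"))
                ## re-standardize columns so depth does not shrink scale
                x <- scale(x)
                attr(x, "scaled:center") <- NULL
                attr(x, "scaled:scale") <- NULL
                vals[, k + 1L, ] <- x
            }
        },
        linear_interp = {
            first <- matrix(rnorm(n * d), n, d)
            last <- matrix(rnorm(n * d), n, d)
            w <- seq(0, 1, length.out = L)
            for (k in seq_len(L))
                vals[, k, ] <- (1 - w[k]) * first + w[k] * last
        },
        null = {
            vals[] <- rnorm(n * L * d)
        },
        stop("unknown nonlinearity '", config@nonlinearity, "'")
    )
    LayeredEmbeddingSet(vals)
}

#' Generate layered per-word embeddings
#'
#' Produces the three embedding regimes the analysis distinguishes:
#' `chain_nonlinear` (layer 1 i.i.d. per word; each subsequent layer is a
#' fixed random affine map followed by an elementwise saturating
#' nonlinearity, shared across words, so successive layers are
#' deterministically but nonlinearly related), `linear_interp`
#' (intermediate layers are convex combinations of the first and last
#' layers with monotonically increasing weights), and `null` (all layers
#' i.i.d.).
#'
#' @param config A [SyntheticConfig-class]; `config@seed` fixes the RNG.
#' @return A [LayeredEmbeddingSet-class] of dimension
#'   `nWords x nLayers x embedDim`.
#' @examples
#' cfg <- SyntheticConfig(nWords = 20, nLayers = 4, embedDim = 8,
#'                        nonlinearity = "linear_interp")
#' emb <- generateLayeredEmbeddings(cfg)
#' all.equal(layerMatrix(emb, 1), layerMatrix(emb, 1))
#' @export
generateLayeredEmbeddings <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    set.seed(config@seed)
    .generateEmbeddings(config)
}

## Raised-cosine (Hamming) response kernel, peak-normalized.
.responseKernel <- function(fs, widthMs = 200) {
    m <- max(3L, round(widthMs / 1000 * fs))
    k <- 0.54 - 0.46 * cos(2 * pi * seq(0L, m - 1L) / (m - 1L))
    k / max(k)
}

#' Generate a synthetic dataset with a planted lag-layer gradient
#'
#' For each electrode the signal is a sum over words and layers of a
#' response kernel centered at `onset + lagMap(layer)`, scaled by a
#' linear readout of that word's layer embedding, plus white Gaussian
#' noise whose variance is set so that the signal-to-noise variance
#' ratio *on the lagged-window scale* (the scale the encoding model
#' sees) equals `config@snr`. Under the `null` regime the per-word
#' response amplitudes are i.i.d. random and carry no embedding (hence
#' no layer) information.
#'
#' Word onsets form a jittered regular grid with mean spacing
#' `config@wordSpacing`, snapped to the sample grid so kernel/window
#' alignment is exact across words.
#'
#' @param config A [SyntheticConfig-class].
#' @return A [SyntheticDataset-class]; `syntheticTruth()` returns the
#'   lag map actually used and the per-electrode readout weights.
#' @examples
#' cfg <- SyntheticConfig(nWords = 30, nLayers = 4, embedDim = 8,
#'                        nElectrodes = 2, samplingRate = 128,
#'                        padding = 800,
#'                        lagMap = c(0, 100, 200, 300), seed = 7)
#' ds <- generateNeuralDataset(cfg)
#' syntheticTruth(ds)$lagMap
#' @export
generateNeuralDataset <- function(config) {
    stopifnot(is(config, "SyntheticConfig"))
    validObject(config)
    fs <- config@samplingRate
    n <- config@nWords; L <- config@nLayers
    d <- config@embedDim; E <- config@nElectrodes
    lagMap <- .resolveLagMap(config)

    set.seed(config@seed)
    emb <- .generateEmbeddings(config)

    ## --- word onsets: jittered regular grid, snapped to sample grid ----
    spacing <- config@wordSpacing
    jitter <- runif(n, -0.2 * spacing, 0.2 * spacing)
    onset <- config@padding + (seq_len(n) - 1L) * spacing + jitter
    onset <- round(onset * fs / 1000) / fs * 1000       # snap to samples
    if (any(diff(onset) <= 0)) stop("degenerate onset grid")

    kern <- .responseKernel(fs)
    halfKern <- (length(kern) - 1) / 2 / fs * 1000
    durMs <- 2 * config@padding + (n - 1L) * spacing
    nsamp <- ceiling(durMs * fs / 1000)
    maxLag <- max(abs(lagMap))
    if (max(onset) + maxLag + halfKern >= durMs ||
        min(onset) - maxLag - halfKern <= 0)
        stop("lagMap places responses outside the recording bounds; ",
             "increase 'padding'")

    ## --- clean signal ---------------------------------------------------
    nullRegime <- config@nonlinearity == "null"
    readout <- array(rnorm(d * L * E, sd = 1 / sqrt(d)), dim = c(d, L, E))
    desig <- config@designatedLayers
    if (is.null(desig)) desig <- rep(list(seq_len(L)), E)
    onsetIdx <- round(onset * fs / 1000)                # 0-based samples
    clean <- matrix(0, E, nsamp)
    for (e in seq_len(E)) {
        ## accumulate all layers' impulse trains, then convolve once
        ## (convolution is linear in the train)
        train <- numeric(nsamp)
        for (l in desig[[e]]) {
            amp <- if (nullRegime) rnorm(n) else {
                s <- layerMatrix(emb, layerIds(emb)[l]) %*% readout[, l, e]
                as.numeric(scale(s))                    # unit amplitude scale
            }
            idx <- onsetIdx + round(lagMap[l] * fs / 1000) + 1L  # 1-based
            train[idx] <- train[idx] + amp
        }
        clean[e, ] <- .convSame(train, kern)
    }

    ## --- noise scaled on the lagged-window scale -------------------------
    windowMs <- 200
    m <- max(1L, floor(windowMs / 1000 * fs))
    ## variance across words of the windowed-mean clean signal at the
    ## planted lags, averaged over electrodes and layers
    sigVar <- mean(vapply(seq_len(E), function(e) {
        cs <- cumsum(clean[e, ])
        mean(vapply(desig[[e]], function(l) {
            ctr <- onsetIdx + round(lagMap[l] * fs / 1000)
            lo <- ctr - m %/% 2L; hi <- lo + m - 1L
            var((cs[hi + 1L] - c(0, cs)[lo + 1L]) / m)
        }, numeric(1)))
    }, numeric(1)))
    if (config@snr == 0) {
        clean[] <- 0
        noiseSd <- 1
    } else if (is.infinite(config@snr)) {
        noiseSd <- 0
    } else {
        ## windowed mean of white noise has variance sd^2 / m
        noiseSd <- sqrt(m * sigVar / config@snr)
    }
    sig <- clean + matrix(rnorm(E * nsamp, sd = noiseSd), E, nsamp)

    rec <- NeuralRecording(sig, samplingRate = fs,
                           roiLabels = rep("SYN", E))
    events <- WordEventTable(onset = onset)
    new("SyntheticDataset", events = events, embeddings = emb,
        recording = rec,
        truth = list(lagMap = lagMap, readout = readout, kernel = kern,
                     noiseSd = noiseSd, windowSamples = m,
                     designatedLayers = desig),
        config = config)
}

## Linear "same" convolution with the kernel centered; FFT-based.
.convSame <- function(x, k) {
    n <- length(x); m <- length(k)
    nfft <- stats::nextn(n + m - 1L, 2L)
    full <- Re(fft(fft(c(x, numeric(nfft - n))) *
                   fft(c(k, numeric(nfft - m))), inverse = TRUE)) / nfft
    off <- (m - 1L) %/% 2L
    full[(off + 1L):(off + n)]
}
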