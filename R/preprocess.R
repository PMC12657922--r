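#' @include AllClasses.R
NULL

#' Remove large spikes and impute replacements
#'
#' Samples exceeding `k` inter-quartile ranges above or below the median
#' of each electrode are flagged and replaced by cubic interpolation
#' through the neighboring unflagged samples; flagged samples at the
#' recording edges take the nearest unflagged value. Electrodes with
#' more than 50% flagged samples are marked suspect (with a warning) but
#' still imputed.
#'
#' @param recording A [NeuralRecording-class] with at least 4 finite
#'   samples per electrode.
#' @param k Threshold in IQR units (default 4).
#' @return A [NeuralRecording-class] of the same shape.
#' @export
despike <- function(recording, k = 4) {
    stopifnot(is(recording, "NeuralRecording"))
    sig <- signalMatrix(recording)
    if (ncol(sig) < 4L) stop("need at least 4 samples per electrode")
    suspect <- recording@suspect
    for (e in seq_len(nrow(sig))) {
        x <- sig[e, ]
        med <- median(x)
        iqr <- stats::IQR(x)
        bad <- abs(x - med) > k * iqr
        if (!any(bad)) next
        if (mean(bad) > 0.5) {
            warning("electrode ", recording@electrodeIds[e], ": more than ",
                    "50% of samples flagged; marked suspect")
            suspect[e] <- TRUE
        }
        good <- which(!bad)
        if (length(good) < 2L) {
            sig[e, bad] <- med
            next
        }
        idx <- which(bad)
        inner <- idx[idx > good[1L] & idx < good[length(good)]]
        if (length(inner))
            sig[e, inner] <- spline(good, x[good], xout = inner,
                                    method = "natural")$y
        lead <- idx[idx < good[1L]]
        if (length(lead)) sig[e, lead] <- x[good[1L]]
        trail <- idx[idx > good[length(good)]]
        if (length(trail)) sig[e, trail] <- x[good[length(good)]]
    }
    out <- recording
    out@signal <- sig
    out@suspect <- suspect
    out
}

#' Common average referencing
#'
#' Subtracts the per-sample mean across electrodes from every electrode,
#' removing signal components shared by the whole montage.
#'
#' @param recording A [NeuralRecording-class] with at least 2 electrodes.
#' @return A [NeuralRecording-class]; at every sample the mean across
#'   electrodes of the output is 0.
#' @export
rereferenceCAR <- function(recording) {
    stopifnot(is(recording, "NeuralRecording"))
    sig <- signalMatrix(recording)
    if (nrow(sig) < 2L)
        stop("common average referencing needs at least 2 electrodes")
    out <- recording
    out@signal <- sweep(sig, 2L, colMeans(sig), "-")
    out
}

## Complex Morlet kernel at frequency f (Hz), nCycles cycles.
.morletKernel <- function(f, fs, nCycles) {
    sdT <- nCycles / (2 * pi * f)
    tt <- seq(-4 * sdT, 4 * sdT, by = 1 / fs)
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sdT^2))
    w - mean(w)                       # zero-mean: insensitive to DC offset
}

## Complex "same" convolution via FFT.
.convSameComplex <- function(x, k) {
    n <- length(x); m <- length(k)
    nfft <- stats::nextn(n + m - 1L, 2L)
    full <- fft(fft(c(x, numeric(nfft - n))) *
                fft(c(k, numeric(nfft - m))), inverse = TRUE) / nfft
    off <- (m - 1L) %/% 2L
    full[(off + 1L):(off + n)]
}

#' High-gamma band power
#'
#' Computes wavelet power with `nCycles`-cycle complex Morlet wavelets on
#' a log-spaced frequency grid inside `band`, drops frequencies within
#' `guard` Hz of the excluded line-noise frequencies, and averages power
#' across the remaining frequencies.
#'
#' @param recording A [NeuralRecording-class]; its sampling rate must
#'   exceed twice the upper band edge.
#' @param band Numeric length-2, band edges in Hz (default `c(70, 200)`,
#'   the high-gamma band).
#' @param exclude Line-noise frequencies to drop (default 60, 120, 180).
#' @param nCycles Wavelet cycles (default 6).
#' @param nFreqs Number of log-spaced frequencies in the grid (default 10).
#' @param guard Exclusion guard half-width in Hz (default 5).
#' @return A [NeuralRecording-class] of the same shape holding band
#'   power.
#' @export
highGammaPower <- function(recording, band = c(70, 200),
                           exclude = c(60, 120, 180), nCycles = 6,
                           nFreqs = 10, guard = 5) {
    stopifnot(is(recording, "NeuralRecording"))
    fs <- samplingRate(recording)
    if (fs <= 2 * band[2L])
        stop("samplingRateTooLow: sampling rate (", fs,
             " Hz) must exceed twice the upper band edge (", band[2L], " Hz)")
    freqs <- exp(seq(log(band[1L]), log(band[2L]), length.out = nFreqs))
    keep <- vapply(freqs, function(f) all(abs(f - exclude) > guard),
                   logical(1))
    freqs <- freqs[keep]
    if (!length(freqs)) stop("no wavelet frequencies left after exclusion")
    sig <- signalMatrix(recording)
    pow <- matrix(0, nrow(sig), ncol(sig))
    for (f in freqs) {
        kern <- .morletKernel(f, fs, nCycles)
        for (e in seq_len(nrow(sig)))
            pow[e, ] <- pow[e, ] + Mod(.convSameComplex(sig[e, ], kern))^2
    }
    out <- recording
    out@signal <- pow / length(freqs)
    out
}

#' Smooth power with a Hamming window
#'
#' Convolves each electrode with a unit-sum Hamming window of length
#' `kernelMs` (same-length output, symmetric edge padding), the standard
#' final smoothing applied to band power.
#'
#' @param recording A [NeuralRecording-class].
#' @param kernelMs Kernel length in ms (default 50); must be positive
#'   and shorter than the recording.
#' @return A [NeuralRecording-class] of the same shape.
#' @export
smoothHamming <- function(recording, kernelMs = 50) {
    stopifnot(is(recording, "NeuralRecording"))
    if (kernelMs <= 0) stop("kernel length must be positive")
    fs <- samplingRate(recording)
    m <- max(3L, round(kernelMs / 1000 * fs))
    if (m >= nSamples(recording))
        stop("kernel must be shorter than the recording")
    k <- 0.54 - 0.46 * cos(2 * pi * seq(0L, m - 1L) / (m - 1L))
    k <- k / sum(k)
    sig <- signalMatrix(recording)
    off <- (m - 1L) %/% 2L            # kernel reach: m-1-off left, off right
    padL <- m - 1L - off
    out <- recording
    out@signal <- t(apply(sig, 1L, function(x) {
        n <- length(x)
        xx <- c(if (padL) rev(x[seq_len(padL)]), x,
                if (off) rev(x[(n - off + 1L):n]))
        .convSame(xx, k)[(padL + 1L):(padL + n)]
    }))
    out
}
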