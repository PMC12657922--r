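#' @include AllClasses.R encoding.R
NULL

#' @rdname peakLags
#' @export
setMethod("peakLags", "matrix", function(x, lags, ...) {
    if (missing(lags)) stop("a lag grid is required for matrix input")
    if (length(lags) != ncol(x))
        stop("length(lags) must equal ncol(x)")
    apply(x, 1L, function(row) {
        if (all(is.na(row))) stop("a layer's encoding row is all-missing")
        lags[which.max(row)]            # which.max: first max = earliest lag
    })
})

#' @rdname peakLags
#' @export
setMethod("peakLags", "EncodingTensor", function(x, lags, ...) {
    peakLags(averageOverElectrodes(x, ...), lagGrid(x))
})

#' Correlation between layer index and peak lag
#'
#' The headline statistic: Pearson and Spearman correlation between the
#' layer index and the lag at which each layer's encoding peaks. A
#' positive correlation means deeper layers peak later in time.
#'
#' @param peakLags Numeric vector of per-layer peak lags (ms).
#' @param layerIds Integer layer indices (default `1:n`).
#' @return List with `pearson` and `spearman`. Zero-variance peak lags
#'   yield NA with a warning.
#' @export
lagLayerCorrelation <- function(peakLags, layerIds = seq_along(peakLags)) {
    if (length(peakLags) < 3L) stop("need at least 3 layers")
    if (length(peakLags) != length(layerIds))
        stop("peakLags and layerIds lengths differ")
    if (sd(peakLags) == 0) {
        warning("peak lags have zero variance; correlation undefined")
        return(list(pearson = NA_real_, spearman = NA_real_))
    }
    list(pearson = cor(layerIds, peakLags),
         spearman = cor(layerIds, peakLags, method = "spearman"))
}

#' Exact p-value for a Pearson correlation
#'
#' Tail probability of the sample Pearson correlation for `n`
#' bivariate-normal pairs under the null of zero correlation, computed
#' through the monotone map to a Student-t statistic with `n - 2`
#' degrees of freedom.
#'
#' @param r Observed correlation, in \[-1, 1\].
#' @param n Number of pairs (>= 4).
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return The p-value.
#' @examples
#' pearsonExactP(0.85, 48)   # < 1e-12
#' @export
pearsonExactP <- function(r, n, alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    if (abs(r) > 1) stop("|r| must be <= 1")
    if (n < 4) stop("need n >= 4")
    if (abs(r) == 1) return(.Machine$double.xmin)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    switch(alternative,
           two.sided = 2 * pt(-abs(tt), df = n - 2),
           greater = pt(tt, df = n - 2, lower.tail = FALSE))
}

## all permutations of seq_len(n) as an n x n! matrix (small n only)
.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPermutations(n - 1L)
    out <- matrix(0L, n, n * ncol(sub))
    col <- 0L
    for (k in seq_len(n)) {
        rest <- seq_len(n)[-k]
        for (j in seq_len(ncol(sub))) {
            col <- col + 1L
            out[, col] <- c(k, rest[sub[, j]])
        }
    }
    out
}

#' Layer-index permutation test for the lag-layer correlation
#'
#' Permutes the layer indices (keeping the peak lags fixed) and
#' recomputes the correlation, giving a nonparametric null for the
#' observed lag-layer correlation. The add-one estimator
#' `p = (1 + #extreme) / (K + 1)` is used, so p is never 0 and its floor
#' is `1/(K + 1)`. With `exhaustive = TRUE` (layer counts up to 7) all
#' `n!` permutations are enumerated and `p = #extreme / n!`.
#'
#' @param peakLags Numeric vector of per-layer peak lags (ms).
#' @param layerIds Integer layer indices.
#' @param K Number of sampled permutations (default 100000).
#' @param seed Optional RNG seed.
#' @param alternative `"two.sided"` (default; extreme means
#'   `|r_perm| >= |r_obs|`) or `"greater"` (`r_perm >= r_obs`).
#' @param exhaustive Enumerate all permutations instead of sampling.
#' @return List with `p`, `observed` (Pearson r) and `nullR` (the
#'   permuted correlations).
#' @export
permutationTestLayerIndex <- function(peakLags, layerIds =
                                          seq_along(peakLags),
                                      K = 100000, seed = NULL,
                                      alternative = c("two.sided",
                                                      "greater"),
                                      exhaustive = FALSE) {
    alternative <- match.arg(alternative)
    n <- length(peakLags)
    if (n < 3L) stop("need at least 3 layers")
    if (!exhaustive && K < 1) stop("K must be >= 1")
    if (sd(peakLags) == 0 || sd(layerIds) == 0)
        stop("zero-variance input; correlation undefined")
    obs <- cor(layerIds, peakLags)
    y <- peakLags - mean(peakLags)
    x <- as.numeric(layerIds)
    sxy <- sd(x) * sd(peakLags) * (n - 1)
    if (exhaustive) {
        if (n > 7L) stop("exhaustive enumeration supported up to 7 layers")
        perms <- .allPermutations(n)
        nullR <- as.numeric(crossprod(matrix((x - mean(x))[perms], n), y)) /
            sxy
        extreme <- if (alternative == "two.sided")
            abs(nullR) >= abs(obs) - 1e-12 else nullR >= obs - 1e-12
        return(list(p = sum(extreme) / ncol(perms), observed = obs,
                    nullR = nullR))
    }
    if (!is.null(seed)) set.seed(seed)
    xc <- x - mean(x)
    perms <- vapply(seq_len(K), function(i) sample.int(n), integer(n))
    nullR <- as.numeric(crossprod(matrix(xc[perms], n), y)) / sxy
    extreme <- if (alternative == "two.sided")
        abs(nullR) >= abs(obs) - 1e-12 else nullR >= obs - 1e-12
    list(p = (1 + sum(extreme)) / (K + 1), observed = obs, nullR = nullR)
}

#' Full lag-layer inference for an encoding matrix
#'
#' Convenience wrapper: peak lags, Pearson/Spearman lag-layer
#' correlations, the exact parametric p and the layer-index permutation
#' p, bundled as a [LagLayerResult-class].
#'
#' @param m Numeric layers x lags matrix (e.g. from
#'   [averageOverElectrodes()]) or an [EncodingTensor-class].
#' @param lags Lag grid (taken from the tensor if omitted).
#' @param layerIds Layer indices (default `1:n_layers`).
#' @param K Permutations for the nonparametric test (default 100000).
#' @param seed Optional RNG seed for the permutation test.
#' @param alternative Sidedness for both p-values: `"two.sided"`
#'   (default) or `"greater"`.
#' @return A [LagLayerResult-class].
#' @export
lagLayerStats <- function(m, lags = NULL, layerIds = NULL, K = 100000,
                          seed = NULL,
                          alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    if (is(m, "EncodingTensor")) {
        lags <- lagGrid(m)
        if (is.null(layerIds)) layerIds <- layerIds(m)
        m <- averageOverElectrodes(m)
    }
    if (is.null(layerIds)) layerIds <- seq_len(nrow(m))
    pk <- peakLags(as.matrix(m), lags)
    cors <- lagLayerCorrelation(pk, layerIds)
    perm <- permutationTestLayerIndex(pk, layerIds, K = K, seed = seed,
                                      alternative = alternative)
    new("LagLayerResult", peakLags = pk, layerIds = as.integer(layerIds),
        rPearson = cors$pearson, rSpearman = cors$spearman,
        pExact = pearsonExactP(cors$pearson, length(pk),
                               alternative = alternative),
        pPermutation = perm$p, nLayers = length(pk))
}

#' Bootstrap significance of electrode-mean statistics
#'
#' Resamples electrodes with replacement, recomputes the mean per
#' resample, and assesses the observed mean against zero two-tailed
#' from the percentile of zero in the bootstrap distribution (add-one
#' rule).
#'
#' @param x Numeric vector of per-electrode values (e.g. max
#'   correlations for one layer), or a layers x electrodes matrix for
#'   per-layer assessment.
#' @param B Number of bootstrap resamples (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed Optional RNG seed.
#' @return For a vector: list with `mean`, `bootMeans`, `p`. For a
#'   matrix: data.frame with one row per layer.
#' @export
bootstrapElectrodeMeans <- function(x, B = 10000, seed = NULL) {
    if (is.matrix(x)) {
        if (!is.null(seed)) set.seed(seed)
        res <- lapply(seq_len(nrow(x)), function(l)
            bootstrapElectrodeMeans(x[l, ], B = B))
        return(data.frame(layer = seq_len(nrow(x)),
                          mean = vapply(res, `[[`, numeric(1), "mean"),
                          p = vapply(res, `[[`, numeric(1), "p")))
    }
    n <- length(x)
    if (n < 2L) stop("need at least 2 electrodes")
    if (B < 100) warning("fewer than 100 bootstrap resamples")
    if (!is.null(seed)) set.seed(seed)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    bm <- colMeans(matrix(x[idx], n, B))
    pLow <- (1 + sum(bm <= 0)) / (B + 1)
    pHigh <- (1 + sum(bm >= 0)) / (B + 1)
    list(mean = mean(x), bootMeans = bm, p = min(1, 2 * min(pLow, pHigh)))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up q-values with rejection flags at threshold `q`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param q FDR threshold (default 0.01); rejection is `qValues < q`.
#' @return List with `qValues` and `reject` (empty inputs give empty
#'   outputs).
#' @export
bhFdr <- function(p, q = 0.01) {
    if (!length(p)) return(list(qValues = numeric(), reject = logical()))
    if (any(!is.na(p) & (p <= 0 | p > 1)))
        stop("p-values must lie in (0, 1]")
    qv <- p.adjust(p, method = "BH")
    list(qValues = qv, reject = !is.na(qv) & qv < q)
}

#' Levene test for unequal spread of peak lags between two ROIs
#'
#' The spread (standard deviation) of per-layer peak lags is a proxy
#' for an area's temporal receptive window. This compares two ROIs'
#' spreads via Levene's test: an ANOVA F statistic on absolute
#' deviations from the group centers.
#'
#' @param a,b Numeric vectors of peak lags (ms), >= 3 values each.
#' @param center `"mean"` (default) or `"median"` centering.
#' @return List with `F`, `p`, and the two group standard deviations.
#' @export
levenePeakLagSpread <- function(a, b, center = c("mean", "median")) {
    center <- match.arg(center)
    if (length(a) < 3L || length(b) < 3L)
        stop("need at least 3 values per group")
    ctr <- if (center == "mean") mean else median
    da <- abs(a - ctr(a))
    db <- abs(b - ctr(b))
    if (sd(da) == 0 && sd(db) == 0 && mean(da) == mean(db))
        stop("zero within-group deviation in both groups")
    g <- factor(rep(c("a", "b"), c(length(a), length(b))))
    fit <- summary(aov(c(da, db) ~ g))[[1L]]
    list(F = fit[["F value"]][1L], p = fit[["Pr(>F)"]][1L],
         sd = c(a = sd(a), b = sd(b)))
}

#' Per-layer paired contrast of peak lags between two conditions
#'
#' For each layer, a paired t-test on electrode-wise differences of the
#' lags of maximal correlation between two conditions (e.g. predicted
#' vs. not-predicted words), with Benjamini-Hochberg correction across
#' layers.
#'
#' @param a,b Numeric layers x electrodes matrices of peak lags with
#'   matched electrodes (>= 3 pairs).
#' @param q FDR threshold (default 0.01).
#' @return data.frame with per-layer `t`, `p`, `qValue`, `reject`, and
#'   `degenerate` (TRUE where the differences had zero variance with a
#'   nonzero shift, leaving the t statistic undefined).
#' @export
pairedTTestLayers <- function(a, b, q = 0.01) {
    a <- as.matrix(a); b <- as.matrix(b)
    if (!all(dim(a) == dim(b)))
        stop("conditions must have matching layers x electrodes")
    if (ncol(a) < 3L) stop("need at least 3 electrode pairs")
    L <- nrow(a)
    tt <- p <- rep(NA_real_, L)
    degen <- logical(L)
    for (l in seq_len(L)) {
        d <- a[l, ] - b[l, ]
        if (sd(d) == 0) {
            if (all(d == 0)) { tt[l] <- 0; p[l] <- 1 }
            else degen[l] <- TRUE     # constant nonzero shift: t undefined
            next
        }
        ht <- t.test(a[l, ], b[l, ], paired = TRUE)
        tt[l] <- unname(ht$statistic)
        p[l] <- ht$p.value
    }
    fdr <- bhFdr(p, q)
    data.frame(layer = seq_len(L), t = tt, p = p, qValue = fdr$qValues,
               reject = fdr$reject, degenerate = degen)
}
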