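test_that("peak lags take the earliest lag on ties", {
    lags <- seq(-100, 100, 25)
    m <- rbind(c(0, 0, 1, 0, 0, 0, 0, 0, 0),
               c(0, 0, 0.5, 0, 0, 0.5, 0, 0, 0))  # tie at -50 and +25
    expect_equal(peakLags(m, lags), c(-50, -50))
    m2 <- matrix(c(0.1, 0.9, 0.3), 1)
    expect_equal(peakLags(m2, c(100, 150, 200)), 150)
    expect_error(peakLags(rbind(NA_real_), 0), "all-missing")
})

test_that("lag-layer correlation distinguishes linear from monotone", {
    expect_equal(lagLayerCorrelation(25 * (1:10))$pearson, 1)
    convex <- (1:10)^3
    cc <- lagLayerCorrelation(convex)
    expect_equal(cc$spearman, 1)
    expect_lt(cc$pearson, 1)
    # 5-layer toy against the hand covariance formula
    pk <- c(-50, 0, 100, 75, 250)
    li <- 1:5
    hand <- sum((li - mean(li)) * (pk - mean(pk))) /
        sqrt(sum((li - mean(li))^2) * sum((pk - mean(pk))^2))
    expect_equal(lagLayerCorrelation(pk)$pearson, hand, tolerance = 1e-12)
    expect_warning(z <- lagLayerCorrelation(rep(5, 4)), "zero variance")
    expect_true(is.na(z$pearson))
})

test_that("exact Pearson p behaves analytically", {
    expect_equal(pearsonExactP(0, 10), 1)
    # the workhorse case: r = 0.85 over 48 layers is overwhelmingly
    # unlikely under the null
    expect_lt(pearsonExactP(0.85, 48), 1e-12)
    # monotone in |r| and in n
    rs <- seq(0.1, 0.9, 0.1)
    expect_true(all(diff(vapply(rs, pearsonExactP, numeric(1),
                                n = 20)) < 0))
    ns <- c(5, 10, 20, 40, 80)
    expect_true(all(diff(vapply(ns, function(n)
        pearsonExactP(0.5, n), numeric(1))) < 0))
    expect_error(pearsonExactP(0.5, 3), "n >= 4")
})

test_that("exact Pearson p matches a Monte-Carlo null at n = 5", {
    set.seed(16)
    B <- 400000
    x <- matrix(rnorm(5 * B), 5)
    y <- matrix(rnorm(5 * B), 5)
    xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
    rs <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
    pMC <- mean(abs(rs) >= 0.9)
    se <- sqrt(pMC * (1 - pMC) / B)
    expect_lt(abs(pearsonExactP(0.9, 5) - pMC), 3 * se)
})

test_that("permutation test matches exhaustive enumeration on 4 layers", {
    pk <- c(10, -20, 35, 30)
    ex <- permutationTestLayerIndex(pk, 1:4, exhaustive = TRUE)
    # brute-force enumeration oracle
    perms <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
    perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
    rs <- apply(perms, 1, function(r) cor(as.numeric(r), pk))
    obs <- cor(1:4, pk)
    expect_equal(nrow(perms), 24)
    expect_equal(ex$p, mean(abs(rs) >= abs(obs) - 1e-12))
    expect_equal(sort(ex$nullR), sort(rs), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # sampled version converges to the exhaustive value
    sam <- permutationTestLayerIndex(pk, 1:4, K = 20000, seed = 1)
    expect_lt(abs(sam$p - ex$p), 0.02)
})

test_that("a perfect ordering sits at the permutation floor", {
    pk <- 25 * (1:12) + c(0.01 * (1:12))          # strictly increasing
    res <- permutationTestLayerIndex(pk, 1:12, K = 999, seed = 2)
    expect_equal(res$p, 1 / 1000)
    # reproducibility under a fixed seed
    res2 <- permutationTestLayerIndex(pk, 1:12, K = 999, seed = 2)
    expect_identical(res$p, res2$p)
    expect_identical(res$nullR, res2$nullR)
})

test_that("electrode bootstrap is consistent and seed-stable", {
    x <- c(0.2, 0.25, 0.3, 0.22, 0.28, 0.35, 0.19, 0.27)
    b <- bootstrapElectrodeMeans(x, B = 4000, seed = 3)
    expect_equal(mean(b$bootMeans), mean(x),
                 tolerance = 3 * sd(x) / sqrt(length(x) * 4000) * 50)
    expect_lt(b$p, 0.01)                          # clearly above zero
    b2 <- bootstrapElectrodeMeans(x, B = 4000, seed = 3)
    expect_identical(b$p, b2$p)
    # all-equal electrodes: every resample mean is that constant
    bc <- bootstrapElectrodeMeans(rep(0.4, 5), B = 500, seed = 4)
    expect_true(all(bc$bootMeans == 0.4))
    expect_warning(bootstrapElectrodeMeans(x, B = 50), "100")
    # matrix input: one row per layer
    m <- rbind(x, x - 0.25)
    bm <- bootstrapElectrodeMeans(m, B = 2000, seed = 5)
    expect_equal(nrow(bm), 2)
    expect_lt(bm$p[1], 0.05)
    expect_gt(bm$p[2], 0.05)
})

test_that("BH-FDR matches the textbook step-up enumeration", {
    p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205,
           0.212, 0.36)
    got <- bhFdr(p, q = 0.05)
    # brute-force step-up oracle
    n <- length(p)
    ord <- order(p)
    stepup <- p[ord] * n / seq_len(n)
    qv <- rev(cummin(rev(stepup)))
    qOracle <- numeric(n); qOracle[ord] <- pmin(qv, 1)
    expect_equal(got$qValues, qOracle, tolerance = 1e-12)
    expect_equal(got$reject, qOracle < 0.05)
    expect_true(bhFdr(0.005, 0.01)$reject)
    expect_false(any(bhFdr(rep(1, 7), 0.05)$reject))
    expect_length(bhFdr(numeric())$qValues, 0)
})

test_that("Levene spread test is location-invariant and powered", {
    a <- c(-40, -10, 0, 15, 30, 55)
    expect_equal(levenePeakLagSpread(a, a + 500)$p, 1, tolerance = 1e-12)
    # 10x spread difference with n = 48 per group is detected
    set.seed(17)
    pows <- vapply(1:5, function(i) {
        g1 <- rnorm(48, sd = 100); g2 <- rnorm(48, sd = 10)
        levenePeakLagSpread(g1, g2)$p
    }, numeric(1))
    expect_true(all(pows < 0.01))
    # 6-point toy against the textbook formula
    x <- c(1, 3, 8); y <- c(2, 4, 11)
    got <- levenePeakLagSpread(x, y)
    dx <- abs(x - mean(x)); dy <- abs(y - mean(y))
    k <- 2; N <- 6
    num <- (N - k) * (3 * (mean(dx) - mean(c(dx, dy)))^2 +
                      3 * (mean(dy) - mean(c(dx, dy)))^2)
    den <- (k - 1) * (sum((dx - mean(dx))^2) + sum((dy - mean(dy))^2))
    expect_equal(got$F, num / den, tolerance = 1e-12)
    expect_equal(got$p, pf(num / den, 1, 4, lower.tail = FALSE),
                 tolerance = 1e-12)
})

test_that("Levene test agrees with an established implementation", {
    skip_if_not_installed("car")
    set.seed(18)
    a <- rnorm(20, sd = 3); b <- rnorm(25, sd = 1)
    got <- levenePeakLagSpread(a, b)
    ref <- car::leveneTest(c(a, b),
                           factor(rep(1:2, c(20, 25))), center = mean)
    expect_equal(got$F, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(got$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("paired layer contrast handles identical and shifted inputs", {
    set.seed(19)
    a <- matrix(rnorm(5 * 10), 5, 10)
    same <- pairedTTestLayers(a, a)
    expect_true(all(same$t == 0))
    expect_true(all(same$p == 1))
    expect_false(any(same$reject))
    # constant nonzero shift with zero noise: degenerate, flagged
    degen <- pairedTTestLayers(a, a + 5)
    expect_true(all(degen$degenerate))
    expect_true(all(is.na(degen$p)))
    expect_error(pairedTTestLayers(a[, 1:2], a[, 1:2]), "3 electrode")
})

test_that("paired layer contrast detects a one-SD shift", {
    # 40 electrodes, shift = 1 SD: rejection rate across seeds > 80%
    rej <- unlist(lapply(1:6, function(s) {
        set.seed(s)
        a <- matrix(rnorm(4 * 40, sd = 50), 4, 40)
        b <- a + 50 + matrix(rnorm(4 * 40, sd = 50), 4, 40)
        pairedTTestLayers(a, b, q = 0.01)$reject
    }))
    expect_gt(mean(rej), 0.8)
})
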