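test_that("windowing counts, discards remainders and bounds correlations", {
    set.seed(3)
    ts <- regionTimeSeries(matrix(rnorm(6 * 230), 6, 230,
                                  dimnames = list(paste0("R", 1:6), NULL)))
    expect_length(partitionWindows(ts, 10)@windows, 23)
    expect_length(partitionWindows(ts, 28)@windows, 8)   # 6 points dropped
    W <- partitionWindows(ts, 10)@windows[[1]]
    expect_equal(W, t(W))
    expect_equal(unname(diag(W)), rep(1, 6))
    expect_true(all(abs(W) <= 1))
    ## two perfectly correlated regions stay at 1 in every window
    x <- matrix(rnorm(2 * 60), 2, 60); x[2, ] <- 2 * x[1, ] + 5
    rownames(x) <- c("A", "B")
    wc <- partitionWindows(regionTimeSeries(x), 10)
    for (W in wc@windows) expect_equal(W["A", "B"], 1)
    ## constant region: zeroed with a warning
    y <- matrix(rnorm(3 * 30), 3, 30, dimnames = list(c("A", "B", "C"), NULL))
    y[2, ] <- 7
    ws <- capture_warnings(wc2 <- partitionWindows(regionTimeSeries(y), 10))
    expect_match(ws, "constant region", all = TRUE)
    expect_length(ws, 3)                 # one warning per window
    expect_true(all(wc2@windows[[1]]["B", c("A", "C")] == 0))
    expect_error(partitionWindows(ts, 2), "at least 3")
    expect_error(partitionWindows(ts, 200), "fewer than 2 windows")
})

test_that("regional variability hits its boundary cases exactly", {
    lab <- paste0("R", 1:4)
    base <- matrix(c(1, .5, .2, .1,
                     .5, 1, .3, .2,
                     .2, .3, 1, .4,
                     .1, .2, .4, 1), 4, 4, dimnames = list(lab, lab))
    ## identical profiles in every window: V = 0
    wc <- wcFromWindows(list(base, base, base))
    expect_equal(unname(regionalVariability(wc)), rep(0, 4))
    ## two windows with anticorrelated profiles: V = 2
    flipped <- -base; diag(flipped) <- 1
    wc2 <- wcFromWindows(list(base, flipped))
    expect_equal(unname(regionalVariability(wc2, "R1")), 2)
    expect_error(regionalVariability(wcFromWindows(list(base))),
                 "2 windows")
})

test_that("three windows with pairwise profile correlations (1,0,0) give 2/3", {
    ## region 1's profile: equal in windows 1 and 2, orthogonal in 3
    p1 <- c(0.8, 0.6, -0.8, -0.6)        # centred, so cor() is exact
    p3 <- c(0.6, -0.8, 0.6, -0.8)        # orthogonal to p1
    mk <- function(p) {
        W <- diag(5); W[1, 2:5] <- p; W[2:5, 1] <- p
        dimnames(W) <- list(paste0("R", 1:5), paste0("R", 1:5))
        W
    }
    wc <- wcFromWindows(list(mk(p1), mk(p1), mk(p3)))
    expect_equal(unname(regionalVariability(wc, "R1")), 1 - 1 / 3)
})

test_that("variability matches the brute-force pairwise oracle exactly", {
    set.seed(17)
    for (rep in 1:10) {
        windows <- lapply(1:4, function(i) {
            x <- matrix(rnorm(6 * 15), 6, 15,
                        dimnames = list(paste0("R", 1:6), NULL))
            stats::cor(t(x))
        })
        wc <- wcFromWindows(windows)
        v <- regionalVariability(wc)
        for (k in 1:6)
            expect_equal(unname(v[k]), bruteVariability(windows, k))
    }
})

test_that("variability is invariant to rescaling and window order", {
    set.seed(23)
    x <- matrix(rnorm(8 * 120), 8, 120,
                dimnames = list(paste0("R", 1:8), NULL))
    ts <- regionTimeSeries(x)
    v <- regionalVariability(partitionWindows(ts, 20))
    ## per-region affine rescaling of the BOLD series
    ts2 <- regionTimeSeries(x * runif(8, 0.5, 3) + rnorm(8))
    expect_equal(regionalVariability(partitionWindows(ts2, 20)), v)
    ## permuting window order leaves the pair mean unchanged
    wc <- partitionWindows(ts, 20)
    wc_perm <- wcFromWindows(wc@windows[sample(length(wc@windows))], 20L)
    expect_equal(regionalVariability(wc_perm), v)
    expect_true(all(v >= 0 & v <= 2))
})

test_that("multiscale averaging and the consistency diagnostic behave", {
    set.seed(29)
    b <- simulateBOLD(nRegions = 30, T = 230, seed = 29)
    ## singleton length set reduces to the single-length computation
    v10 <- multiscaleVariability(b$ts, 10)
    expect_equal(variability(v10),
                 regionalVariability(partitionWindows(b$ts, 10)))
    expect_equal(windowLengths(v10), 10)
    expect_error(multiscaleVariability(b$ts, c(10, 300)), "300")
    ## duplicated length correlates perfectly with itself
    cc <- windowLengthConsistency(b$ts, c(14, 14))
    expect_equal(cc[1, 2], 1)
    ## without dynamics (or after shuffling time) the per-region V vector
    ## is estimation noise, so two lengths no longer agree
    set.seed(31)
    b0 <- simulateBOLD(nRegions = 84, T = 230, nStates = 1, seed = 31)
    v_a <- regionalVariability(partitionWindows(b0$ts, 14))
    shuffled <- regionTimeSeries(b0$ts@data[, sample(230)])
    v_b <- regionalVariability(partitionWindows(shuffled, 16))
    expect_lt(abs(cor(v_a, v_b)), 0.5)
})

test_that("hemispheric flip is an involution that swaps paired labels", {
    m <- matrix(rnorm(4 * 60), 4, 60)
    rownames(m) <- c("L_M1", "R_M1", "L_SPL", "R_SPL")
    ts <- regionTimeSeries(m, lesionSide = "L")
    ## right-lesion input passes through unchanged
    expect_equal(flipToLesionRight(ts, "R")@data, m)
    flipped <- flipToLesionRight(ts, "L")
    expect_equal(unname(flipped@data["L_M1", ]), unname(m["R_M1", ]))
    expect_equal(unname(flipped@data["R_SPL", ]), unname(m["L_SPL", ]))
    ## flipping twice restores the original
    twice <- flipToLesionRight(flipped, "L")
    expect_equal(twice@data, m)
    ## profiles flip the same way
    vp <- new("VariabilityProfile",
              values = c(L_M1 = 0.3, R_M1 = 0.9, L_SPL = 0.1, R_SPL = 0.2),
              windowLengths = 10, subnetworkMeans = numeric())
    vf <- flipToLesionRight(vp, "L")
    expect_equal(unname(variability(vf)["L_M1"]), 0.9)
    expect_equal(unname(variability(vf)["R_M1"]), 0.3)
    bad <- regionTimeSeries(matrix(rnorm(60), 1, 60,
                                   dimnames = list("L_Orphan", NULL)))
    expect_error(flipToLesionRight(bad, "L"), "unpaired")
})

test_that("subnetwork aggregation averages member regions", {
    map <- defaultSubnetworkMap()
    v <- rep(0.37, length(map)); names(v) <- names(map)
    vp <- new("VariabilityProfile", values = v, windowLengths = 10,
              subnetworkMeans = numeric())
    agg <- subnetworkAggregate(vp, map)
    expect_equal(unname(subnetworkMeans(agg)),
                 rep(0.37, 6))
    expect_setequal(names(subnetworkMeans(agg)),
                    c("SMA", "ATT", "AUD", "VIS", "DMN", "SUB"))
    ## a one-region subnetwork reports that region's value
    vp1 <- new("VariabilityProfile", values = c(L_X = 0.5, L_Y = 0.1),
               windowLengths = 10, subnetworkMeans = numeric())
    agg1 <- subnetworkAggregate(vp1, c(L_X = "A", L_Y = "B"))
    expect_equal(unname(subnetworkMeans(agg1)["A"]), 0.5)
    expect_error(subnetworkAggregate(vp1, c(L_X = "A")), "L_Y")
})

test_that("pre/post contrast flags injected regional increases", {
    regions <- paste0("R", 1:20)
    ## no change: nothing significant
    set.seed(41)
    pre <- matrix(rnorm(8 * 20, 1, 0.1), 8, 20,
                  dimnames = list(NULL, regions))
    expect_false(any(prePostRegionContrast(pre, pre)$significant))
    expect_false(any(prePostRegionContrast(pre, pre + rnorm(160, 0, 0.05),
                                           alpha = 0)$significant))
    ## power simulation: +delta on 3 designated regions, n = 8 subjects,
    ## delta = 2 x within-subject noise SD
    hits <- 0; total <- 0
    for (s in 1:50) {
        set.seed(1000 + s)
        noise_sd <- 0.05
        pre <- matrix(rnorm(8 * 20, 1, 0.1), 8, 20,
                      dimnames = list(NULL, regions))
        post <- pre + matrix(rnorm(8 * 20, 0, noise_sd), 8, 20)
        target <- c("R3", "R11", "R17")
        post[, target] <- post[, target] + 2 * noise_sd
        res <- prePostRegionContrast(pre, post, alpha = 0.01)
        hits <- hits + sum(res$significant[res$region %in% target])
        total <- total + 3
    }
    expect_gte(hits / total, 0.8)
    expect_error(prePostRegionContrast(pre, pre[, 1:10]), "same subjects")
})
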