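## Independent oracles and small fixture builders shared across tests.

## Guided/sham FMA-UE score matrices typed in directly from the bundled
## cohort, independently of the CSV reader.
guidedScores <- function() {
    rbind(c(24, 21, 22), c(22, 24, 24), c(19, 34, 28), c(22, 27, 32),
          c(13, 16, 27), c(17, 25, 25), c(16, 14, 18), c(41, 36, 40),
          c(36, 41, 48), c(20, 24, 26), c(25, 26, 26), c(23, 33, NA),
          c(25, 32, NA))
}

shamScores <- function() {
    rbind(c(28, 33, 24), c(20, 25, 21), c(24, 22, 22), c(15, 17, 16),
          c(17, 20, 20), c(13, 23, 20), c(34, 34, 37), c(34, 37, 35),
          c(20, 19, 28), c(33, 31, 50), c(31, 39, 35))
}

## Exact two-tailed signed-rank p-value by enumerating all 2^m sign
## assignments of the observed absolute-rank vector (m <= ~15).
exactSignedRankP <- function(d) {
    d <- d[d != 0]
    m <- length(d)
    r <- rank(abs(d))
    s_obs <- sum(r[d < 0])
    signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
    S <- apply(signs, 1L, function(neg) sum(r[neg]))
    lo <- mean(S <= s_obs)
    hi <- mean(S >= s_obs)
    min(1, 2 * min(lo, hi))
}

## Brute-force temporal variability: materialise every profile pair and
## average the correlations explicitly.
bruteVariability <- function(windows, k) {
    n <- length(windows)
    rs <- c()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        a <- windows[[i]][k, -k]
        b <- windows[[j]][k, -k]
        rs <- c(rs, stats::cor(a, b))
    }
    1 - mean(rs)
}

## Rank-based AUC of "flexible regions score higher".
rankAUC <- function(values, positive) {
    r <- rank(values)
    n1 <- sum(positive)
    n0 <- sum(!positive)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## A subject's worth of training sessions for the DR pipeline.
makeSessions <- function(seed, nSessions = 8, nTrials = 8, erd = 0.5,
                         lesionSide = "R") {
    set.seed(seed)
    seeds <- sample.int(1e6, nSessions)
    lapply(seeds, function(s)
        simulateEEG(nTrials = nTrials, erdRatio = erd,
                    lesionSide = lesionSide, seed = s))
}

## Windowed-connectivity object from a plain list of adjacency matrices.
wcFromWindows <- function(windows, L = 10L) {
    new("WindowedConnectivity", windowLength = as.integer(L),
        windows = windows)
}
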