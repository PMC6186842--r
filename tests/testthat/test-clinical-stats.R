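test_that("Friedman statistic matches the closed form on tie-free rows", {
    ## (1,2,3) repeated: every row ranks 1,2,3, no ties, chi2 = 6 at n=3,k=3
    m <- rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
    res <- friedmanTieCorrected(m)
    expect_equal(statistic(res), 6)
    expect_false(res@tieCorrected)
    expect_equal(degreesFreedom(res), 2)

    ## tie-free random tables: corrected == uncorrected closed form,
    ## and both agree with stats::friedman.test
    set.seed(101)
    for (i in 1:20) {
        n <- sample(5:12, 1); k <- sample(3:5, 1)
        m <- matrix(sample.int(1000, n * k), n, k)   # distinct values
        res <- friedmanTieCorrected(m)
        r <- t(apply(m, 1, rank))
        chi <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
        expect_equal(statistic(res), chi)
        expect_equal(statistic(res),
                     unname(stats::friedman.test(m)$statistic))
        expect_false(res@tieCorrected)
    }
})

test_that("Friedman handles ties like friedman.test and rejects bad input", {
    set.seed(7)
    for (i in 1:10) {
        m <- matrix(sample.int(4, 30, replace = TRUE), 10, 3)  # heavy ties
        if (any(apply(m, 1, function(x) length(unique(x))) == 1)) next
        expect_equal(statistic(friedmanTieCorrected(m)),
                     unname(stats::friedman.test(m)$statistic))
    }
    expect_error(friedmanTieCorrected(rbind(c(1, NA, 2), c(1, 2, 3))),
                 "complete-case")
    expect_error(friedmanTieCorrected(rbind(c(2, 2, 2), c(5, 5, 5))),
                 "degenerate")
    expect_error(friedmanTieCorrected(matrix(1:3, 1, 3)), "two subjects")
})

test_that("signed-rank Z follows the zero-exclusion negative-rank convention", {
    ## six all-increasing tie-free pairs: S = 0, Z = -10.5/sqrt(22.75)
    x <- c(10, 20, 30, 40, 50, 60)
    y <- x + c(1, 2, 3, 4, 5, 6)
    res <- wilcoxonSignedRank(x, y)
    expect_equal(statistic(res), -10.5 / sqrt(22.75))
    expect_equal(nUsed(res), 6L)

    ## zero differences drop out of m
    res2 <- wilcoxonSignedRank(c(1, 2, 3, 4), c(1, 3, 5, 7))
    expect_equal(nUsed(res2), 3L)
    expect_lt(statistic(res2), 0)   # increases give negative Z

    expect_error(wilcoxonSignedRank(1:4, 1:4), "all paired differences")
    expect_error(wilcoxonSignedRank(1:3, 1:4), "paired")
})

test_that("signed-rank normal p tracks the exact 2^m enumeration", {
    set.seed(33)
    for (i in 1:25) {
        m <- sample(6:10, 1)
        x <- rnorm(m)
        y <- x + sample(-3:5, m, replace = TRUE) + rnorm(m, sd = 0.1)
        d <- y - x
        if (all(d == 0)) next
        res <- wilcoxonSignedRank(x, y)
        ## S is recovered exactly from the statistic definition
        dd <- d[d != 0]; r <- rank(abs(dd)); mm <- length(dd)
        expect_equal(sum(r[dd < 0]),
                     statistic(res) *
                         sqrt(mm * (mm + 1) * (2 * mm + 1) / 24 -
                              sum(table(abs(dd))^3 - table(abs(dd))) / 48) +
                         mm * (mm + 1) / 4,
                     tolerance = 1e-10)
        ## normal approximation vs the discrete exact null: the worst-case
        ## gap at untied ranks is 0.099 at m = 6 falling to 0.050 at
        ## m = 10, so 0.7/m bounds it with margin for tied ranks
        expect_lt(abs(pValue(res) - exactSignedRankP(d)), 0.7 / m)
    }
})

test_that("Mann-Whitney U satisfies its symmetries", {
    set.seed(5)
    for (i in 1:15) {
        a <- sample.int(40, sample(4:12, 1), replace = TRUE)
        b <- sample.int(40, sample(4:12, 1), replace = TRUE)
        ua <- statistic(mannWhitneyU(a, b))
        ub <- statistic(mannWhitneyU(b, a))
        expect_equal(ua + ub, length(a) * length(b))
        ## invariant under strictly monotone transforms of pooled scores
        f <- function(x) exp(x / 10) + 3 * x
        expect_equal(ua, statistic(mannWhitneyU(f(a), f(b))))
        expect_equal(pValue(mannWhitneyU(a, b)),
                     pValue(mannWhitneyU(f(a), f(b))))
        ## agreement with the tie-corrected normal wilcox.test
        expect_equal(pValue(mannWhitneyU(a, b)),
                     stats::wilcox.test(a, b, exact = FALSE,
                                        correct = FALSE)$p.value)
    }
    ident <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
    expect_equal(statistic(ident), 4.5)        # n1 n2 / 2
    expect_equal(pValue(ident), 1)
    expect_equal(statistic(mannWhitneyU(c(1, 2), c(3, 4))), 0)
    expect_error(mannWhitneyU(numeric(), 1:3), "non-empty")
})

test_that("Scheirer-Ray-Hare matches brute-force SS-on-ranks", {
    ## 2x2 balanced toy table with one dominant cell
    score <- c(1, 2, 2, 3, 1, 3, 20, 25, 22, 24, 2, 1)
    grp <- rep(c("a", "b"), each = 6)
    tim <- rep(rep(c("t1", "t2"), each = 3), 2)
    res <- scheirerRayHare(score, tim, grp)

    ## independent spreadsheet-style computation on the ranks
    r <- rank(score)
    N <- length(r)
    ms_total <- sum((r - mean(r))^2) / (N - 1)
    cellmean <- tapply(r, list(grp, tim), mean)
    gmean <- rowMeans(cellmean); tmean <- colMeans(cellmean)
    ss_g <- 6 * sum((gmean - mean(r))^2)
    ss_t <- 6 * sum((tmean - mean(r))^2)
    ss_cells <- 3 * sum((cellmean - mean(r))^2)
    ss_int <- ss_cells - ss_g - ss_t
    expect_equal(statistic(res$group), ss_g / ms_total)
    expect_equal(statistic(res$time), ss_t / ms_total)
    expect_equal(statistic(res$interaction), ss_int / ms_total)

    ## all-equal scores: H = 0 everywhere
    res0 <- scheirerRayHare(rep(5, 12), tim, grp)
    for (e in res0) expect_equal(statistic(e), 0)

    expect_error(scheirerRayHare(1:6, rep("t1", 6), rep(c("a", "b"), 3)),
                 "two levels")
})

test_that("Scheirer-Ray-Hare on the cohort finds no significant effects", {
    d <- clinicalData(clinicalFixture())
    long <- data.frame(
        score = c(d$fma_pre, d$fma_post, d$fma_6mo),
        time = rep(c("pre", "post", "6mo"), each = nrow(d)),
        group = rep(d$group, 3))
    res <- scheirerRayHare(long$score, long$time, long$group)
    expect_gt(pValue(res$interaction), 0.05)
    expect_gt(pValue(res$group), 0.05)
    expect_gt(pValue(res$time), 0.05)
})

test_that("paired t handles the textbook cases", {
    expect_error(pairedT(c(1, 2, 3, 4), c(2, 3, 4, 5)), "zero variance")
    same <- pairedT(c(3, 1, 4, 1), c(3, 1, 4, 1))
    expect_equal(statistic(same), 0)
    expect_equal(pValue(same), 1)
    res <- pairedT(c(0, 0, 0, 0), c(1, 2, 3, 4))
    expect_equal(statistic(res), 2.5 / (sd(1:4) / 2))
    expect_equal(degreesFreedom(res), 3)
})

test_that("MCID responders are order- and relabel-invariant", {
    tab <- clinicalFixture()
    base <- mcidResponders(tab, "pre_post")
    ## permuting subject rows changes nothing
    d <- clinicalData(tab)
    set.seed(2)
    perm <- clinicalTable(d[sample(nrow(d)), ])
    expect_equal(mcidResponders(perm, "pre_post")$proportion,
                 base$proportion)
    ## swapping group labels swaps the rows of the summary
    d2 <- d
    d2$group <- ifelse(d$group == "guided", "sham", "guided")
    swapped <- mcidResponders(clinicalTable(d2), "pre_post")
    expect_equal(swapped$proportion, rev(base$proportion))
    ## a threshold above the scale maximum leaves no responders
    high <- mcidResponders(tab, "pre_post", threshold = 67)
    expect_true(all(high$n_exceeding == 0))
    ## missing 6-month endpoints shrink the eligible denominator
    m6 <- mcidResponders(tab, "pre_6mo")
    expect_equal(m6$n_eligible[m6$group == "guided"], 11)
})
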