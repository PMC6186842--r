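## Tie-corrected rank statistics matching the SPSS conventions used for the
## clinical outcome analysis, plus the MCID responder summary.

.newTestResult <- function(method, statistic, df, p, n, tie) {
    new("TestResult", method = method, statistic = unname(statistic),
        df = as.numeric(df), pValue = unname(p), nUsed = as.integer(n),
        tieCorrected = tie)
}

## Sum of (t^3 - t) over tie groups of a vector.
.tieTerm <- function(x) {
    t <- table(x)
    sum(t^3 - t)
}

#' Tie-corrected Friedman test
#'
#' Friedman's rank test for k repeated measurements on n subjects, with
#' within-row mid-ranks and the tie-correction divisor
#' \eqn{C = 1 - \sum(t^3 - t) / (n (k^3 - k))} applied to the classical
#' chi-square statistic, as SPSS computes it.  Rows with any missing entry
#' must be removed by the caller (complete-case analysis).
#'
#' @param scores numeric matrix, subjects in rows, time points in columns;
#'   no missing entries.
#' @return a \code{\linkS4class{TestResult}} with a chi-square statistic on
#'   \code{k - 1} degrees of freedom.
#' @examples
#' fma <- clinicalData(clinicalFixture())
#' g <- as.matrix(fma[fma$group == "guided", c("fma_pre", "fma_post", "fma_6mo")])
#' friedmanTieCorrected(g[stats::complete.cases(g), ])
#' @export
friedmanTieCorrected <- function(scores) {
    scores <- as.matrix(scores)
    if (anyNA(scores))
        stop("missing entries in 'scores'; drop incomplete rows first ",
             "(complete-case filtering)")
    n <- nrow(scores)
    k <- ncol(scores)
    if (k < 2L) stop("need at least two time points (columns)")
    if (n < 2L) stop("need at least two subjects (rows)")
    ranks <- t(apply(scores, 1L, rank))        # within-row mid-ranks
    chi_uncorrected <- 12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) -
        3 * n * (k + 1)
    tie_sum <- sum(apply(scores, 1L, .tieTerm))
    C <- 1 - tie_sum / (n * (k^3 - k))
    if (C <= 0)
        stop("degenerate input: every row is constant (tie correction ",
             "divisor is zero)")
    stat <- chi_uncorrected / C
    .newTestResult("Friedman chi-square (tie-corrected)", stat, k - 1,
                   stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
                   n, tie_sum > 0)
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' Paired signed-rank test in the zero-exclusion convention: zero
#' differences are dropped, absolute differences get mid-ranks, and
#' \eqn{S} is the sum of the ranks of negative differences
#' (\eqn{d = y - x}), so the Z statistic is negative when scores increase.
#' The variance carries the tie correction \eqn{\sum(t^3 - t)/48}; no
#' continuity correction is applied.  Pairs with a missing value must be
#' dropped by the caller.
#'
#' @param x,y paired numeric vectors of equal length, no missing values.
#' @return a \code{\linkS4class{TestResult}} with a Z statistic and the
#'   two-tailed normal p-value; \code{nUsed} counts nonzero differences.
#' @export
wilcoxonSignedRank <- function(x, y) {
    if (length(x) != length(y)) stop("'x' and 'y' must be paired")
    if (anyNA(x) || anyNA(y))
        stop("missing values in pairs; drop incomplete pairs first")
    d <- y - x
    d <- d[d != 0]                              # zero-exclusion
    m <- length(d)
    if (m == 0L)
        stop("degenerate input: all paired differences are zero")
    r <- rank(abs(d))
    S <- sum(r[d < 0])
    mu <- m * (m + 1) / 4
    tie_sum <- .tieTerm(abs(d))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - tie_sum / 48
    z <- (S - mu) / sqrt(sigma2)
    .newTestResult("Wilcoxon signed-rank Z", z, NA_real_,
                   2 * stats::pnorm(-abs(z)), m, tie_sum > 0)
}

#' Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' Two-sample rank-sum test on pooled mid-ranks.  \code{U} is reported for
#' the first sample; the normal approximation uses the tie-corrected
#' variance \eqn{n_1 n_2 / 12 [(N + 1) - \sum(t^3 - t) / (N (N - 1))]},
#' without continuity correction.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return a \code{\linkS4class{TestResult}}; the statistic is \eqn{U_a}.
#' @export
mannWhitneyU <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
    N <- n1 + n2
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    tie_sum <- .tieTerm(c(a, b))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_sum / (N * (N - 1)))
    if (sigma2 <= 0)
        stop("degenerate input: all pooled observations identical")
    z <- (U - n1 * n2 / 2) / sqrt(sigma2)
    .newTestResult("Mann-Whitney U", U, NA_real_,
                   2 * stats::pnorm(-abs(z)), N, tie_sum > 0)
}

#' Scheirer-Ray-Hare test
#'
#' Nonparametric two-way ANOVA on ranks: all observations are ranked
#' together (mid-ranks), a standard two-way ANOVA decomposition is carried
#' out on the ranks, and each effect's H statistic is its sum of squares
#' divided by the total mean square \eqn{MS_{total} = SS_{total} / (N - 1)};
#' H is referred to the chi-square distribution on the effect's degrees of
#' freedom.  Unbalanced cells are handled through the sequential ANOVA fit.
#'
#' @param score numeric response.
#' @param time_factor,group_factor factors (or coercible) with at least two
#'   levels each.
#' @return a named list of three \code{\linkS4class{TestResult}}s:
#'   \code{group}, \code{time} and \code{interaction}.
#' @export
scheirerRayHare <- function(score, time_factor, group_factor) {
    ok <- stats::complete.cases(score, time_factor, group_factor)
    score <- score[ok]
    tf <- factor(time_factor[ok])
    gf <- factor(group_factor[ok])
    if (nlevels(tf) < 2L || nlevels(gf) < 2L)
        stop("each factor needs at least two levels")
    N <- length(score)
    r <- rank(score)
    ms_total <- sum((r - mean(r))^2) / (N - 1)
    fit <- stats::aov(r ~ gf * tf)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    df <- summary(fit)[[1]][["Df"]]
    eff <- function(i, label) {
        if (ms_total == 0)
            return(.newTestResult(paste("Scheirer-Ray-Hare H:", label),
                                  0, df[i], 1, N, TRUE))
        H <- ss[i] / ms_total
        .newTestResult(paste("Scheirer-Ray-Hare H:", label), H, df[i],
                       stats::pchisq(H, df = df[i], lower.tail = FALSE),
                       N, TRUE)
    }
    list(group = eff(1L, "group"), time = eff(2L, "time"),
         interaction = eff(3L, "group x time"))
}

#' Paired t-test
#'
#' Thin wrapper around \code{stats::t.test(..., paired = TRUE)} returning
#' the package's \code{\linkS4class{TestResult}}, with an explicit error on
#' zero-variance differences.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @return a \code{\linkS4class{TestResult}} with a t statistic on
#'   \code{n - 1} degrees of freedom.
#' @export
pairedT <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 2L) stop("need at least two complete pairs")
    d <- y - x
    if (stats::sd(d) == 0) {
        if (all(d == 0))
            return(.newTestResult("Paired t", 0, n - 1, 1, n, FALSE))
        stop("degenerate input: paired differences have zero variance")
    }
    tt <- stats::t.test(y, x, paired = TRUE)
    .newTestResult("Paired t", tt$statistic, tt$parameter, tt$p.value,
                   n, FALSE)
}

## Round half away from zero, the convention behind the printed percentages.
.roundHalfUp <- function(x, digits = 1) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' MCID responder analysis
#'
#' Counts, per group, the subjects whose FMA-UE change from baseline
#' reaches the minimal clinically important difference (MCID): a subject
#' responds when \code{later - earlier >= threshold}.  Subjects missing the
#' later endpoint are excluded from the eligible denominator.
#'
#' @param table a \code{\linkS4class{ClinicalTable}}.
#' @param contrast \code{"pre_post"} (baseline vs immediately after) or
#'   \code{"pre_6mo"} (baseline vs six-month follow-up).
#' @param threshold MCID on the FMA-UE scale; the study value is 4 points.
#' @return a \code{data.frame} with one row per group: \code{n_eligible},
#'   \code{n_exceeding}, \code{proportion}, and \code{percent} rounded half
#'   away from zero to one decimal.
#' @examples
#' mcidResponders(clinicalFixture(), "pre_post")
#' @export
mcidResponders <- function(table, contrast = c("pre_post", "pre_6mo"),
                           threshold = 4) {
    stopifnot(is(table, "ClinicalTable"))
    contrast <- match.arg(contrast)
    d <- clinicalData(table)
    later_col <- if (contrast == "pre_post") "fma_post" else "fma_6mo"
    groups <- sort(unique(d$group))
    out <- lapply(groups, function(g) {
        sub <- d[d$group == g, ]
        if (nrow(sub) == 0L) stop("empty group: ", g)
        ok <- !is.na(sub[[later_col]]) & !is.na(sub$fma_pre)
        change <- sub[[later_col]][ok] - sub$fma_pre[ok]
        n_el <- sum(ok)
        n_ex <- sum(change >= threshold)
        data.frame(group = g, contrast = contrast, n_eligible = n_el,
                   n_exceeding = n_ex, proportion = n_ex / n_el,
                   percent = .roundHalfUp(100 * n_ex / n_el, 1),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Full clinical report for a cohort table
#'
#' Runs the complete clinical analysis: per-group tie-corrected Friedman
#' across the three time points (complete cases), Wilcoxon signed-rank
#' post-hoc contrasts in the guided group, the baseline Mann-Whitney
#' between-group comparison, the Scheirer-Ray-Hare two-way rank ANOVA, and
#' the MCID responder proportions for both contrasts.
#'
#' @param table a \code{\linkS4class{ClinicalTable}}.
#' @param mcid MCID threshold on the FMA-UE scale.
#' @return a nested list of \code{\linkS4class{TestResult}} objects and
#'   responder data frames, suitable for \code{\link{writeReport}}.
#' @export
clinicalStatsReport <- function(table, mcid = 4) {
    stopifnot(is(table, "ClinicalTable"))
    d <- clinicalData(table)
    cols <- c("fma_pre", "fma_post", "fma_6mo")
    per_group <- function(g) {
        m <- as.matrix(d[d$group == g, cols])
        friedmanTieCorrected(m[stats::complete.cases(m), , drop = FALSE])
    }
    guided <- d[d$group == "guided", ]
    cc6 <- !is.na(guided$fma_6mo)
    long <- data.frame(
        score = unlist(d[cols], use.names = FALSE),
        time = rep(c("pre", "post", "6mo"), each = nrow(d)),
        group = rep(d$group, times = 3))
    list(
        friedman = list(guided = per_group("guided"),
                        sham = per_group("sham")),
        wilcoxon = list(
            pre_post = wilcoxonSignedRank(guided$fma_pre, guided$fma_post),
            pre_6mo = wilcoxonSignedRank(guided$fma_pre[cc6],
                                         guided$fma_6mo[cc6]),
            post_6mo = wilcoxonSignedRank(guided$fma_post[cc6],
                                          guided$fma_6mo[cc6])),
        baseline_between_group = mannWhitneyU(
            d$fma_pre[d$group == "guided"], d$fma_pre[d$group == "sham"]),
        scheirer_ray_hare = scheirerRayHare(long$score, long$time,
                                            long$group),
        mcid = rbind(mcidResponders(table, "pre_post", mcid),
                     mcidResponders(table, "pre_6mo", mcid)))
}
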