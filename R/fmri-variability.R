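## Temporal variability of dynamic functional connectivity: windowing,
## Pearson adjacency, the per-region variability statistic, multi-length
## averaging, hemispheric flip, subnetwork aggregation and the pre/post
## regional contrast.

#' Construct a RegionTimeSeries
#'
#' @param data region x time numeric matrix; rownames are region labels.
#' @param trSeconds repetition time in seconds.
#' @param subjectId,session,lesionSide metadata; session is \code{"pre"},
#'   \code{"post"} or \code{"unknown"}.
#' @return a \code{\linkS4class{RegionTimeSeries}}.
#' @export
regionTimeSeries <- function(data, trSeconds = 2, subjectId = "subject",
                             session = "unknown", lesionSide = "unknown") {
    new("RegionTimeSeries", data = as.matrix(data), trSeconds = trSeconds,
        subjectId = subjectId, session = session, lesionSide = lesionSide)
}

## Pearson correlation matrix with zero-variance columns mapped to 0
## rather than NA, with a single warning.
.safeCor <- function(x) {
    const <- apply(x, 2L, stats::sd) == 0
    W <- suppressWarnings(stats::cor(x))
    if (any(const)) {
        warning("constant region(s) within a window; their correlations ",
                "are set to 0: ",
                paste(colnames(x)[const], collapse = ", "))
        W[const, ] <- 0
        W[, const] <- 0
    }
    diag(W) <- 1
    W
}

#' Cut a BOLD series into windowed Pearson adjacency matrices
#'
#' Partitions the time axis into consecutive non-overlapping windows of
#' \code{L} time points starting at the first volume; a trailing remainder
#' shorter than \code{L} is discarded.  Within each window the region x
#' region Pearson correlation matrix is computed.  Regions constant within
#' a window get zero correlations (with a warning) instead of undefined
#' values.
#'
#' @param ts a \code{\linkS4class{RegionTimeSeries}}.
#' @param L window length in time points (>= 3).
#' @param offset index of the first volume used (0 = start).
#' @return a \code{\linkS4class{WindowedConnectivity}}.
#' @export
partitionWindows <- function(ts, L, offset = 0L) {
    stopifnot(is(ts, "RegionTimeSeries"))
    L <- as.integer(L)
    if (L < 3L) stop("window length must be at least 3 time points")
    x <- ts@data[, (offset + 1L):ncol(ts@data), drop = FALSE]
    n_win <- floor(ncol(x) / L)
    if (n_win < 2L)
        stop("fewer than 2 windows of length ", L, " fit in ", ncol(x),
             " time points")
    windows <- lapply(seq_len(n_win), function(i) {
        seg <- x[, ((i - 1L) * L + 1L):(i * L), drop = FALSE]
        .safeCor(t(seg))
    })
    new("WindowedConnectivity", windowLength = L, windows = windows)
}

#' Temporal variability of one region (or all regions)
#'
#' The variability of region k is one minus the mean Pearson correlation
#' between its connectivity profiles (its adjacency row with the self
#' entry removed) over all unordered window pairs:
#' \deqn{V_k = 1 - \overline{\mathrm{corr}(W_{i,k}, W_{j,k})}, \quad i \ne j.}
#' Identical profiles across windows give 0; two anticorrelated profiles
#' give the upper bound 2.
#'
#' @param wc a \code{\linkS4class{WindowedConnectivity}} with >= 2 windows.
#' @param region region label or index; \code{NULL} computes all regions.
#' @return named numeric vector of V values (scalar if \code{region} was
#'   given).
#' @export
regionalVariability <- function(wc, region = NULL) {
    stopifnot(is(wc, "WindowedConnectivity"))
    n <- length(wc@windows)
    if (n < 2L) stop("need at least 2 windows")
    labels <- rownames(wc@windows[[1]])
    idx <- if (is.null(region)) seq_along(labels)
           else if (is.character(region)) match(region, labels)
           else as.integer(region)
    if (anyNA(idx)) stop("unknown region: ", region)
    out <- vapply(idx, function(k) {
        profiles <- vapply(wc@windows, function(W) W[k, -k],
                           numeric(length(labels) - 1L))
        C <- suppressWarnings(stats::cor(profiles))
        pair_r <- C[upper.tri(C)]            # unordered window pairs i < j
        if (anyNA(pair_r)) {
            warning("zero-variance connectivity profile in region '",
                    labels[k], "'; affected pair correlation(s) set to 0")
            pair_r[is.na(pair_r)] <- 0
        }
        1 - mean(pair_r)
    }, numeric(1))
    names(out) <- labels[idx]
    out
}

#' Variability averaged over multiple window lengths
#'
#' Computes the per-region variability at each window length and averages
#' with equal weights, removing the arbitrariness of a single window
#' length.  The study range is 10 to 30 time points in steps of 2
#' (20--60 s at TR = 2 s).
#'
#' @param ts a \code{\linkS4class{RegionTimeSeries}}.
#' @param lengths integer window lengths in time points.
#' @return a \code{\linkS4class{VariabilityProfile}}.
#' @export
multiscaleVariability <- function(ts, lengths = seq(10L, 30L, 2L)) {
    stopifnot(is(ts, "RegionTimeSeries"))
    Tn <- ncol(ts@data)
    bad <- lengths[floor(Tn / lengths) < 2L | lengths < 3L]
    if (length(bad))
        stop("window length(s) not usable with T = ", Tn, ": ",
             paste(bad, collapse = ", "))
    per_length <- vapply(lengths, function(L)
        regionalVariability(partitionWindows(ts, L)),
        numeric(nrow(ts@data)))
    new("VariabilityProfile", values = rowMeans(per_length),
        windowLengths = as.numeric(lengths), subnetworkMeans = numeric())
}

#' Consistency of variability across window lengths
#'
#' Pearson correlation between the per-region variability vectors computed
#' at each pair of window lengths — the diagnostic used to justify
#' averaging across lengths.
#'
#' @param ts a \code{\linkS4class{RegionTimeSeries}}.
#' @param lengths two or more window lengths.
#' @return symmetric correlation matrix with one row per length.
#' @export
windowLengthConsistency <- function(ts, lengths = seq(10L, 30L, 2L)) {
    if (length(lengths) < 2L) stop("need at least two window lengths")
    V <- vapply(lengths, function(L)
        regionalVariability(partitionWindows(ts, L)),
        numeric(nrow(ts@data)))
    colnames(V) <- as.character(lengths)
    stats::cor(V)
}

.flipLabels <- function(labels) {
    side <- substr(labels, 1L, 2L)
    if (!all(side %in% c("L_", "R_")))
        stop("region labels must carry an 'L_'/'R_' hemisphere prefix; ",
             "offending: ",
             paste(labels[!side %in% c("L_", "R_")], collapse = ", "))
    flipped <- ifelse(side == "L_", sub("^L_", "R_", labels),
                      sub("^R_", "L_", labels))
    miss <- setdiff(flipped, labels)
    if (length(miss))
        stop("unpaired region label(s): no partner for ",
             paste(miss, collapse = ", "))
    match(flipped, labels)
}

#' @rdname flipToLesionRight
setMethod("flipToLesionRight", "RegionTimeSeries",
    function(x, lesionSide) {
        if (missing(lesionSide)) lesionSide <- x@lesionSide
        if (!lesionSide %in% c("L", "R"))
            stop("lesion side must be 'L' or 'R'")
        if (lesionSide == "R") return(x)
        perm <- .flipLabels(rownames(x@data))
        out <- x@data[perm, , drop = FALSE]
        rownames(out) <- rownames(x@data)
        x@data <- out
        x
    })

#' @rdname flipToLesionRight
setMethod("flipToLesionRight", "VariabilityProfile",
    function(x, lesionSide) {
        if (!lesionSide %in% c("L", "R"))
            stop("lesion side must be 'L' or 'R'")
        if (lesionSide == "R") return(x)
        perm <- .flipLabels(names(x@values))
        v <- x@values[perm]
        names(v) <- names(x@values)
        x@values <- v
        x
    })

#' Aggregate regional variability into subnetworks
#'
#' Unweighted mean variability per functional subnetwork (SMA, ATT, AUD,
#' VIS, DMN, SUB).
#'
#' @param profile a \code{\linkS4class{VariabilityProfile}}.
#' @param map named character vector or list mapping every region label to
#'   its subnetwork; see \code{\link{defaultSubnetworkMap}}.
#' @return the profile with \code{subnetworkMeans} filled in.
#' @export
subnetworkAggregate <- function(profile, map = defaultSubnetworkMap()) {
    stopifnot(is(profile, "VariabilityProfile"))
    map <- unlist(map)
    unmapped <- setdiff(names(profile@values), names(map))
    if (length(unmapped))
        stop("region(s) missing from the subnetwork map: ",
             paste(unmapped, collapse = ", "))
    grp <- map[names(profile@values)]
    means <- tapply(profile@values, grp, mean)
    profile@subnetworkMeans <- stats::setNames(as.numeric(means),
                                               names(means))
    profile
}

#' Pre/post regional variability contrast
#'
#' Per-region paired t-test of post- against pre-intervention variability
#' across matched subjects; regions with \code{p < alpha} are flagged.  No
#' multiple-comparison correction is applied by default (the study reports
#' uncorrected p < 0.01); Benjamini-Hochberg adjusted p-values are
#' available via \code{adjust = "BH"}.
#'
#' @param pre,post subject x region matrices of variability values with
#'   identical dimnames (or lists of \code{VariabilityProfile}s in matched
#'   subject order).
#' @param alpha significance level on the (possibly adjusted) p-value.
#' @param adjust \code{"none"} or \code{"BH"}.
#' @return \code{data.frame} with one row per region: mean change, t, df,
#'   p, adjusted p and the significance flag.
#' @export
prePostRegionContrast <- function(pre, post, alpha = 0.01,
                                  adjust = c("none", "BH")) {
    adjust <- match.arg(adjust)
    toMatrix <- function(x) {
        if (is.list(x) && all(vapply(x, is, logical(1), "VariabilityProfile")))
            x <- do.call(rbind, lapply(x, variability))
        as.matrix(x)
    }
    pre <- toMatrix(pre); post <- toMatrix(post)
    if (!identical(dim(pre), dim(post)) ||
        !identical(colnames(pre), colnames(post)))
        stop("pre and post must cover the same subjects and regions")
    res <- lapply(colnames(pre), function(rg) {
        d <- post[, rg] - pre[, rg]
        if (stats::sd(d) == 0)
            return(data.frame(region = rg, mean_change = mean(d),
                              t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                              df = length(d) - 1L,
                              p = if (mean(d) == 0) 1 else 0))
        tt <- stats::t.test(post[, rg], pre[, rg], paired = TRUE)
        data.frame(region = rg, mean_change = mean(d),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p = tt$p.value)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- if (adjust == "BH") stats::p.adjust(out$p, "BH")
                      else out$p
    out$significant <- out$p_adjusted < alpha
    out
}
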