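#' @import methods
NULL

#' Clinical outcome table
#'
#' Per-subject group membership, lesion side, and Fugl-Meyer Assessment
#' upper-extremity (FMA-UE, 0--66) scores at three time points: before the
#' intervention (\code{fma_pre}), immediately after (\code{fma_post}) and at
#' six-month follow-up (\code{fma_6mo}).  The six-month column may contain
#' missing values; baseline and post scores must be present for every
#' subject.  Optional demographic columns (\code{age_band}, \code{gender},
#' \code{stroke_type}, \code{onset_years}, \code{lesion_locations}) are
#' carried along untouched.
#'
#' @slot data a \code{data.frame} with one row per subject.
#'
#' @seealso \code{\link{readClinicalTable}}, \code{\link{clinicalFixture}},
#'   \code{\link{friedmanTieCorrected}}, \code{\link{mcidResponders}}
#' @export
setClass("ClinicalTable", representation(data = "data.frame"))

.validClinicalTable <- function(object) {
    d <- object@data
    msg <- character()
    required <- c("subject_id", "group", "lesion_side",
                  "fma_pre", "fma_post", "fma_6mo")
    missing_cols <- setdiff(required, names(d))
    if (length(missing_cols))
        return(paste("missing required column(s):",
                     paste(missing_cols, collapse = ", ")))
    if (anyDuplicated(d$subject_id))
        msg <- c(msg, "duplicate subject_id values")
    if (!all(d$group %in% c("guided", "sham")))
        msg <- c(msg, "group must be 'guided' or 'sham'")
    if (!all(d$lesion_side %in% c("L", "R", "unknown")))
        msg <- c(msg, "lesion_side must be 'L', 'R' or 'unknown'")
    for (col in c("fma_pre", "fma_post", "fma_6mo")) {
        v <- d[[col]]
        if (!is.numeric(v))
            msg <- c(msg, sprintf("%s must be numeric", col))
        else if (any(v < 0 | v > 66, na.rm = TRUE))
            msg <- c(msg, sprintf("%s outside the 0-66 FMA-UE range", col))
    }
    if (anyNA(d$fma_pre) || anyNA(d$fma_post))
        msg <- c(msg, "fma_pre and fma_post must be present for every subject")
    if (length(msg)) msg else TRUE
}
setValidity("ClinicalTable", .validClinicalTable)

#' Result of a single statistical test
#'
#' A light container for the rank-based and parametric tests in this
#' package: the test statistic, its degrees of freedom (\code{NA} for
#' Z- and U-statistics), the two-tailed p-value, the number of
#' observations actually used after dropping missing or zero entries,
#' and whether a tie correction entered the variance or divisor.
#'
#' @export
setClass("TestResult",
    representation(method = "character", statistic = "numeric",
                   df = "numeric", pValue = "numeric", nUsed = "integer",
                   tieCorrected = "logical"))

setValidity("TestResult", function(object) {
    if (length(object@pValue) == 1 && !is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
        return("pValue outside [0, 1]")
    TRUE
})

#' Epoched EEG recording
#'
#' Paired task/rest segments for each trial of a robot-hand training
#' session, recorded from the 16-electrode motor-area montage of the
#' international 10--20 system (C1--C6, Cz, FC1--FC4, FCz, CP1--CP4).
#' Each trial holds a task segment (action observation or motor imagery)
#' and a rest segment of equal duration, both channel x sample matrices.
#'
#' @slot channelLabels character vector of unique 10--20 labels, one per
#'   matrix row.
#' @slot samplingRate sampling rate in Hz.
#' @slot trials list; each element is \code{list(task =, rest =)} of
#'   channel x sample matrices.
#' @slot lesionSide \code{"L"}, \code{"R"} or \code{"unknown"}.
#' @export
setClass("EpochedEEG",
    representation(channelLabels = "character", samplingRate = "numeric",
                   trials = "list", lesionSide = "character"))

setValidity("EpochedEEG", function(object) {
    msg <- character()
    if (anyDuplicated(object@channelLabels))
        msg <- c(msg, "channel labels must be unique")
    nch <- length(object@channelLabels)
    for (i in seq_along(object@trials)) {
        tr <- object@trials[[i]]
        if (!all(c("task", "rest") %in% names(tr))) {
            msg <- c(msg, sprintf("trial %d lacks task/rest segments", i))
            next
        }
        if (nrow(tr$task) != nch || nrow(tr$rest) != nch)
            msg <- c(msg, sprintf("trial %d: rows do not match channel labels", i))
        if (ncol(tr$task) != ncol(tr$rest))
            msg <- c(msg, sprintf("trial %d: task and rest segment lengths differ", i))
    }
    if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a positive scalar")
    if (!object@lesionSide %in% c("L", "R", "unknown"))
        msg <- c(msg, "lesionSide must be 'L', 'R' or 'unknown'")
    if (length(msg)) msg else TRUE
})

#' Mu suppression of one trial
#'
#' Holds the mu-band (default 8--13 Hz) power during the task segment and
#' the rest baseline, and the resulting suppression score
#' \eqn{MSS = -(P_{task} - P_{rest})/P_{rest} \times 100}.  A positive
#' score means the mu rhythm was suppressed during the task; the score is
#' bounded above by 100 (total suppression) and unbounded below.
#'
#' @export
setClass("MuSuppression",
    representation(pTask = "numeric", pRest = "numeric", score = "numeric"))

setValidity("MuSuppression", function(object) {
    if (object@pRest <= 0) return("pRest must be positive")
    if (object@pTask < 0) return("pTask must be non-negative")
    if (object@score > 100 + 1e-9) return("score cannot exceed 100")
    TRUE
})

#' Two-class linear discriminant model
#'
#' Fisher linear discriminant over band-power features: class means, pooled
#' within-class covariance (ridge-regularized when near-singular), weight
#' vector \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)} and bias placing the decision
#' boundary midway between the projected class means, shifted by the
#' log-prior ratio.  Predicts the second class when \eqn{w \cdot x + b > 0}.
#'
#' @export
setClass("LinearDiscriminantModel",
    representation(weights = "numeric", bias = "numeric",
                   classMeans = "matrix", pooledCov = "matrix",
                   priors = "numeric", classes = "character",
                   regularized = "logical"))

#' Region-level BOLD time series
#'
#' Mean BOLD signal per brain region over the resting-state acquisition, a
#' region x time matrix with region labels as rownames.  Labels carry a
#' hemisphere prefix (\code{"L_"} / \code{"R_"}) so that left-lesion
#' subjects can be flipped onto a common (lesion-right) orientation.
#'
#' @slot data region x time numeric matrix, rownames = region labels.
#' @slot trSeconds repetition time between volumes, seconds.
#' @slot subjectId,session,lesionSide acquisition metadata; session is
#'   \code{"pre"} or \code{"post"}.
#' @export
setClass("RegionTimeSeries",
    representation(data = "matrix", trSeconds = "numeric",
                   subjectId = "character", session = "character",
                   lesionSide = "character"))

setValidity("RegionTimeSeries", function(object) {
    msg <- character()
    if (is.null(rownames(object@data)))
        msg <- c(msg, "data must have region labels as rownames")
    else if (anyDuplicated(rownames(object@data)))
        msg <- c(msg, "region labels must be unique")
    if (anyNA(object@data))
        msg <- c(msg, "missing time points are not allowed")
    if (length(object@trSeconds) != 1 || object@trSeconds <= 0)
        msg <- c(msg, "trSeconds must be a positive scalar")
    if (!object@session %in% c("pre", "post", "unknown"))
        msg <- c(msg, "session must be 'pre', 'post' or 'unknown'")
    if (length(msg)) msg else TRUE
})

#' Windowed dynamic connectivity
#'
#' The sequence of region x region Pearson adjacency matrices obtained by
#' cutting a BOLD time series into consecutive non-overlapping windows of a
#' fixed length; the trailing remainder shorter than one window is
#' discarded, so the number of windows is \code{floor(T / L)}.
#'
#' @export
setClass("WindowedConnectivity",
    representation(windowLength = "integer", windows = "list"))

setValidity("WindowedConnectivity", function(object) {
    for (W in object@windows) {
        if (!isTRUE(all.equal(W, t(W), tolerance = 1e-8)))
            return("window adjacency matrices must be symmetric")
        if (any(abs(W) > 1 + 1e-8))
            return("correlation entries must lie in [-1, 1]")
    }
    TRUE
})

#' Per-region temporal variability profile
#'
#' For each region, one minus the mean pairwise Pearson correlation between
#' its connectivity profiles across time windows, averaged over the window
#' lengths used.  Values lie in [0, 2]: 0 when the region's connectivity
#' profile is perfectly preserved across windows, 2 in the anticorrelated
#' extreme.  Optionally carries subnetwork means after aggregation.
#'
#' @export
setClass("VariabilityProfile",
    representation(values = "numeric", windowLengths = "numeric",
                   subnetworkMeans = "numeric"))

setValidity("VariabilityProfile", function(object) {
    if (is.null(names(object@values)))
        return("values must be named by region")
    if (any(object@values < -1e-8 | object@values > 2 + 1e-8, na.rm = TRUE))
        return("variability values must lie in [0, 2]")
    TRUE
})
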