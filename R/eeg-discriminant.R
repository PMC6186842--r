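## The discriminant-rate (DR) pipeline: four-band hemispheric power
## features, an in-package two-class linear discriminant, and the
## session-based train/test protocol for early vs late training stages.

#' Canonical analysis bands
#'
#' The four frequency bands whose hemispheric powers form the feature
#' vector: alpha 8--13, low-beta 12.5--16, beta 16.5--20 and high-beta
#' 20.5--28 Hz.
#'
#' @return named list of \code{c(lo, hi)} pairs in Hz.
#' @export
analysisBands <- function() {
    list(alpha = c(8, 13), low_beta = c(12.5, 16),
         beta = c(16.5, 20), high_beta = c(20.5, 28))
}

#' Split the montage into hemispheric electrode sets
#'
#' Under the 10--20 convention odd-numbered electrodes sit over the left
#' hemisphere and even-numbered over the right; the midline electrodes
#' (Cz, FCz) belong to neither set.  The ipsilesional set is the one on
#' the lesion side.
#'
#' @param labels channel labels, drawn from \code{\link{montageChannels}}.
#' @param lesionSide \code{"L"} or \code{"R"}.
#' @return \code{list(ipsilesional =, contralesional =)} of 7 labels each
#'   for the full montage.
#' @export
hemisphericChannels <- function(labels = montageChannels(), lesionSide) {
    if (!lesionSide %in% c("L", "R"))
        stop("lesion side must be 'L' or 'R' (got '", lesionSide, "')")
    num <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
    left <- labels[!is.na(num) & num %% 2L == 1L]
    right <- labels[!is.na(num) & num %% 2L == 0L]
    if (lesionSide == "L")
        list(ipsilesional = left, contralesional = right)
    else
        list(ipsilesional = right, contralesional = left)
}

#' Band-power feature vectors per trial and state
#'
#' For every trial of a preprocessed recording, computes the four band
#' powers averaged over a hemispheric electrode set, separately for the
#' imagery (task) and rest segments: two labeled four-feature vectors per
#' trial.
#'
#' @param epochs an \code{\linkS4class{EpochedEEG}} (already filtered; see
#'   \code{\link{preprocessEEG}}).
#' @param channels electrode labels to average over, e.g. one element of
#'   \code{\link{hemisphericChannels}}.
#' @param bands named list of bands; default \code{\link{analysisBands}}.
#' @return \code{data.frame} with columns \code{trial}, \code{state}
#'   (\code{"imagery"}/\code{"rest"}) and one column per band.
#' @export
extractFeatures <- function(epochs, channels, bands = analysisBands()) {
    stopifnot(is(epochs, "EpochedEEG"))
    if (length(channels) == 0L) stop("empty channel selection")
    fs <- samplingRate(epochs)
    labels <- channelLabels(epochs)
    rows <- list()
    for (i in seq_len(nTrials(epochs))) {
        tr <- epochs@trials[[i]]
        if (is.null(tr$task) || is.null(tr$rest)) {
            warning("trial ", i, " lacks a segment; skipped")
            next
        }
        for (state in c("imagery", "rest")) {
            seg <- if (state == "imagery") tr$task else tr$rest
            rownames(seg) <- labels
            pw <- vapply(bands, function(b) bandPower(seg, fs, b, channels),
                         numeric(1))
            rows[[length(rows) + 1L]] <-
                c(list(trial = i, state = state), as.list(pw))
        }
    }
    do.call(rbind, lapply(rows, as.data.frame))
}

#' Fit a two-class linear discriminant
#'
#' Fisher LDA with class means, pooled within-class covariance and, when
#' the pooled covariance is near-singular (condition number above
#' \code{condThreshold}), a ridge term \code{lambda * mean(diag(S))} on the
#' diagonal.  The weight vector is \eqn{w = \Sigma^{-1}(\mu_1 - \mu_0)};
#' the bias places the boundary midway between the projected class means,
#' shifted by the log-prior ratio.
#'
#' @param x numeric feature matrix, observations in rows.
#' @param labels two-level factor or vector; the second sorted level is the
#'   positive class.
#' @param priors class prior probabilities in sorted-level order; default
#'   equal.
#' @param lambda relative ridge weight applied only when near-singular.
#' @param condThreshold condition-number cutoff for regularization.
#' @return a \code{\linkS4class{LinearDiscriminantModel}}.
#' @export
fitLDA <- function(x, labels, priors = c(0.5, 0.5), lambda = 1e-6,
                   condThreshold = 1e8) {
    x <- as.matrix(x)
    cl <- sort(unique(as.character(labels)))
    if (length(cl) != 2L)
        stop("need exactly two classes, got ", length(cl))
    x0 <- x[labels == cl[1], , drop = FALSE]
    x1 <- x[labels == cl[2], , drop = FALSE]
    n0 <- nrow(x0); n1 <- nrow(x1)
    if (n0 < 2L || n1 < 2L) stop("need at least two samples per class")
    mu0 <- colMeans(x0); mu1 <- colMeans(x1)
    S <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) /
        (n0 + n1 - 2)
    regularized <- FALSE
    kappaS <- tryCatch(kappa(S, exact = TRUE), error = function(e) Inf)
    if (!is.finite(kappaS) || kappaS > condThreshold) {
        S <- S + diag(lambda * mean(diag(S)) + .Machine$double.eps,
                      ncol(S))
        regularized <- TRUE
    }
    w <- drop(solve(S, mu1 - mu0))
    b <- -sum(w * (mu0 + mu1)) / 2 + log(priors[2] / priors[1])
    new("LinearDiscriminantModel", weights = w, bias = b,
        classMeans = rbind(mu0, mu1), pooledCov = S,
        priors = priors, classes = cl, regularized = regularized)
}

#' Predict classes from a linear discriminant model
#'
#' @param object a \code{\linkS4class{LinearDiscriminantModel}}.
#' @param newdata feature matrix with observations in rows.
#' @return character vector of predicted class labels.
#' @export
predictLDA <- function(object, newdata) {
    stopifnot(is(object, "LinearDiscriminantModel"))
    newdata <- as.matrix(newdata)
    score <- drop(newdata %*% object@weights) + object@bias
    ifelse(score > 0, object@classes[2], object@classes[1])
}

#' Train/test session split for one training stage
#'
#' The early stage uses the first four training sessions, the late stage
#' the last four.  Within the stage, two sessions are drawn uniformly at
#' random as the training set and the remaining two form the test set.
#'
#' @param nSessions total number of sessions (at least 8).
#' @param stage \code{"early"} or \code{"late"}.
#' @param seed optional integer seed for the draw.
#' @return \code{list(train =, test =)} of session indices (2 + 2,
#'   disjoint).
#' @export
sessionSplit <- function(nSessions, stage = c("early", "late"),
                         seed = NULL) {
    stage <- match.arg(stage)
    if (nSessions < 8L) stop("need at least 8 sessions")
    pool <- if (stage == "early") 1:4 else (nSessions - 3L):nSessions
    if (!is.null(seed)) set.seed(seed)
    train <- sort(sample(pool, 2L))
    list(train = train, test = setdiff(pool, train))
}

#' Discriminant rate of a fitted model on a test set
#'
#' The proportion of test feature vectors whose predicted state matches
#' the label — the study's index of how separable motor imagery and rest
#' are in a subject's EEG.
#'
#' @param model a \code{\linkS4class{LinearDiscriminantModel}}.
#' @param x test feature matrix.
#' @param labels true state labels.
#' @return proportion correct in [0, 1].
#' @export
discriminantRate <- function(model, x, labels) {
    if (NROW(x) == 0L) stop("empty test set")
    mean(predictLDA(model, x) == as.character(labels))
}

.featureMatrix <- function(feat, bands = names(analysisBands())) {
    as.matrix(feat[, bands, drop = FALSE])
}

#' Session-based discriminant-rate study
#'
#' The full DR protocol for one subject and hemisphere: extract band-power
#' features per session, split the stage's four sessions into 2 training +
#' 2 test sessions, fit the discriminant on the training trials, score the
#' test trials, and average the rate over \code{nSplits} seeded splits.
#' With \code{sessionAverage = TRUE} the features of all trials in a
#' session are first averaged per state (one vector per session and
#' state) before fitting and scoring.
#'
#' @param sessions list of \code{\linkS4class{EpochedEEG}} objects, one per
#'   training session in chronological order (at least 8).
#' @param hemisphere \code{"ipsilesional"} or \code{"contralesional"}.
#' @param stage \code{"early"} or \code{"late"}.
#' @param nSplits number of random 2+2 splits to average over; 1 reproduces
#'   the single-split protocol.
#' @param seed integer seed controlling the split draws.
#' @param sessionAverage average trial features within a session first.
#' @param preprocess run \code{\link{preprocessEEG}} on every segment.
#' @return list with the mean \code{rate}, per-split \code{rates},
#'   \code{hemisphere}, \code{stage} and \code{n_test}.
#' @export
discriminantRateStudy <- function(sessions, hemisphere = c("ipsilesional",
                                  "contralesional"),
                                  stage = c("early", "late"), nSplits = 10,
                                  seed = 1, sessionAverage = FALSE,
                                  preprocess = TRUE) {
    hemisphere <- match.arg(hemisphere)
    stage <- match.arg(stage)
    if (length(sessions) < 8L) stop("need at least 8 sessions")
    side <- lesionSide(sessions[[1]])
    channels <- hemisphericChannels(channelLabels(sessions[[1]]),
                                    side)[[hemisphere]]
    fs <- samplingRate(sessions[[1]])
    prep <- function(ep) {
        if (!preprocess) return(ep)
        ep@trials <- lapply(ep@trials, function(tr) {
            list(task = preprocessEEG(tr$task, fs),
                 rest = preprocessEEG(tr$rest, fs))
        })
        ep
    }
    pool <- if (stage == "early") 1:4 else
        (length(sessions) - 3L):length(sessions)
    feats <- lapply(pool, function(s)
        extractFeatures(prep(sessions[[s]]), channels))
    names(feats) <- as.character(pool)
    if (sessionAverage) {
        feats <- lapply(feats, function(f) {
            do.call(rbind, lapply(split(f, f$state), function(g) {
                out <- g[1, , drop = FALSE]
                out[names(analysisBands())] <-
                    colMeans(g[, names(analysisBands()), drop = FALSE])
                out
            }))
        })
    }
    set.seed(seed)
    split_seeds <- sample.int(.Machine$integer.max, nSplits)
    rates <- vapply(split_seeds, function(s) {
        sp <- sessionSplit(length(sessions), stage, seed = s)
        tr <- do.call(rbind, feats[as.character(sp$train)])
        te <- do.call(rbind, feats[as.character(sp$test)])
        model <- fitLDA(.featureMatrix(tr), tr$state)
        discriminantRate(model, .featureMatrix(te), te$state)
    }, numeric(1))
    list(rate = mean(rates), rates = rates, hemisphere = hemisphere,
         stage = stage,
         n_test = nrow(do.call(rbind, feats[1:2])))
}
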