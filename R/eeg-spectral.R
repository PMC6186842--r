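## Band-power estimation and the online mu-suppression trigger.

#' The 16-channel motor-area montage
#'
#' Channel labels of the 10--20 montage over the central motor areas used
#' throughout the package: C1--C6, Cz, FC1--FC4, FCz, CP1--CP4.
#'
#' @return character vector of 16 channel labels.
#' @export
montageChannels <- function() {
    c("C1", "C2", "C3", "C4", "C5", "C6", "Cz",
      "FC1", "FC2", "FC3", "FC4", "FCz",
      "CP1", "CP2", "CP3", "CP4")
}

#' Band-pass and notch filtering of raw EEG
#'
#' Applies the acquisition filters to a channel x sample matrix: a 2--60 Hz
#' band-pass and a 48--52 Hz band-stop (power-line notch), both 4th-order
#' Butterworth run forward and backward (\code{signal::filtfilt}) for zero
#' phase distortion.
#'
#' @param x channel x sample numeric matrix (a plain vector is treated as
#'   one channel).
#' @param samplingRate sampling rate in Hz, at least 128 so the 60 Hz edge
#'   stays below Nyquist.
#' @param band band-pass corner frequencies in Hz.
#' @param notch band-stop corner frequencies in Hz.
#' @return filtered matrix of the same shape.
#' @export
preprocessEEG <- function(x, samplingRate, band = c(2, 60),
                          notch = c(48, 52)) {
    if (is.vector(x)) x <- matrix(x, nrow = 1L)
    if (!all(is.finite(x))) stop("non-finite samples in input")
    if (samplingRate < 128) stop("samplingRate must be at least 128 Hz")
    if (max(band, notch) >= samplingRate / 2)
        stop("filter edge at or above Nyquist")
    ## filtfilt needs ~3x the filter order of samples for edge transients
    if (ncol(x) < 24L)
        stop("segment shorter than the filter warm-up (need >= 24 samples)")
    nyq <- samplingRate / 2
    bp <- signal::butter(4, band / nyq, type = "pass")
    bs <- signal::butter(4, notch / nyq, type = "stop")
    out <- t(apply(x, 1L, function(ch) {
        signal::filtfilt(bs, signal::filtfilt(bp, ch))
    }))
    dimnames(out) <- dimnames(x)
    out
}

#' In-band power from a single Hanning-tapered FFT
#'
#' Estimates band power the way the online system did: one Hanning window
#' over the whole segment, one FFT, and the power integrated over the
#' frequency bins whose center lies in \code{[band[1], band[2]]} (both
#' boundaries inclusive).  With a 6 s segment the bin spacing is 1/6 Hz.
#' The per-channel band powers are averaged over the selected channels.
#'
#' @param segment channel x sample matrix (vector = one channel).
#' @param samplingRate sampling rate in Hz.
#' @param band \code{c(f_lo, f_hi)} in Hz, inside (0, Nyquist).
#' @param channels character labels (matched against rownames) or numeric
#'   indices of the channels to average; default all.
#' @return scalar mean in-band power (signal units squared).
#' @export
bandPower <- function(segment, samplingRate, band, channels = NULL) {
    if (is.vector(segment)) segment <- matrix(segment, nrow = 1L)
    if (band[1] <= 0 || band[2] >= samplingRate / 2)
        stop("band must lie strictly inside (0, Nyquist)")
    if (band[2] <= band[1]) stop("band edges must be increasing")
    n <- ncol(segment)
    if (n / samplingRate < 1 / (band[2] - band[1]))
        stop("segment too short to resolve the requested band")
    if (!is.null(channels)) {
        if (length(channels) == 0L) stop("empty channel selection")
        if (is.character(channels)) {
            if (is.null(rownames(segment)))
                stop("character channel selection needs rownames")
            missing_ch <- setdiff(channels, rownames(segment))
            if (length(missing_ch))
                stop("unknown channel(s): ", paste(missing_ch, collapse = ", "))
        }
        segment <- segment[channels, , drop = FALSE]
    }
    w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))   # Hanning taper
    freqs <- (seq_len(n) - 1L) * samplingRate / n
    half <- seq_len(floor(n / 2) + 1L)
    in_band <- freqs[half] >= band[1] & freqs[half] <= band[2]
    if (!any(in_band)) stop("no FFT bin center falls inside the band")
    scale <- sum(w^2) * samplingRate                       # PSD normalisation
    per_channel <- apply(segment, 1L, function(ch) {
        spec <- abs(stats::fft(ch * w))^2 / scale
        psd <- spec[half]
        ## one-sided PSD: double everything except DC and Nyquist
        dbl <- rep(2, length(half))
        dbl[1] <- 1
        if (n %% 2 == 0) dbl[length(half)] <- 1
        sum(psd[in_band] * dbl[in_band]) * samplingRate / n
    })
    mean(per_channel)
}

#' Mu suppression score
#'
#' The event-related desynchronization score of the closed-loop trigger:
#' \deqn{MSS = -\frac{P_{task} - P_{rest}}{P_{rest}} \times 100} where
#' \eqn{P_{task}} and \eqn{P_{rest}} are the mu-band powers during the task
#' (action observation / motor imagery) and rest segments.  A score of 20
#' means task power dropped to 80\% of the rest baseline.
#'
#' @param pTask,pRest mu-band powers; \code{pRest} must be positive.
#' @return a \code{\linkS4class{MuSuppression}} object.
#' @examples
#' suppressionScore(muSuppressionScore(0.8, 1))  # 20
#' @export
muSuppressionScore <- function(pTask, pRest) {
    if (pRest <= 0) stop("pRest must be positive")
    if (pTask < 0) stop("pTask must be non-negative")
    new("MuSuppression", pTask = pTask, pRest = pRest,
        score = -(pTask - pRest) / pRest * 100)
}

#' Robot-hand trigger decision
#'
#' In \code{"eeg_guided"} mode the robot hand fires iff the mu suppression
#' score strictly exceeds the threshold (a score of exactly 20 does not
#' trigger).  In \code{"random"} mode the decision is a Bernoulli draw at
#' \code{successRate}, independent of the score — the sham condition that
#' matches training intensity without neural guidance.
#'
#' @param mss a \code{\linkS4class{MuSuppression}} or a bare numeric score.
#' @param threshold trigger threshold on the MSS scale.
#' @param mode \code{"eeg_guided"} or \code{"random"}.
#' @param successRate Bernoulli probability for random mode.
#' @param seed optional integer seed for random mode.
#' @return logical: trigger the robot hand.
#' @export
triggerDecision <- function(mss, threshold = 20,
                            mode = c("eeg_guided", "random"),
                            successRate = 0.8, seed = NULL) {
    mode <- match.arg(mode)
    score <- if (is(mss, "MuSuppression")) mss@score else as.numeric(mss)
    if (mode == "eeg_guided")
        return(score > threshold)
    if (!is.null(seed)) set.seed(seed)
    stats::runif(1) < successRate
}

#' Online electrode for the lesioned hemisphere
#'
#' The single electrode the online trigger listens to: C3 over the left
#' sensorimotor cortex for left-hemisphere lesions, C4 for right — always
#' the ipsilesional side, to train signals from the lesioned motor areas.
#'
#' @param lesionSide \code{"L"} or \code{"R"}.
#' @return \code{"C3"} or \code{"C4"}.
#' @export
onlineChannel <- function(lesionSide) {
    switch(as.character(lesionSide),
           L = "C3", R = "C4",
           stop("lesion side must be 'L' or 'R' (got '", lesionSide, "')"))
}

#' Per-trial mu suppression for an epoched recording
#'
#' Runs the full online pipeline over every trial: preprocessing (band-pass
#' + notch), mu-band power on the ipsilesional online electrode for the
#' task segment and for the rest segment immediately preceding it, and the
#' suppression score.
#'
#' @param epochs an \code{\linkS4class{EpochedEEG}}.
#' @param band mu band in Hz.
#' @param channel electrode label; defaults to the ipsilesional online
#'   electrode for the recording's lesion side.
#' @param preprocess logical; apply \code{\link{preprocessEEG}} first.
#' @return numeric vector of one MSS per trial.
#' @export
muSuppressionPipeline <- function(epochs, band = c(8, 13), channel = NULL,
                                  preprocess = TRUE) {
    stopifnot(is(epochs, "EpochedEEG"))
    if (is.null(channel)) channel <- onlineChannel(lesionSide(epochs))
    fs <- samplingRate(epochs)
    vapply(epochs@trials, function(tr) {
        task <- tr$task; rest <- tr$rest
        rownames(task) <- rownames(rest) <- channelLabels(epochs)
        if (preprocess) {
            task <- preprocessEEG(task, fs)
            rest <- preprocessEEG(rest, fs)
        }
        p_task <- bandPower(task, fs, band, channel)
        p_rest <- bandPower(rest, fs, band, channel)
        suppressionScore(muSuppressionScore(p_task, p_rest))
    }, numeric(1))
}
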